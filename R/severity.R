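#' Construct a seizure diary
#'
#' Timestamped behavioral stage intervals for one animal, with the dosing
#' protocol and optional diazepam/death times. Stages are the behavioral
#' Racine stages 0-5 (the EEG 3A/3B split collapses to 3 for behavioral
#' scoring; see [stage_to_behavioral()]).
#'
#' @param animal_id identifier.
#' @param protocol `"RLD"` (repeated low dose) or `"SHD"` (single high dose).
#' @param intervals data.frame with `start`, `end` (s) and `stage` (0-5);
#'   must be ordered and non-overlapping.
#' @param diazepam_time,death_time seconds, or NA.
#' @return object of class `seizure_diary`.
#' @export
seizure_diary <- function(animal_id, protocol, intervals,
                          diazepam_time = NA_real_, death_time = NA_real_) {
  protocol <- match.arg(protocol, c("RLD", "SHD"))
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("start", "end", "stage") %in% names(intervals)))
  if (nrow(intervals)) {
    if (any(intervals$end <= intervals$start)) {
      stop("intervals must have end > start")
    }
    if (is.unsorted(intervals$start)) {
      intervals <- intervals[order(intervals$start), ]
    }
    if (nrow(intervals) > 1L &&
        any(intervals$start[-1] < intervals$end[-nrow(intervals)] - 1e-9)) {
      stop("intervals overlap")
    }
    if (any(!intervals$stage %in% 0:5)) stop("stages must be in 0..5")
  }
  structure(list(animal_id = animal_id, protocol = protocol,
                 intervals = intervals, diazepam_time = diazepam_time,
                 death_time = death_time),
            class = "seizure_diary")
}

#' Map EEG stage labels to behavioral Racine stages
#'
#' `baseline` maps to 0; HFT has no behavioral correlate and maps to the
#' stage in force (0 here, callers may carry the previous stage); 3A and 3B
#' collapse to 3.
#'
#' @param labels character vector of classifier labels.
#' @return integer vector of behavioral stages.
#' @export
stage_to_behavioral <- function(labels) {
  map <- c(baseline = 0L, `1` = 1L, `2` = 2L, HFT = 2L,
           `3A` = 3L, `3B` = 3L, `4` = 4L, `5` = 5L)
  unname(map[labels])
}

.diary_span <- function(diary) {
  if (!nrow(diary$intervals)) return(c(0, 0))
  c(0, max(diary$intervals$end, diary$diazepam_time, diary$death_time,
           na.rm = TRUE))
}

#' Racine score of one 5-min epoch
#'
#' The highest behavioral stage reached in the epoch (0 if seizure-free):
#' e.g. an epoch with 3 min of stages 1-2 followed by 2 min of stage 3
#' scores 3.
#'
#' @param diary a [seizure_diary()].
#' @param epoch_start epoch start (s); the epoch is
#'   `[epoch_start, epoch_start + 300)`.
#' @param epoch_end optional end of the scored part of the epoch (used for
#'   clipping at diazepam/death).
#' @return integer stage 0-5.
#' @export
racine_epoch_score <- function(diary, epoch_start, epoch_end = NULL) {
  stopifnot(inherits(diary, "seizure_diary"))
  span <- .diary_span(diary)
  if (epoch_start < span[1] || epoch_start >= span[2]) {
    stop("epoch outside the diary span")
  }
  if (is.null(epoch_end)) epoch_end <- epoch_start + 300
  iv <- diary$intervals
  ov <- pmin(iv$end, epoch_end) - pmax(iv$start, epoch_start)
  hit <- ov > 1e-9
  if (!any(hit)) return(0L)
  as.integer(max(iv$stage[hit]))
}

#' The status epilepticus window
#'
#' SE is the 2-h window from the protocol's index seizure: the first onset
#' of stage 5 for RLD animals, the first onset of stage >= 3 (CMS) for SHD
#' animals.
#'
#' @param diary a [seizure_diary()].
#' @return list of class `se_window`: `achieved` (logical), and when
#'   achieved `start` and `end` (s; end - start = 7200).
#' @export
se_window <- function(diary) {
  stopifnot(inherits(diary, "seizure_diary"))
  iv <- diary$intervals
  idx_stage <- if (diary$protocol == "RLD") 5L else 3L
  hit <- if (diary$protocol == "RLD") which(iv$stage == 5L) else
    which(iv$stage >= 3L)
  if (!length(hit)) {
    return(structure(list(achieved = FALSE, index_stage = idx_stage),
                     class = "se_window"))
  }
  s <- iv$start[hit[1]]
  structure(list(achieved = TRUE, index_stage = idx_stage,
                 start = s, end = s + 7200),
            class = "se_window")
}

#' Cumulative seizure severity over the SE window
#'
#' Computes the total time at CMS (stage >= 3), the total time at stage 5,
#' and the cumulative seizure severity score: the sum over the 24 five-min
#' epochs tiling the window of each epoch's highest behavioral stage.
#' Contributions are clipped at diazepam or death, whichever comes first.
#'
#' @param diary a [seizure_diary()].
#' @param window an achieved [se_window()].
#' @return list: `time_in_cms_s`, `time_in_stage5_s`, `severity_score`.
#' @export
cumulative_severity <- function(diary, window) {
  stopifnot(inherits(diary, "seizure_diary"), inherits(window, "se_window"))
  if (!isTRUE(window$achieved)) stop("SE not achieved for this diary")
  clip <- min(window$end, diary$diazepam_time, diary$death_time, na.rm = TRUE)
  iv <- diary$intervals
  ov <- function(min_stage) {
    sel <- iv$stage >= min_stage
    sum(pmax(0, pmin(iv$end[sel], clip) - pmax(iv$start[sel], window$start)))
  }
  span_end <- .diary_span(diary)[2]
  ep_starts <- seq(window$start, window$end - 1, by = 300)
  sev <- sum(vapply(ep_starts, function(t0) {
    t1 <- min(t0 + 300, clip)
    if (t1 <= t0 || t0 >= span_end) return(0L)  # beyond the diary: 0
    racine_epoch_score(diary, t0, t1)
  }, integer(1)))
  list(time_in_cms_s = ov(3L), time_in_stage5_s = ov(5L),
       severity_score = sev)
}

#' Build a diary from classified epochs
#'
#' Converts a classifier epoch labeling into behavioral stage intervals
#' (artifact epochs inherit the previous stage; 3A/3B collapse to 3).
#'
#' @param classified output of [classify_epochs()].
#' @param animal_id,protocol,diazepam_time,death_time forwarded to
#'   [seizure_diary()].
#' @param epoch_length epoch length (s).
#' @return a [seizure_diary()].
#' @export
diary_from_epochs <- function(classified, animal_id = "rec",
                              protocol = "RLD", diazepam_time = NA_real_,
                              death_time = NA_real_, epoch_length = 10) {
  st <- stage_to_behavioral(ifelse(classified$excluded, NA,
                                   classified$label))
  # artifact epochs inherit the previous behavioral stage
  for (i in seq_along(st)) {
    if (is.na(st[i])) st[i] <- if (i > 1L) st[i - 1L] else 0L
  }
  r <- rle(st)
  ends <- cumsum(r$lengths) * epoch_length
  starts <- ends - r$lengths * epoch_length
  iv <- data.frame(start = starts + classified$epoch_start[1],
                   end = ends + classified$epoch_start[1],
                   stage = r$values)
  seizure_diary(animal_id, protocol, iv[iv$stage > 0 | TRUE, ],
                diazepam_time, death_time)
}
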