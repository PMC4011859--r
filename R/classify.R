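#' Classify an epoch as artifact
#'
#' Applies the published artifact criteria to one epoch:
#' * electrical — any spike above 2 mV lasting under 20 ms;
#' * grooming — delta, theta and alpha power elevated above the stage-free
#'   baseline while sigma, beta and gamma remain at baseline, with no
#'   detected epileptiform spikes and no activity;
#' * movement — activity counts with all six band powers at baseline and a
#'   slow (> 0.5 s) large deflection present.
#' Precedence: electrical > grooming > movement.
#'
#' @param features one row of [epoch_features()].
#' @param spikes data.frame of detected spikes within the epoch
#'   (amplitude, duration_ms).
#' @param slow_events data.frame of slow deflections overlapping the epoch
#'   (may be empty).
#' @return `"electrical"`, `"grooming"`, `"movement"`, or `NA_character_`.
#' @export
classify_artifact <- function(features, spikes = NULL, slow_events = NULL) {
  f <- as.list(features)
  if (!is.null(spikes) && nrow(spikes) &&
      any(spikes$amplitude > 2000 & spikes$duration_ms < 20)) {
    return("artifact_electrical")
  }
  pow <- unlist(f[.BANDS$band])
  b <- .BASELINE_POWER_BOUND
  n_spk <- if (is.null(spikes)) f$spike_count else nrow(spikes)
  has_slow <- !is.null(slow_events) && nrow(slow_events) > 0
  if (any(is.na(pow))) {
    # epoch too occluded to measure power: a slow deflection with paired
    # activity is still identifiable as movement
    if (has_slow && isTRUE(f$activity > 0)) return("artifact_movement")
    return(NA_character_)
  }
  if (pow["delta"] > 2 * b && pow["theta"] > b && pow["alpha"] > 3 &&
      pow["sigma"] < b && pow["beta"] < b && pow["gamma"] < b &&
      isTRUE(n_spk == 0) && isTRUE(f$activity == 0)) {
    return("artifact_grooming")
  }
  if (isTRUE(f$activity > 0) && all(pow < b) && has_slow) {
    return("artifact_movement")
  }
  NA_character_
}

#' Detect slow deflections (movement-artifact candidates)
#'
#' Contiguous runs of deflection from an 8-s running-median baseline that
#' stay above `threshold` for at least `min_width_s` — far wider than any
#' epileptiform spike.
#'
#' @param record an [eeg_record].
#' @param threshold uV (default 200).
#' @param min_width_s minimum width in seconds (default 0.6).
#' @param baseline_win_s running-median window (s); long enough that a
#'   multi-second deflection is not tracked by its own baseline.
#' @return data.frame with `onset`, `offset`, `peak` (uV).
#' @export
detect_slow_deflections <- function(record, threshold = 200,
                                    min_width_s = 0.6,
                                    baseline_win_s = 20) {
  x <- record$samples
  fs <- record$sampling_rate
  d <- abs(x - .running_baseline(x, fs, baseline_win_s))
  r <- rle(d >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_width_s * fs
  data.frame(onset = (starts[sel] - 1) / fs, offset = ends[sel] / fs,
             peak = vapply(which(sel), function(i)
               max(d[starts[i]:ends[i]]), numeric(1)))
}

#' Score an epoch against every stage
#'
#' For each stage label the score is the fraction of the 11 features
#' (spike amplitude, duration, ISI, rate; six band powers; activity) lying
#' inside that stage's published range.
#'
#' @param features one row of [epoch_features()].
#' @param rules a [stage_rule_table()].
#' @return named numeric vector over stages, values in [0, 1].
#' @export
score_stage <- function(features, rules) {
  f <- as.list(features)
  vals <- c(amp = f$mean_amplitude, dur = f$mean_duration, isi = f$mean_isi,
            rate = f$rate,
            unlist(f[.BANDS$band]), act = f$activity)
  names(vals) <- c("amp", "dur", "isi", "rate", .BANDS$band, "act")
  out <- vapply(.STAGES, function(st) {
    inr <- vapply(names(vals), function(feat) {
      v <- vals[[feat]]
      if (is.na(v)) return(0)
      r <- .rule_range(rules, st, feat)
      as.numeric(v >= r[1] & v <= r[2])
    }, numeric(1))
    sum(inr) / length(inr)
  }, numeric(1))
  names(out) <- .STAGES
  out
}

#' Classify every epoch of a feature table
#'
#' Artifact epochs are labeled first (and excluded from everything
#' downstream); remaining epochs are labeled baseline when they carry no
#' epileptiform spikes and all band powers are below the baseline bound,
#' otherwise by the argmax of [score_stage()]. Ties are broken toward the
#' temporally previous label, else toward the higher stage. The non-artifact
#' label sequence is then median-smoothed over `smoothing_len` epochs.
#'
#' @param features data.frame from [epoch_features()].
#' @param rules a [stage_rule_table()].
#' @param smoothing_len odd window length for median smoothing (1 = none).
#' @param spikes optional spikes data.frame (from a [spike_train]) used for
#'   the electrical-artifact rule; assigned to epochs by peak time.
#' @param slow_events optional data.frame from [detect_slow_deflections()].
#' @param epoch_length epoch length in s.
#' @return data.frame: `epoch_start`, `label`, `excluded`, plus a `scores`
#'   matrix attribute.
#' @export
classify_epochs <- function(features, rules, smoothing_len = 3,
                            spikes = NULL, slow_events = NULL,
                            epoch_length = 10) {
  n <- nrow(features)
  labels <- character(n)
  excluded <- logical(n)
  scores <- matrix(NA_real_, n, length(.STAGES),
                   dimnames = list(NULL, .STAGES))
  prev <- "baseline"
  for (i in seq_len(n)) {
    t0 <- features$epoch_start[i]
    sp_i <- if (!is.null(spikes) && nrow(spikes))
      spikes[spikes$peak_time >= t0 &
               spikes$peak_time < t0 + epoch_length, , drop = FALSE]
    else spikes
    sl_i <- if (!is.null(slow_events) && nrow(slow_events))
      slow_events[slow_events$offset > t0 &
                    slow_events$onset < t0 + epoch_length, , drop = FALSE]
    else slow_events
    art <- classify_artifact(features[i, ], sp_i, sl_i)
    if (!is.na(art)) {
      labels[i] <- art
      excluded[i] <- TRUE
      next
    }
    pow <- unlist(features[i, .BANDS$band])
    if (features$spike_count[i] == 0 &&
        all(is.na(pow) | pow < .BASELINE_POWER_BOUND)) {
      labels[i] <- "baseline"
      prev <- "baseline"
      next
    }
    sc <- score_stage(features[i, ], rules)
    scores[i, ] <- sc
    top <- names(sc)[sc == max(sc)]
    lab <- if (prev %in% top) prev else
      top[which.max(.STAGE_ORDER[top])]
    labels[i] <- lab
    prev <- lab
  }
  # median smoothing on the ordinal stage scale, artifact epochs left out
  if (smoothing_len > 1 && n >= smoothing_len) {
    ok <- !excluded
    ord <- .STAGE_ORDER[labels[ok]]
    if (length(ord) >= smoothing_len) {
      sm <- stats::runmed(ord, .odd(as.integer(smoothing_len)),
                          endrule = "keep")
      labels[ok] <- names(.STAGE_ORDER)[match(sm, .STAGE_ORDER)]
    }
  }
  out <- data.frame(epoch_start = features$epoch_start, label = labels,
                    excluded = excluded, stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  out
}

#' Detect high-frequency trigger (HFT) intervals
#'
#' Maximal runs of at least `min_run` consecutive spikes whose amplitude
#' (300-1000 uV), duration (20-40 ms) and inter-spike intervals (25-60 ms)
#' all satisfy the published HFT ranges; runs separated by less than
#' `merge_gap_s` are merged (HFT spikes arrive in bursts; the published
#' 120-200/min frequency counts spikes per minute across bursts). Intervals
#' are kept only where the surrounding epochs show the HFT signature of
#' elevated alpha and sigma power with zero activity.
#'
#' @param train a [spike_train].
#' @param features data.frame from [epoch_features()] (for the power gate);
#'   optional — when NULL the power gate is skipped.
#' @param min_run minimum spikes per run (default 5).
#' @param merge_gap_s merge gap in seconds (default 5).
#' @return data.frame with `start`, `end` (s).
#' @export
detect_hft <- function(train, features = NULL, min_run = 5, merge_gap_s = 5) {
  sp <- train$spikes
  empty <- data.frame(start = numeric(0), end = numeric(0))
  if (nrow(sp) < min_run) return(empty)
  amp_ok <- sp$amplitude >= 300 & sp$amplitude <= 1000
  dur_ok <- sp$duration_ms >= 20 & sp$duration_ms <= 40
  # ISIs from event-extent midpoints (more stable than peak argmax for
  # short spikes), with a quantization allowance of 1.5 sample periods
  mid <- (sp$onset + sp$offset) / 2
  isi <- diff(mid) * 1000
  tol <- 1.5 / train$sampling_rate * 1000
  link <- isi >= 25 - tol & isi <= 60 + tol
  runs <- list()
  i <- 1L
  while (i <= nrow(sp)) {
    if (amp_ok[i] && dur_ok[i]) {
      j <- i
      while (j < nrow(sp) && link[j] && amp_ok[j + 1L] && dur_ok[j + 1L]) {
        j <- j + 1L
      }
      if (j - i + 1L >= min_run) {
        runs[[length(runs) + 1L]] <- c(sp$onset[i], sp$offset[j])
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(empty)
  iv <- do.call(rbind, runs)
  merged <- list(iv[1, ])
  for (k in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv[k, 1] - last[2] < merge_gap_s) {
      merged[[length(merged)]] <- c(last[1], iv[k, 2])
    } else merged[[length(merged) + 1L]] <- iv[k, ]
  }
  iv <- do.call(rbind, merged)
  out <- data.frame(start = iv[, 1], end = iv[, 2])
  if (!is.null(features)) {
    keep <- vapply(seq_len(nrow(out)), function(k) {
      ep <- features[features$epoch_start + 10 > out$start[k] &
                       features$epoch_start < out$end[k], , drop = FALSE]
      if (!nrow(ep)) return(TRUE)
      # activity gate: HFT itself has no activity, but a brief trigger can
      # share its epoch with an adjacent stage, so only convulsive-level
      # activity (> the stage-3A bound of 8) vetoes the interval
      mean(ep$alpha, na.rm = TRUE) > .BASELINE_POWER_BOUND &&
        mean(ep$sigma, na.rm = TRUE) > .BASELINE_POWER_BOUND &&
        all(ep$activity <= 8)
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Detect the published power-band transition markers
#'
#' Emits an `ncs_to_cms` marker at the first epoch where delta power has
#' dropped to half (or less) of its stage-2 peak while beta and gamma both
#' exceed their stage-2 epoch means (the progression from non-convulsive to
#' convulsive motor seizures), and a `stage3a_to_3b` marker at the first
#' subsequent epoch where theta rises above the stage-3A upper bound
#' (12 power units).
#'
#' @param classified output of [classify_epochs()].
#' @param features matching [epoch_features()] table.
#' @param delta_drop fraction of the stage-2 delta peak defining the
#'   NCS-to-CMS marker (default 0.5).
#' @param theta_bound stage-3A theta upper bound (default 12).
#' @return data.frame with `time` (s) and `marker`.
#' @export
detect_transitions <- function(classified, features, delta_drop = 0.5,
                               theta_bound = 12) {
  out <- data.frame(time = numeric(0), marker = character(0),
                    stringsAsFactors = FALSE)
  ok <- !classified$excluded
  lab <- classified$label
  s2 <- ok & lab == "2"
  ncs_idx <- NA_integer_
  if (any(s2)) {
    peak_delta <- max(features$delta[s2], na.rm = TRUE)
    beta_ref <- mean(features$beta[s2], na.rm = TRUE)
    gamma_ref <- mean(features$gamma[s2], na.rm = TRUE)
    first2 <- which(s2)[1]
    cand <- which(ok & seq_along(lab) > first2 &
                    features$delta <= delta_drop * peak_delta &
                    features$beta > beta_ref & features$gamma > gamma_ref)
    if (length(cand)) {
      ncs_idx <- cand[1]
      out <- rbind(out, data.frame(time = features$epoch_start[ncs_idx],
                                   marker = "ncs_to_cms"))
    }
  }
  start3 <- if (!is.na(ncs_idx)) ncs_idx else 1L
  seen3a <- FALSE
  for (i in seq(start3, nrow(classified))) {
    if (!ok[i]) next
    if (lab[i] == "3A") seen3a <- TRUE
    if (seen3a && features$theta[i] > theta_bound) {
      out <- rbind(out, data.frame(time = features$epoch_start[i],
                                   marker = "stage3a_to_3b"))
      break
    }
  }
  rownames(out) <- NULL
  out
}

#' One-call analysis of a record
#'
#' Runs spike detection, epoch feature extraction, artifact/stage
#' classification, HFT detection and transition marking.
#'
#' @param record an [eeg_record].
#' @param rules a [stage_rule_table()].
#' @param threshold spike-detection threshold (uV).
#' @param smoothing_len see [classify_epochs()].
#' @return list with `train`, `features`, `epochs`, `hft`, `transitions`,
#'   `slow_events`.
#' @export
analyze_record <- function(record, rules = stage_rule_table(),
                           threshold = 200, smoothing_len = 3) {
  train <- detect_spikes(record, threshold = threshold)
  slow <- detect_slow_deflections(record)
  feats <- epoch_features(record, train, slow_events = slow)
  eps <- classify_epochs(feats, rules, smoothing_len = smoothing_len,
                         spikes = train$spikes, slow_events = slow)
  hft <- detect_hft(train, feats)
  trans <- detect_transitions(eps, feats)
  list(train = train, features = feats, epochs = eps, hft = hft,
       transitions = trans, slow_events = slow)
}
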