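#' Simulation configuration
#'
#' Describes a synthetic video-EEG recording: an ordered plan of stage
#' segments, optional artifact injections, and the sampling/scaling
#' parameters of the virtual acquisition system.
#'
#' @param stage_plan data.frame with columns `label` (one of baseline, 1, 2,
#'   HFT, 3A, 3B, 4, 5) and `duration` (s, > 0; >= 10 s for non-HFT stages,
#'   >= 2 s for HFT).
#' @param artifact_plan optional data.frame with columns `kind` (electrical,
#'   movement, grooming), `onset` (s) and `duration` (s); windows must lie
#'   inside the recording and must not overlap each other.
#' @param sampling_rate Hz; must be >= 160 (Nyquist for the 80 Hz gamma
#'   upper edge). Default 250.
#' @param baseline_noise_sd total background noise sd (uV) for baseline
#'   epochs; split evenly across the six bands. Default 10 uV, which keeps
#'   every baseline band power (including occasional sub-threshold baseline
#'   spikes) below the published 5-unit bound.
#' @param margin fraction in [0, 0.5) by which every published feature range
#'   is shrunk toward its midpoint when sampling, making classes separable.
#'   Default 0.2.
#' @param power_scale uV^2 of periodogram band integral per printed power
#'   unit (acquisition gain; see the methods vignette).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @param rules stage rule table (defaults to the shipped table).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(stage_plan, artifact_plan = NULL, sampling_rate = 250,
                       baseline_noise_sd = 10, margin = 0.2,
                       power_scale = .POWER_SCALE, seed = 1L, rules = NULL) {
  if (sampling_rate < 160) {
    stop("sampling_rate must be >= 160 Hz (gamma band Nyquist)")
  }
  if (margin < 0 || margin >= 0.5) stop("margin must be in [0, 0.5)")
  stage_plan <- as.data.frame(stage_plan)
  stopifnot(all(c("label", "duration") %in% names(stage_plan)))
  stage_plan$label <- as.character(stage_plan$label)
  bad <- setdiff(stage_plan$label, c("baseline", .STAGES))
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (any(stage_plan$duration <= 0)) stop("stage durations must be > 0")
  .check_segment_durations(stage_plan)
  total <- sum(stage_plan$duration)
  if (!is.null(artifact_plan)) {
    artifact_plan <- as.data.frame(artifact_plan)
    stopifnot(all(c("kind", "onset", "duration") %in% names(artifact_plan)))
    artifact_plan$kind <- as.character(artifact_plan$kind)
    bad <- setdiff(artifact_plan$kind, c("electrical", "movement", "grooming"))
    if (length(bad)) stop("unknown artifact kind(s): ",
                          paste(bad, collapse = ", "))
    if (any(artifact_plan$onset < 0 |
            artifact_plan$onset + artifact_plan$duration > total)) {
      stop("artifact window outside the recording")
    }
    o <- order(artifact_plan$onset)
    ap <- artifact_plan[o, ]
    if (nrow(ap) > 1L &&
        any(ap$onset[-1] < (ap$onset + ap$duration)[-nrow(ap)])) {
      stop("artifact windows overlap")
    }
  }
  if (is.null(rules)) rules <- stage_rule_table()
  structure(list(stage_plan = stage_plan, artifact_plan = artifact_plan,
                 sampling_rate = sampling_rate,
                 baseline_noise_sd = baseline_noise_sd, margin = margin,
                 power_scale = power_scale, seed = as.integer(seed),
                 rules = rules),
            class = "sim_config")
}

.check_segment_durations <- function(plan) {
  min_dur <- ifelse(plan$label == "HFT", 2, ifelse(plan$label == "baseline",
                                                   10, 10))
  short <- plan$duration < min_dur
  if (any(short)) {
    stop("segment duration below minimum (>= 10 s, HFT >= 2 s) for label(s): ",
         paste(unique(plan$label[short]), collapse = ", "))
  }
}

# ---- spike waveforms --------------------------------------------------------

# unit-amplitude spike waveform sampled at fs; returns main lobe + after-wave.
# base shape sin(pi u)^(1/8): near-rectangular shoulders so the width
# measured at the detection threshold stays close to the nominal duration.
.spike_wave <- function(dur_ms, kind, fs) {
  n <- max(4L, as.integer(round(dur_ms / 1000 * fs)))
  u <- (seq_len(n) - 0.5) / n
  w <- sin(pi * u)^(1 / 8) *
    (0.9 + 0.1 * exp(-(u - 0.45)^2 / (2 * 0.06^2)))
  if (kind == "complex") {
    k <- sample(3:4, 1L)
    ph <- stats::runif(1, 0, 2 * pi)
    w <- w * (1 - 0.2 * (0.5 - 0.5 * cos(2 * pi * k * u + ph)))
  } else if (kind == "brush") {
    f <- stats::runif(1, 100, 140)
    t <- u * n / fs
    w <- w * (1 - 0.15 * (0.5 - 0.5 * cos(2 * pi * f * t)))
  }
  m <- max(2L, as.integer(round(0.3 * n)))
  # after-wave kept shallow for brief (< 50 ms) spikes so that tightly
  # packed HFT spikes do not bridge the detector's half-threshold gap
  depth <- if (dur_ms < 50) 0.03 else 0.1
  tail <- if (kind == "electrical") numeric(0) else
    -depth * sin(pi * (seq_len(m) - 0.5) / m)^2
  list(main = w, tail = tail)
}

# sample cluster-structured spike times/shapes for one stage segment.
# Within-cluster ISIs follow the published ISI range; the per-minute count
# follows the published rate range; durations are capped so consecutive
# spikes never fuse into a single detection event.
.gen_segment_spikes <- function(label, duration, rules, margin) {
  if (label == "baseline") {
    # sparse sub-threshold non-epileptiform spikes: low enough energy that
    # every baseline band power stays below the published 5-unit bound
    n <- max(0L, as.integer(round(stats::runif(1, 2, 8) * duration / 60)))
    if (n == 0L) return(.empty_spikes())
    times <- sort(stats::runif(n, 0.5, duration - 0.5))
    return(data.frame(time = times,
                      amplitude = stats::runif(n, 30, 80),
                      duration_ms = stats::runif(n, 20, 50),
                      kind = "simple", stringsAsFactors = FALSE))
  }
  amp_r <- .shrink(rules[label, "amp_lo"], rules[label, "amp_hi"], margin)
  dur_r <- .shrink(rules[label, "dur_lo"], rules[label, "dur_hi"], margin)
  isi_r <- .shrink(rules[label, "isi_lo"], rules[label, "isi_hi"], margin)
  rate_r <- .shrink(rules[label, "rate_lo"], rules[label, "rate_hi"], margin)
  rate <- stats::runif(1, rate_r[1], rate_r[2])
  n <- as.integer(round(rate * duration / 60))
  if (n <= 0L) return(.empty_spikes())
  d_cap <- max(dur_r[1], min(dur_r[2], isi_r[2] - 15))
  csize <- if (label == "HFT") 5:6 else 3:6
  sizes <- integer(0)
  left <- n
  while (left > 0L) {
    s <- min(left, sample(csize, 1L))
    sizes <- c(sizes, s)
    left <- left - s
  }
  if (label == "HFT" && length(sizes) > 1L && sizes[length(sizes)] < 5L) {
    # no burst below the minimum detectable run length
    sizes[length(sizes) - 1L] <- sizes[length(sizes) - 1L] +
      sizes[length(sizes)]
    sizes <- sizes[-length(sizes)]
  }
  durs <- list(); isis <- list()
  for (s in sizes) {
    d <- stats::runif(s, dur_r[1], d_cap)
    gi <- if (s > 1L) {
      lo <- pmax(isi_r[1], (d[-s] + d[-1]) / 2 + 12)
      stats::runif(s - 1L, pmin(lo, isi_r[2] - 1), isi_r[2])
    } else numeric(0)
    durs[[length(durs) + 1L]] <- d
    isis[[length(isis) + 1L]] <- gi
  }
  spans <- vapply(seq_along(sizes), function(i)
    sum(isis[[i]]) / 1000 + durs[[i]][1] / 2000 +
      durs[[i]][sizes[i]] / 2000, numeric(1))
  pad <- if (label == "HFT") 0.15 else max(0.3, d_cap / 1000)
  free <- duration - 2 * pad - sum(spans)
  ngap <- length(sizes) + 1L
  gw <- stats::runif(ngap, 0.2, 1)
  if (label == "HFT" && ngap > 2L) {
    # spread bursts evenly edge to edge so one detected HFT interval spans
    # the segment (bursts separated by less than the merge gap)
    gw <- c(0.02, stats::runif(ngap - 2L, 0.7, 1), 0.02)
  }
  gaps <- if (free > 0) free * gw / sum(gw) else rep(0, ngap)
  kind <- switch(label, "1" = , "2" = , "HFT" = "simple",
                 "3A" = , "3B" = , "5" = "complex", "4" = "brush")
  times <- numeric(0); dd <- numeric(0)
  cursor <- pad
  for (i in seq_along(sizes)) {
    cursor <- cursor + gaps[i] + durs[[i]][1] / 2000
    tt <- cursor + c(0, cumsum(isis[[i]])) / 1000
    cursor <- tt[length(tt)] + durs[[i]][sizes[i]] / 2000
    times <- c(times, tt)
    dd <- c(dd, durs[[i]])
  }
  keep <- times > pad / 2 & times < duration - pad / 2
  data.frame(time = times[keep],
             amplitude = stats::runif(sum(keep), amp_r[1], amp_r[2]),
             duration_ms = dd[keep], kind = kind, stringsAsFactors = FALSE)
}

.empty_spikes <- function() {
  data.frame(time = numeric(0), amplitude = numeric(0),
             duration_ms = numeric(0), kind = character(0),
             stringsAsFactors = FALSE)
}

# render spikes into a zero trace; returns trace plus extents (s) for masking
.render_spikes <- function(n_samples, fs, spikes) {
  x <- numeric(n_samples)
  if (!nrow(spikes)) {
    return(list(trace = x, onset = numeric(0), offset = numeric(0)))
  }
  ons <- offs <- numeric(nrow(spikes))
  for (i in seq_len(nrow(spikes))) {
    wv <- .spike_wave(spikes$duration_ms[i], spikes$kind[i], fs)
    full <- c(wv$main, wv$tail) * spikes$amplitude[i] *
      sample(c(-1, 1), 1L)
    start <- as.integer(round(spikes$time[i] * fs)) -
      as.integer(round(0.45 * length(wv$main))) + 1L
    idx <- start:(start + length(full) - 1L)
    ok <- idx >= 1L & idx <= n_samples
    x[idx[ok]] <- x[idx[ok]] + full[ok]
    ons[i] <- (max(start, 1L) - 1L) / fs
    offs[i] <- min(start + length(full) - 1L, n_samples) / fs
  }
  list(trace = x, onset = ons, offset = offs)
}

# ---- background noise shaping ----------------------------------------------

# band-limited noise for one epoch whose *masked* band-power measurement hits
# the target (uV^2) exactly up to cross-band leakage; two fixed-point passes
.shape_noise_epoch <- function(N, fs, targets_uv2, kept = NULL) {
  X <- stats::fft(stats::rnorm(N))
  bins <- .band_bins(N, fs)
  inband <- unlist(bins)
  kmax <- floor(N / 2)
  keep_bin <- rep(FALSE, N)
  keep_bin[inband + 1L] <- TRUE
  keep_bin[N - inband + 1L] <- TRUE
  X[!keep_bin] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / N
  for (pass in 1:2) {
    meas <- .epoch_band_power(x, fs, kept, power_scale = 1)[seq_len(6)]
    fac <- sqrt(targets_uv2 / pmax(meas, 1e-12))
    for (b in seq_len(6)) {
      k <- bins[[b]]
      if (!length(k)) next
      X[k + 1L] <- X[k + 1L] * fac[b]
      X[N - k + 1L] <- X[N - k + 1L] * fac[b]
    }
    x <- Re(stats::fft(X, inverse = TRUE)) / N
  }
  x
}

# ---- activity channel -------------------------------------------------------

#' Generate the per-minute activity channel for a stage plan
#'
#' Counts are drawn from the published per-stage activity ranges
#' (0 for baseline, stages 1, 2 and HFT; 0-8 for 3A; 20-120 for 3B;
#' 20-80 for 4; 30-60 for 5); each minute uses the stage occupying most
#' of that minute.
#'
#' @param stage_plan as in [sim_config()].
#' @param margin range-shrink fraction (see [sim_config()]).
#' @param rules stage rule table.
#' @param seed optional seed (local to this call).
#' @return integer vector of counts/min (empty for an empty plan).
#' @export
make_activity_channel <- function(stage_plan, margin = 0.2, rules = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  if (is.null(rules)) rules <- stage_rule_table()
  stage_plan <- as.data.frame(stage_plan)
  if (!nrow(stage_plan)) return(integer(0))
  total <- sum(stage_plan$duration)
  n_min <- ceiling(total / 60)
  vapply(seq_len(n_min), function(m) {
    lab <- .majority_label(stage_plan, (m - 1) * 60, min(m * 60, total))
    if (lab %in% c("baseline", "1", "2", "HFT")) return(0L)
    r <- .shrink(rules[lab, "act_lo"], rules[lab, "act_hi"], margin)
    as.integer(round(stats::runif(1, r[1], r[2])))
  }, integer(1))
}

# label occupying most of [t0, t1) under the plan
.majority_label <- function(plan, t0, t1) {
  ends <- cumsum(plan$duration)
  starts <- c(0, ends[-length(ends)])
  ov <- pmax(0, pmin(ends, t1) - pmax(starts, t0))
  if (all(ov <= 0)) return(plan$label[length(ends)])
  best <- which(ov == max(ov))
  plan$label[best[length(best)]]   # ties go to the later segment
}

.segment_purity <- function(plan, t0, t1) {
  ends <- cumsum(plan$duration)
  starts <- c(0, ends[-length(ends)])
  ov <- pmax(0, pmin(ends, t1) - pmax(starts, t0))
  sum(ov > 1e-9) == 1L
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- stage segments ---------------------------------------------------------

#' Generate one stage-labeled EEG segment
#'
#' Returns a voltage trace containing spikes whose amplitude, duration and
#' within-cluster inter-spike intervals are drawn from the margin-shrunk
#' published ranges for the label, superimposed on band-limited background
#' noise whose per-10-s band powers hit values sampled from the label's
#' published power ranges. Baseline segments carry only sub-threshold
#' (< 200 uV) spikes and near-zero band power. Stage-4 spikes carry a
#' 100-140 Hz ripple burst at the peak ("paint brush" morphology).
#'
#' @param label stage label (baseline, 1, 2, HFT, 3A, 3B, 4, 5).
#' @param duration segment length (s); >= 10 s (>= 2 s for HFT).
#' @param config a [sim_config()] (its stage/artifact plan is ignored here).
#' @param seed optional seed making the call self-contained.
#' @return list with `trace` (uV), `spikes` (data.frame: time, amplitude,
#'   duration_ms, kind) and `targets` (per-epoch band-power targets, printed
#'   units).
#' @export
make_stage_segment <- function(label, duration, config = NULL, seed = NULL) {
  if (is.null(config)) {
    config <- sim_config(data.frame(label = "baseline", duration = 10))
  }
  if (!label %in% c("baseline", .STAGES)) stop("unknown label: ", label)
  plan <- data.frame(label = label, duration = duration)
  .check_segment_durations(plan)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  core <- .synthesize_core(plan, config)
  list(trace = core$trace, spikes = core$spikes[, 1:4], targets = core$targets)
}

# shared assembly: spikes + per-epoch shaped noise for a stage plan
.synthesize_core <- function(plan, config) {
  fs <- config$sampling_rate
  rules <- config$rules
  margin <- config$margin
  total <- sum(plan$duration)
  n <- as.integer(round(total * fs))
  ends <- cumsum(plan$duration)
  starts <- c(0, ends[-length(ends)])
  sp <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
    s <- .gen_segment_spikes(plan$label[i], plan$duration[i], rules, margin)
    if (nrow(s)) {
      s$time <- s$time + starts[i]
      s$label <- plan$label[i]
    } else s$label <- character(0)
    s
  }))
  rend <- .render_spikes(n, fs, sp)
  # epoch grid (includes trailing partial epoch)
  ep_starts <- (seq_len(ceiling(total / 10 - 1e-9)) - 1L) * 10
  ep_ends <- pmin(ep_starts + 10, total)
  labels <- vapply(seq_along(ep_starts), function(i)
    .majority_label(plan, ep_starts[i], ep_ends[i]), character(1))
  pure <- vapply(seq_along(ep_starts), function(i)
    .segment_purity(plan, ep_starts[i], ep_ends[i]), logical(1))
  # per-epoch band-power targets (printed units)
  targets <- t(vapply(labels, function(lab) {
    if (lab == "baseline") {
      per_band <- config$baseline_noise_sd^2 / 6 / config$power_scale
      stats::runif(6, 0.3 * per_band, per_band)
    } else {
      vapply(.BANDS$band, function(b)
        .sample_range(rules, lab, b, margin), numeric(1))
    }
  }, numeric(6)))
  dimnames(targets) <- list(NULL, .BANDS$band)
  trace <- rend$trace
  # shape the noise against the mask the analysis will use: detected event
  # extents on the spike-only trace (identical convention to detect_spikes
  # on the final recording, up to noise jitter at the extent edges)
  det <- detect_spikes(eeg_record(rend$trace, fs))
  ex_on <- det$spikes$onset
  ex_off <- det$spikes$offset
  for (i in seq_along(ep_starts)) {
    i1 <- as.integer(round(ep_starts[i] * fs)) + 1L
    i2 <- as.integer(round(ep_ends[i] * fs))
    Ne <- i2 - i1 + 1L
    if (Ne < fs) next  # ignore sub-second remnants
    sel <- ex_off > ep_starts[i] - 1 & ex_on < ep_ends[i] + 1
    kept <- .exclusion_mask(Ne, fs, ex_on[sel] - ep_starts[i],
                            ex_off[sel] - ep_starts[i])
    if (all(kept)) kept <- NULL
    noise <- .shape_noise_epoch(Ne, fs, targets[i, ] * config$power_scale,
                                kept)
    trace[i1:i2] <- trace[i1:i2] + noise
  }
  list(trace = trace, spikes = sp,
       epochs = data.frame(epoch_start = ep_starts,
                           epoch_len = ep_ends - ep_starts,
                           label = labels, pure = pure,
                           artifact = NA_character_,
                           stringsAsFactors = FALSE),
       targets = as.data.frame(targets))
}

# ---- artifacts --------------------------------------------------------------

#' Inject an artifact into a recording
#'
#' Electrical interference: brief (< 20 ms) spikes exceeding 2 mV.
#' Movement (exploratory behavior): smooth sub-delta (< 0.5 Hz) deflections
#' of 600-1200 uV with paired activity counts of 20-80/min and no change in
#' the 0.5-80 Hz power spectrum. Grooming: low-amplitude oscillations that
#' raise delta (up to 700 units), theta (up to 100) and alpha (up to 10)
#' power only, with no activity counts.
#'
#' @param record an [eeg_record].
#' @param kind one of electrical, movement, grooming.
#' @param onset,duration artifact window (s), inside the recording.
#' @param existing optional data.frame of prior artifact windows
#'   (`onset`, `duration`); overlap raises an error.
#' @param seed optional seed.
#' @return list with the modified `record` and an `artifact` row
#'   (kind, onset, duration, extent_start, extent_end).
#' @export
inject_artifact <- function(record, kind, onset, duration, existing = NULL,
                            seed = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  kind <- match.arg(kind, c("electrical", "movement", "grooming"))
  fs <- record$sampling_rate
  total <- length(record$samples) / fs
  if (onset < 0 || onset + duration > total) {
    stop("artifact window outside the recording")
  }
  if (!is.null(existing) && nrow(existing) &&
      any(onset < existing$onset + existing$duration &
          onset + duration > existing$onset)) {
    stop("artifact window overlaps an existing artifact")
  }
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  x <- record$samples
  ext <- c(onset, onset + duration)
  if (kind == "electrical") {
    n_sp <- max(1L, as.integer(round(duration * 3)))
    tt <- sort(stats::runif(n_sp, onset + 0.05, onset + duration - 0.05))
    sp <- data.frame(time = tt,
                     amplitude = stats::runif(n_sp, 2200, 4000),
                     duration_ms = stats::runif(n_sp, 6, 15),
                     kind = "electrical", stringsAsFactors = FALSE)
    rend <- .render_spikes(length(x), fs, sp)
    x <- x + rend$trace
    ext <- c(min(rend$onset), max(rend$offset))
  } else if (kind == "movement") {
    t <- (seq_along(x) - 1) / fs
    bump <- numeric(length(x))
    # bumps wide enough (sigma >= 1.1 s) that essentially all their energy
    # lies below the delta band lower edge of 0.5 Hz
    n_b <- max(1L, as.integer(round(duration / 8)))
    for (b in seq_len(n_b)) {
      ctr <- stats::runif(1, onset + duration * (b - 0.7) / n_b,
                          onset + duration * (b - 0.3) / n_b)
      sig <- stats::runif(1, 1.1, 1.5)
      amp <- stats::runif(1, 600, 1000) * sample(c(-1, 1), 1L)
      span <- abs(t - ctr) < 4 * sig
      bump[span] <- bump[span] + amp * exp(-(t[span] - ctr)^2 / (2 * sig^2))
    }
    x <- x + bump
    big <- which(abs(bump) > 300)
    if (length(big)) ext <- c((big[1] - 1) / fs, big[length(big)] / fs)
    act <- record$activity_per_min
    if (is.null(act)) act <- integer(ceiling(total / 60))
    mins <- unique(floor(c(ext[1], ext[2]) / 60)) + 1L
    mins <- mins[mins <= length(act)]
    act[mins] <- pmax(act[mins], round(stats::runif(length(mins), 20, 80)))
    record$activity_per_min <- act
  } else { # grooming
    t <- (seq_along(x) - 1) / fs
    win <- t >= onset & t < onset + duration
    tw <- t[win]
    ramp <- pmin(1, pmin(tw - onset, onset + duration - tw) / 0.5)
    comp <- function(f_lo, f_hi, p_lo, p_hi) {
      f <- stats::runif(1, f_lo, f_hi)
      a <- sqrt(2 * stats::runif(1, p_lo, p_hi) * .POWER_SCALE)
      a * sin(2 * pi * f * tw + stats::runif(1, 0, 2 * pi))
    }
    osc <- comp(1.2, 3.2, 100, 600) + comp(4.5, 7.5, 25, 90) +
      comp(8.5, 11, 6, 9.5)
    x[win] <- x[win] + osc * ramp
  }
  record$samples <- x
  list(record = record,
       artifact = data.frame(kind = kind, onset = onset, duration = duration,
                             extent_start = ext[1], extent_end = ext[2],
                             stringsAsFactors = FALSE))
}

# ---- full recording ---------------------------------------------------------

#' Synthesize a ground-truth-labeled recording
#'
#' Assembles the stage plan into a continuous trace (spikes + per-epoch
#' shaped background noise), injects planned artifacts, and generates the
#' activity channel. Deterministic for a given config (seed included).
#'
#' @param config a [sim_config()].
#' @return list of class `synth_recording`: `record` ([eeg_record]) and
#'   `truth` with `spikes` (time, amplitude, duration_ms, kind, label),
#'   `epochs` (epoch_start, epoch_len, label, pure, artifact), `targets`
#'   (per-epoch band-power targets, printed units), `artifacts`,
#'   `activity_per_min`, and the `config`.
#' @export
synthesize_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  fs <- config$sampling_rate
  core <- .synthesize_core(config$stage_plan, config)
  activity <- make_activity_channel(config$stage_plan, config$margin,
                                    config$rules)
  rec <- eeg_record(core$trace, fs, activity)
  epochs <- core$epochs
  artifacts <- NULL
  ap <- config$artifact_plan
  if (!is.null(ap) && nrow(ap)) {
    done <- ap[0, c("onset", "duration")]
    for (i in seq_len(nrow(ap))) {
      res <- inject_artifact(rec, ap$kind[i], ap$onset[i], ap$duration[i],
                             existing = done)
      rec <- res$record
      artifacts <- rbind(artifacts, res$artifact)
      done <- rbind(done, ap[i, c("onset", "duration")])
    }
    # ground-truth artifact epochs: any electrical spike, or >= 50% / >= 2 s
    # overlap with the artifact's supra-threshold extent
    for (j in seq_len(nrow(artifacts))) {
      a <- artifacts[j, ]
      ov <- pmax(0, pmin(epochs$epoch_start + epochs$epoch_len,
                         a$extent_end) -
                   pmax(epochs$epoch_start, a$extent_start))
      hit <- switch(a$kind,
                    electrical = ov > 1e-9,
                    movement   = ov >= 2 - 1e-9,
                    grooming   = ov >= 0.5 * epochs$epoch_len)
      epochs$artifact[hit] <- a$kind
    }
  }
  structure(list(
    record = rec,
    truth = list(spikes = core$spikes, epochs = epochs,
                 targets = core$targets, artifacts = artifacts,
                 activity_per_min = activity, config = config)),
    class = "synth_recording")
}
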