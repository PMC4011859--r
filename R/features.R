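#' Construct an EEG record
#'
#' A uniformly sampled single-channel voltage trace (uV) with an optional
#' per-minute telemetry activity channel.
#'
#' @param samples numeric vector of voltages (uV); must be finite.
#' @param sampling_rate sampling rate in Hz.
#' @param activity_per_min optional integer vector of activity counts, one
#'   per minute of recording.
#' @param start_time recording start offset in seconds (default 0).
#' @return object of class `eeg_record`.
#' @export
eeg_record <- function(samples, sampling_rate, activity_per_min = NULL,
                       start_time = 0) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar (Hz)")
  }
  if (!is.null(activity_per_min)) {
    activity_per_min <- as.numeric(activity_per_min)
    if (any(activity_per_min < 0)) stop("activity counts must be >= 0")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 activity_per_min = activity_per_min,
                 start_time = start_time),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              if (is.null(x$activity_per_min)) "" else
                sprintf(", %d min activity", length(x$activity_per_min))))
  invisible(x)
}

.odd <- function(k) if (k %% 2L == 0L) k + 1L else k

# robust slow baseline: running median; window short enough to pass spikes
# (<= 0.5 s occupancy) through as deflections
.running_baseline <- function(x, fs, win_s) {
  k <- .odd(as.integer(round(fs * win_s)))
  if (k >= length(x)) k <- .odd(max(3L, as.integer(length(x) / 3)))
  if (k < 3L) return(rep(0, length(x)))
  stats::runmed(x, k, endrule = "median")
}

#' Detect epileptiform spikes
#'
#' Threshold-based event detection on the deflection from a running-median
#' baseline. An event is a contiguous run of samples whose absolute
#' deflection exceeds `threshold / 2` and that contains at least one sample
#' above `threshold`; events closer than `min_separation_ms` are merged.
#' Amplitude is the peak deflection from baseline, duration the width
#' between the (linearly interpolated) crossings of `threshold`, and an
#' event is flagged complex when it carries two or more sub-peaks above
#' half its amplitude.
#'
#' @param record an [eeg_record].
#' @param threshold detection threshold in uV above the local baseline.
#'   Default 200 uV, the published upper bound of baseline (non-epileptiform)
#'   spike amplitude.
#' @param min_separation_ms minimum separation between distinct events (ms);
#'   must be at least two sample periods.
#' @param max_duration_ms events whose half-threshold extent exceeds this are
#'   rejected as slow deflections, not spikes (published spike durations are
#'   all below 500 ms; see [detect_slow_deflections()]).
#' @param baseline_win_s running-median window (s) for the local baseline.
#' @return object of class `spike_train`: a list with `spikes`
#'   (data.frame: peak_time, amplitude, duration_ms, complex, onset, offset),
#'   `isis` (ms), `rate_per_min`, `duration_s`, `sampling_rate`.
#' @export
detect_spikes <- function(record, threshold = 200, min_separation_ms = 8,
                          max_duration_ms = 600, baseline_win_s = 4) {
  stopifnot(inherits(record, "eeg_record"))
  x <- record$samples
  fs <- record$sampling_rate
  if (length(x) == 0L) stop("empty record")
  if (threshold <= 0) stop("threshold must be > 0")
  min_sep <- max(2L, as.integer(round(min_separation_ms / 1000 * fs)))
  if (min_separation_ms < 2000 / fs) {
    stop("min_separation must be at least two sample periods")
  }
  a <- abs(x - .running_baseline(x, fs, baseline_win_s))
  empty <- data.frame(peak_time = numeric(0), amplitude = numeric(0),
                      duration_ms = numeric(0), complex = logical(0),
                      onset = numeric(0), offset = numeric(0))
  half <- a >= threshold / 2
  if (!any(half)) {
    return(.spike_train(empty, length(x) / fs, fs))
  }
  r <- rle(half)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by < min_sep samples
  if (nrow(ev) > 1L) {
    keep <- list()
    cur <- ev[1, ]
    for (i in 2:nrow(ev)) {
      if (ev[i, 1] - cur[2] - 1L < min_sep) cur[2] <- ev[i, 2]
      else { keep[[length(keep) + 1L]] <- cur; cur <- ev[i, ] }
    }
    keep[[length(keep) + 1L]] <- cur
    ev <- do.call(rbind, keep)
  }
  # keep only events reaching the full threshold and narrower than the
  # slow-deflection bound
  full <- apply(ev, 1L, function(e) any(a[e[1]:e[2]] >= threshold))
  narrow <- (ev[, 2] - ev[, 1] + 1L) / fs * 1000 <= max_duration_ms
  ev <- ev[full & narrow, , drop = FALSE]
  if (nrow(ev) == 0L) return(.spike_train(empty, length(x) / fs, fs))

  out <- lapply(seq_len(nrow(ev)), function(i) {
    i1 <- ev[i, 1]; i2 <- ev[i, 2]
    seg <- a[i1:i2]
    pk <- which.max(seg)
    amp <- seg[pk]
    # interpolated full-threshold crossing times
    up <- which(seg >= threshold)
    j1 <- up[1]; j2 <- up[length(up)]
    t_on <- i1 + j1 - 2L +
      if (j1 > 1L) (threshold - seg[j1 - 1L]) / (seg[j1] - seg[j1 - 1L]) else 0
    t_off <- i1 + j2 - 1L +
      if (j2 < length(seg))
        (seg[j2] - threshold) / (seg[j2] - seg[j2 + 1L]) else 0
    data.frame(peak_time = (i1 + pk - 2) / fs,
               amplitude = amp,
               duration_ms = max(t_off - t_on, 1) / fs * 1000,
               complex = .is_complex(seg, amp),
               onset = (i1 - 1) / fs,
               offset = (i2 - 1) / fs)
  })
  .spike_train(do.call(rbind, out), length(x) / fs, fs)
}

# >= 2 sub-peaks above half amplitude separated by dips of >= 0.15 amp
.is_complex <- function(seg, amp) {
  n <- length(seg)
  if (n < 5L) return(FALSE)
  pk <- which(diff(sign(diff(seg))) < 0) + 1L
  pk <- pk[seg[pk] >= 0.5 * amp]
  if (length(pk) < 2L) return(FALSE)
  cnt <- 1L
  last <- pk[1]
  for (p in pk[-1]) {
    if (min(seg[last:p]) <= max(seg[last], seg[p]) - 0.15 * amp) {
      cnt <- cnt + 1L
      last <- p
    } else if (seg[p] > seg[last]) last <- p
  }
  cnt >= 2L
}

.spike_train <- function(spikes, duration_s, fs) {
  isis <- if (nrow(spikes) > 1L) diff(spikes$peak_time) * 1000 else numeric(0)
  structure(list(spikes = spikes, isis = isis,
                 rate_per_min = nrow(spikes) / duration_s * 60,
                 duration_s = duration_s, sampling_rate = fs),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.1f s (%.1f /min)\n",
              nrow(x$spikes), x$duration_s, x$rate_per_min))
  invisible(x)
}

#' Spike rate over consecutive windows
#'
#' @param train a [spike_train].
#' @param window window length in seconds (> 0).
#' @return data.frame with `window_start` (s) and `rate_per_min`.
#' @export
spike_rate <- function(train, window = 60) {
  stopifnot(inherits(train, "spike_train"))
  if (window <= 0) stop("window must be > 0")
  starts <- (seq_len(max(1, ceiling(train$duration_s / window - 1e-9))) - 1) *
    window
  counts <- vapply(starts, function(s)
    sum(train$spikes$peak_time >= s & train$spikes$peak_time < s + window),
    numeric(1))
  data.frame(window_start = starts, rate_per_min = counts * 60 / window)
}

# frequency-bin indices per band for an N-sample epoch at fs Hz.
# bin k corresponds to k * fs / N Hz, k = 1 .. floor(N/2).
.band_bins <- function(N, fs) {
  df <- fs / N
  kmax <- floor(N / 2)
  lapply(seq_len(nrow(.BANDS)), function(i) {
    lo <- .BANDS$lo[i]; hi <- .BANDS$hi[i]
    k1 <- if (i == 1L) ceiling(lo / df - 1e-9) else floor(lo / df + 1e-9) + 1L
    k2 <- floor(hi / df + 1e-9)
    k2 <- min(k2, kmax)
    if (k1 > k2) integer(0) else seq.int(k1, k2)
  })
}

# one-sided periodogram bin powers (mean-square units): bin k gets
# 2|X_k|^2/N^2 (Nyquist bin not doubled); sum over all bins + DC = mean(x^2)
.fft_bin_power <- function(x) {
  N <- length(x)
  X <- stats::fft(x)
  kmax <- floor(N / 2)
  p <- 2 * Mod(X[2:(kmax + 1L)])^2 / N^2
  if (N %% 2L == 0L) p[kmax] <- p[kmax] / 2
  p
}

# Lomb-Scargle power at the epoch's Fourier frequencies from a subset of
# samples; normalized against the full grid length N so that the estimate
# is insensitive to the gap fraction (and equals .fft_bin_power when
# gapless).
.lomb_bin_power <- function(t, y, freqs, N, chunk = 160L) {
  n <- length(t)
  y <- y - mean(y)
  out <- numeric(length(freqs))
  for (off in seq(1L, length(freqs), by = chunk)) {
    idx <- off:min(off + chunk - 1L, length(freqs))
    W <- outer(t, 2 * pi * freqs[idx])
    C <- cos(W); S <- sin(W)
    c2 <- colSums(C * C - S * S)
    s2 <- 2 * colSums(C * S)
    R <- sqrt(c2^2 + s2^2)
    th <- 0.5 * atan2(s2, c2)
    ct <- cos(th); st <- sin(th)
    cwt <- colSums(y * C); swt <- colSums(y * S)
    num1 <- (cwt * ct + swt * st)^2
    num2 <- (swt * ct - cwt * st)^2
    d1 <- pmax(0.5 * (n + R), 1e-12)
    d2 <- pmax(0.5 * (n - R), 1e-12)
    out[idx] <- 0.5 * (num1 / d1 + num2 / d2)
  }
  2 * out / N
}

# per-epoch band powers (printed units); kept_mask NULL means all samples
.epoch_band_power <- function(xs, fs, kept = NULL, power_scale = .POWER_SCALE) {
  N <- length(xs)
  bins <- .band_bins(N, fs)
  if (is.null(kept) || all(kept)) {
    p <- .fft_bin_power(xs)
    bp <- vapply(bins, function(b) sum(p[b]), numeric(1))
    total <- mean(xs^2)
  } else {
    t <- (which(kept) - 1L) / fs
    y <- xs[kept]
    allk <- sort(unique(unlist(bins)))
    freqs <- allk * fs / N
    pw <- .lomb_bin_power(t, y, freqs, N)
    names(pw) <- as.character(allk)
    bp <- vapply(bins, function(b) sum(pw[as.character(b)]), numeric(1))
    total <- mean(y^2)
  }
  c(bp, total) / power_scale
}

# exclusion mask for one epoch from detected events (times in s relative to
# epoch start); events are widened to cover shoulders and after-waves
.exclusion_mask <- function(N, fs, onset, offset) {
  kept <- rep(TRUE, N)
  if (length(onset)) {
    w <- pmax(offset - onset, 0.02)
    a <- pmax(1L, as.integer(floor((onset - 0.02) * fs)) + 1L)
    b <- pmin(N, as.integer(ceiling((offset + 0.5 * w + 0.02) * fs)) + 1L)
    for (i in seq_along(a)) if (a[i] <= b[i]) kept[a[i]:b[i]] <- FALSE
  }
  kept
}

#' Per-epoch band powers
#'
#' Splits the record into consecutive `epoch_length`-second epochs (trailing
#' partial epoch discarded) and integrates the one-sided periodogram over
#' the six bands of [band_definitions()]. Powers are reported in the printed
#' power unit (`power_scale` uV^2 of band integral per unit). When a spike
#' train is supplied via `exclude`, detected events (widened to cover their
#' shoulders and after-waves) are excised and the remaining samples are
#' analyzed with a Lomb-Scargle periodogram on the same frequency grid, so
#' band powers describe the ongoing background activity rather than spike
#' energy; with no exclusions the estimate is the exact FFT periodogram.
#'
#' @param record an [eeg_record].
#' @param epoch_length epoch length in seconds (default 10).
#' @param exclude optional [spike_train] whose events are excised.
#' @param exclude_slow optional data.frame from
#'   [detect_slow_deflections()]; slow deflections are excised with a 2.5-s
#'   margin (their sub-threshold flanks still carry slow energy that would
#'   otherwise leak into delta).
#' @param detrend subtract a 20-s running-median baseline (slow drift only)
#'   before analysis; default FALSE so short test signals are analyzed
#'   verbatim.
#' @param power_scale uV^2 per printed power unit.
#' @return data.frame: `epoch_start`, `delta` ... `gamma`, `total`
#'   (all-frequency mean-square power in the same unit), `kept_frac`.
#'   If the sampling rate is below 160 Hz the gamma band cannot be resolved
#'   and the `gamma` column is NA (with a warning).
#' @export
band_power <- function(record, epoch_length = 10, exclude = NULL,
                       exclude_slow = NULL, detrend = FALSE,
                       power_scale = .POWER_SCALE) {
  stopifnot(inherits(record, "eeg_record"))
  x <- record$samples
  fs <- record$sampling_rate
  Ne <- as.integer(round(fs * epoch_length))
  if (length(x) < Ne) stop("record shorter than one epoch")
  gamma_ok <- fs >= 2 * .BANDS$hi[.BANDS$band == "gamma"]
  if (!gamma_ok) warning("sampling rate < 160 Hz: gamma band not resolvable; ",
                         "reporting NA")
  if (detrend) x <- x - .running_baseline(x, fs, 20)
  n_ep <- floor(length(x) / Ne)
  ons <- numeric(0); offs <- numeric(0)
  if (!is.null(exclude)) {
    stopifnot(inherits(exclude, "spike_train"))
    ons <- exclude$spikes$onset; offs <- exclude$spikes$offset
  }
  s_ons <- numeric(0); s_offs <- numeric(0)
  if (!is.null(exclude_slow) && nrow(exclude_slow)) {
    s_ons <- exclude_slow$onset - 2.5
    s_offs <- exclude_slow$offset + 2.5
  }
  rows <- lapply(seq_len(n_ep), function(i) {
    t0 <- (i - 1L) * epoch_length
    xs <- x[((i - 1L) * Ne + 1L):(i * Ne)]
    sel <- offs > t0 - 1 & ons < t0 + epoch_length + 1
    kept <- .exclusion_mask(Ne, fs, ons[sel] - t0, offs[sel] - t0)
    ssel <- s_offs > t0 & s_ons < t0 + epoch_length
    if (any(ssel)) {
      a <- pmax(1L, as.integer(floor((s_ons[ssel] - t0) * fs)) + 1L)
      b <- pmin(Ne, as.integer(ceiling((s_offs[ssel] - t0) * fs)) + 1L)
      for (j in seq_along(a)) if (a[j] <= b[j]) kept[a[j]:b[j]] <- FALSE
    }
    if (mean(kept) < 0.3) {
      bp <- rep(NA_real_, 7)
    } else {
      bp <- .epoch_band_power(xs, fs, kept, power_scale)
    }
    data.frame(epoch_start = t0, delta = bp[1], theta = bp[2], alpha = bp[3],
               sigma = bp[4], beta = bp[5],
               gamma = if (gamma_ok) bp[6] else NA_real_,
               total = bp[7], kept_frac = mean(kept))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-epoch feature table
#'
#' Combines [band_power()] with per-epoch spike summaries and the activity
#' channel: spike count, mean amplitude (uV), mean duration (ms), median
#' inter-spike interval (ms; robust to between-cluster gaps), spike rate
#' (/min) and activity (counts/min, taken from the minute containing the
#' epoch start).
#'
#' @inheritParams band_power
#' @param train [spike_train] from [detect_spikes()]; also used as the
#'   band-power exclusion set.
#' @param slow_events optional [detect_slow_deflections()] output, excised
#'   from the spectral estimate.
#' @return data.frame of epoch features.
#' @export
epoch_features <- function(record, train, epoch_length = 10,
                           slow_events = NULL, detrend = FALSE,
                           power_scale = .POWER_SCALE) {
  bp <- band_power(record, epoch_length, exclude = train,
                   exclude_slow = slow_events,
                   detrend = detrend, power_scale = power_scale)
  sp <- train$spikes
  act <- record$activity_per_min
  feats <- lapply(bp$epoch_start, function(t0) {
    in_ep <- sp$peak_time >= t0 & sp$peak_time < t0 + epoch_length
    s <- sp[in_ep, , drop = FALSE]
    isis <- if (nrow(s) > 1L) diff(s$peak_time) * 1000 else numeric(0)
    minute <- floor(t0 / 60) + 1L
    data.frame(
      spike_count = nrow(s),
      mean_amplitude = if (nrow(s)) mean(s$amplitude) else NA_real_,
      mean_duration = if (nrow(s)) mean(s$duration_ms) else NA_real_,
      mean_isi = if (length(isis)) stats::median(isis) else NA_real_,
      rate = nrow(s) * 60 / epoch_length,
      activity = if (!is.null(act) && minute <= length(act))
        act[minute] else 0)
  })
  cbind(bp, do.call(rbind, feats))
}
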