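# Minimal EDF (European Data Format) reader/writer: fixed 256-byte ASCII
# header + per-signal headers + 16-bit little-endian data records. Record
# duration is 10 s (one analysis epoch); the activity channel is stored as
# a second signal at 1 sample per record (0.1 Hz, each minute's count
# repeated). Recordings are zero-padded to a whole number of records.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.EDF_EEG_RANGE <- c(-8000, 8000)    # uV
.EDF_ACT_RANGE <- c(0, 1000)        # counts/min

#' Write a recording to EDF
#'
#' Writes the EEG trace (uV) and, when present, the activity channel as a
#' second 0.1 Hz signal. Samples are quantized to the 16-bit EDF digital
#' range over +/- 8000 uV (activity 0-1000 counts).
#'
#' @param record an [eeg_record].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$sampling_rate
  spr <- as.integer(round(fs * 10))
  if (abs(spr - fs * 10) > 1e-6) {
    stop("sampling rate must give an integer number of samples per 10 s")
  }
  x <- record$samples
  n_rec <- as.integer(ceiling(length(x) / spr))
  x <- c(x, numeric(n_rec * spr - length(x)))
  act <- record$activity_per_min
  has_act <- !is.null(act)
  ns <- if (has_act) 2L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X X X X", 80), .edf_pad("Startdate X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad("10", 8), .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- function(field, width) {
    for (s in field) writeChar(.edf_pad(s, width), con, eos = NULL)
  }
  labels <- c("EEG", if (has_act) "Activity")
  dims <- c("uV", if (has_act) "counts")
  pmin_ <- c(.EDF_EEG_RANGE[1], if (has_act) .EDF_ACT_RANGE[1])
  pmax_ <- c(.EDF_EEG_RANGE[2], if (has_act) .EDF_ACT_RANGE[2])
  sprs <- c(spr, if (has_act) 1L)
  sig(labels, 16); sig(rep("", ns), 80); sig(dims, 8)
  sig(pmin_, 8); sig(pmax_, 8)
  sig(rep(-32768L, ns), 8); sig(rep(32767L, ns), 8)
  sig(rep("", ns), 80); sig(sprs, 8); sig(rep("", ns), 32)
  to_dig <- function(v, pr) {
    v <- pmin(pmax(v, pr[1]), pr[2])
    as.integer(round((v - pr[1]) / (pr[2] - pr[1]) * 65535 - 32768))
  }
  for (r in seq_len(n_rec)) {
    seg <- x[((r - 1L) * spr + 1L):(r * spr)]
    writeBin(to_dig(seg, .EDF_EEG_RANGE), con, size = 2L,
             endian = "little")
    if (has_act) {
      minute <- floor((r - 1L) * 10 / 60) + 1L
      a <- if (minute <= length(act)) act[minute] else 0
      writeBin(to_dig(a, .EDF_ACT_RANGE), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads the first EEG signal (physical dimension uV) and, when present, an
#' activity signal (reconstructed to counts/min).
#'
#' @param path EDF file path.
#' @return an [eeg_record].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF: bad signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  sprs <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (any(is.na(sprs)) || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    stop("malformed EDF header")
  }
  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- numeric(n_rec * sprs[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, integer(), n = sprs[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (raw - dmin_[i]) / (dmax_[i] - dmin_[i]) *
        (pmax_[i] - pmin_[i]) + pmin_[i]
      data[[i]][((r - 1L) * sprs[i] + 1L):(r * sprs[i])] <- phys
    }
  }
  eeg_i <- which(tolower(dims) %in% c("uv", "µv"))[1]
  if (is.na(eeg_i)) eeg_i <- 1L
  fs <- sprs[eeg_i] / rec_dur
  act_i <- which(grepl("activ", tolower(labels)))[1]
  act <- NULL
  if (!is.na(act_i)) {
    a <- data[[act_i]]
    per_min <- max(1L, as.integer(round(60 / rec_dur * sprs[act_i])))
    idx <- seq(1L, length(a), by = per_min)
    act <- round(a[idx])
  }
  eeg_record(data[[eeg_i]], fs, act)
}

#' Read a recording from EDF or CSV
#'
#' CSV input must have columns `time_s` and `uv` and requires an explicit
#' `sampling_rate` (never silently inferred).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param sampling_rate required for CSV input (Hz).
#' @return an [eeg_record].
#' @export
read_record <- function(path, format = c("auto", "edf", "csv"),
                        sampling_rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") return(read_edf(path))
  if (is.null(sampling_rate)) {
    stop("CSV input requires an explicit sampling_rate (Hz)")
  }
  d <- utils::read.csv(path)
  if (!all(c("time_s", "uv") %in% names(d))) {
    stop("CSV must have columns time_s and uv")
  }
  eeg_record(d$uv, sampling_rate, start_time = d$time_s[1])
}

#' Write a recording to CSV
#'
#' @param record an [eeg_record].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  t <- (seq_along(record$samples) - 1) / record$sampling_rate
  utils::write.csv(data.frame(time_s = t, uv = record$samples), path,
                   row.names = FALSE)
  invisible(path)
}
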