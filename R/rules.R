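#' @keywords internal
"_PACKAGE"

# Frequency band edges (Hz). A frequency bin falling on a shared edge belongs
# to the lower band, so bands are (lo, hi] except delta which includes 0.5.
.BANDS <- data.frame(
  band = c("delta", "theta", "alpha", "sigma", "beta", "gamma"),
  lo   = c(0.5, 4, 8, 12, 16, 24),
  hi   = c(4, 8, 12, 16, 24, 80),
  stringsAsFactors = FALSE
)

.STAGES  <- c("1", "2", "HFT", "3A", "3B", "4", "5")
# ordinal order used for tie-breaks and median smoothing
.STAGE_ORDER <- c(baseline = 0L, `1` = 1L, `2` = 2L, HFT = 3L,
                  `3A` = 4L, `3B` = 5L, `4` = 6L, `5` = 7L)

# epoch band power (printed units) below which a band is "at baseline"
.BASELINE_POWER_BOUND <- 5
# spike amplitude (uV) below which a deflection is a baseline spike
.BASELINE_AMP <- 200
# periodogram uV^2 per printed power unit (acquisition-gain calibration;
# see the methods vignette for why the printed unit cannot be a literal mV^2)
.POWER_SCALE <- 10

#' Frequency band definitions
#'
#' The six power bands used throughout the package: delta (0.5-4 Hz),
#' theta (4-8), alpha (8-12), sigma (12-16), beta (16-24), gamma (24-80).
#'
#' @return data.frame with columns `band`, `lo`, `hi` (Hz).
#' @export
band_definitions <- function() .BANDS

#' Load the stage rule table
#'
#' Reads the versioned rule table mapping each seizure stage label
#' (1, 2, HFT, 3A, 3B, 4, 5) to its published feature ranges: spike
#' amplitude (uV), spike duration (ms), inter-spike interval (ms),
#' spike rate (/min), the six band powers (printed power units per 10-s
#' epoch) and activity (counts/min).
#'
#' @param path path to a rule CSV; defaults to the table shipped with the
#'   package.
#' @return data.frame of class `stage_rules`, one row per stage.
#' @export
stage_rule_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stage_rules.csv", package = "seizstage")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("stage rule table not found: ", path)
  }
  rules <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("stage",
              as.vector(t(outer(c("amp", "dur", "isi", "rate",
                                  .BANDS$band, "act"),
                                c("lo", "hi"), paste, sep = "_"))))
  miss <- setdiff(needed, names(rules))
  if (length(miss)) stop("rule table missing columns: ",
                         paste(miss, collapse = ", "))
  rules$stage <- as.character(rules$stage)
  if (!setequal(rules$stage, .STAGES)) {
    stop("rule table must contain exactly the stages ",
         paste(.STAGES, collapse = ", "))
  }
  lo <- rules[, grep("_lo$", names(rules))]
  hi <- rules[, grep("_hi$", names(rules))]
  if (any(as.matrix(lo) > as.matrix(hi))) {
    stop("rule table has a range with low > high")
  }
  rownames(rules) <- rules$stage
  class(rules) <- c("stage_rules", "data.frame")
  rules
}

# shrink [lo, hi] toward its midpoint by `margin` of the width on each side
.shrink <- function(lo, hi, margin) {
  w <- hi - lo
  c(lo + margin * w, hi - margin * w)
}

# sample uniformly from the margin-shrunk range of a rule-table cell
.sample_range <- function(rules, stage, feature, margin, n = 1L) {
  lo <- rules[stage, paste0(feature, "_lo")]
  hi <- rules[stage, paste0(feature, "_hi")]
  r <- .shrink(lo, hi, margin)
  stats::runif(n, r[1], r[2])
}

.rule_range <- function(rules, stage, feature) {
  c(rules[stage, paste0(feature, "_lo")], rules[stage, paste0(feature, "_hi")])
}
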