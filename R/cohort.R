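#' Outcome model for cohort simulation
#'
#' Stochastic outcome layer calibrated to the published cohort frequencies.
#' RLD animals receive 5 mg/kg doses at 30-min intervals until stage-5
#' onset or `max_doses`; the per-dose stage-5 hazard defaults to a fit in
#' which ~76% of animals reach stage 5 by 25 mg/kg (dose 5), ~95% by
#' 35 mg/kg and 96% overall, with stage 5 reachable from dose 3 (15 mg/kg)
#' on. SHD animals receive a single 20 mg/kg dose and reach stage 5 with
#' probability `shd_p_stage5` (default 0.65, the printed percentage) and
#' stage 3 with probability `shd_p_stage3` (22/24). Death is sampled only
#' among animals that reached stage-5 seizures (all published deaths
#' occurred during SE after reaching stage 5).
#'
#' @param rld_hazard per-dose stage-5 hazard, length `max_doses`.
#' @param rld_death_given_s5 death probability given stage 5, RLD (5/79).
#' @param shd_death_given_s5 death probability given stage 5, SHD (5/16).
#' @param shd_p_stage5,shd_p_stage3 SHD attainment probabilities.
#' @param rld_p_stage3_given_no5 stage-3 attainment among RLD non-attainers
#'   of stage 5 (2/3: 81 of 82 reached stage 3, 79 reached stage 5).
#' @param pre_se_death probability of death before SE (default 0).
#' @param max_doses RLD dose cap (11 doses = 55 mg/kg).
#' @param f_cms expected fraction of the 2-h SE window spent at CMS
#'   (stage >= 3) per protocol.
#' @return list of class `outcome_model`.
#' @export
outcome_model <- function(rld_hazard = NULL,
                          rld_death_given_s5 = 5 / 79,
                          shd_death_given_s5 = 5 / 16,
                          shd_p_stage5 = 0.65,
                          shd_p_stage3 = 22 / 24,
                          rld_p_stage3_given_no5 = 2 / 3,
                          pre_se_death = 0,
                          max_doses = 11L,
                          f_cms = c(RLD = 0.55, SHD = 0.21)) {
  if (is.null(rld_hazard)) {
    # piecewise-constant hazard: cumulative attainment 0.76 by dose 5,
    # 0.95 by dose 7, 0.96 by dose 11
    h35 <- 1 - 0.24^(1 / 3)
    h67 <- 1 - (0.05 / 0.24)^(1 / 2)
    h811 <- 1 - (0.04 / 0.05)^(1 / 4)
    rld_hazard <- c(0, 0, rep(h35, 3), rep(h67, 2), rep(h811, 4))
  }
  stopifnot(length(rld_hazard) == max_doses,
            all(rld_hazard >= 0 & rld_hazard <= 1),
            shd_p_stage5 <= shd_p_stage3)
  structure(list(rld_hazard = rld_hazard,
                 rld_death_given_s5 = rld_death_given_s5,
                 shd_death_given_s5 = shd_death_given_s5,
                 shd_p_stage5 = shd_p_stage5, shd_p_stage3 = shd_p_stage3,
                 rld_p_stage3_given_no5 = rld_p_stage3_given_no5,
                 pre_se_death = pre_se_death, max_doses = max_doses,
                 f_cms = f_cms),
            class = "outcome_model")
}

# per-5-min-epoch stage sampling for the SE window
.sample_se_stages <- function(p_cms, protocol) {
  n_ep <- 24L
  cms <- stats::runif(n_ep) < p_cms
  st <- integer(n_ep)
  st[cms] <- sample(3:5, sum(cms), replace = TRUE, prob = c(0.4, 0.2, 0.4))
  st[!cms] <- sample(1:2, sum(!cms), replace = TRUE)
  st
}

#' Simulate one animal
#'
#' @param protocol `"RLD"` or `"SHD"`.
#' @param model an [outcome_model()].
#' @param diary build the full 5-min-resolution [seizure_diary()] (TRUE) or
#'   only outcome flags (FALSE; much faster for calibration sweeps).
#' @return list of class `animal_record`: `animal_id`, `protocol`, `doses`
#'   (data.frame time_min, mg_per_kg), `total_dose`, `reached_stage3`,
#'   `reached_stage5`, `died`, `diary` (or NULL).
#' @export
simulate_animal <- function(protocol, model = outcome_model(), diary = TRUE) {
  protocol <- match.arg(protocol, c("RLD", "SHD"))
  died <- FALSE
  onset_min <- NA_real_
  if (protocol == "RLD") {
    k_onset <- NA_integer_
    for (k in seq_len(model$max_doses)) {
      if (stats::runif(1) < model$rld_hazard[k]) { k_onset <- k; break }
    }
    n_doses <- if (is.na(k_onset)) model$max_doses else k_onset
    doses <- data.frame(time_min = 30 * (seq_len(n_doses) - 1),
                        mg_per_kg = 5)
    reached5 <- !is.na(k_onset)
    reached3 <- reached5 || stats::runif(1) < model$rld_p_stage3_given_no5
    if (reached5) {
      onset_min <- 30 * (k_onset - 1) + stats::runif(1, 5, 25)
      died <- stats::runif(1) < model$rld_death_given_s5
    }
  } else {
    doses <- data.frame(time_min = 0, mg_per_kg = 20)
    u <- stats::runif(1)
    reached5 <- u < model$shd_p_stage5
    reached3 <- u < model$shd_p_stage3
    if (reached3) onset_min <- stats::runif(1, 10, 30)
    if (reached5) died <- stats::runif(1) < model$shd_death_given_s5
  }
  d <- NULL
  se_index <- if (protocol == "RLD") reached5 else reached3
  if (diary) {
    iv <- NULL
    if (se_index) {
      onset_s <- onset_min * 60
      st <- .sample_se_stages(model$f_cms[[protocol]], protocol)
      # the index seizure opens the window
      st[1] <- if (protocol == "RLD") 5L else max(st[1], 3L)
      if (reached5 && !any(st == 5L)) st[sample.int(24L, 1L)] <- 5L
      iv <- data.frame(start = onset_s + 300 * (0:23),
                       end = onset_s + 300 * (1:24), stage = st)
      # pre-onset ramp of non-convulsive seizures
      if (onset_s >= 600) {
        iv <- rbind(data.frame(start = c(onset_s / 3, 2 * onset_s / 3),
                               end = c(2 * onset_s / 3, onset_s),
                               stage = c(1L, 2L)), iv)
      }
    } else if (reached3) {
      iv <- data.frame(start = c(600, 1200), end = c(1200, 1500),
                       stage = c(2L, 3L))
    }
    if (is.null(iv)) iv <- data.frame(start = numeric(0), end = numeric(0),
                                      stage = integer(0))
    death_time <- if (died && se_index)
      onset_min * 60 + stats::runif(1, 900, 6900) else NA_real_
    dz <- if (se_index) onset_min * 60 + 7200 else NA_real_
    if (died && !is.na(death_time)) iv <- iv[iv$start < death_time, ]
    if (nrow(iv) && !is.na(death_time)) {
      iv$end <- pmin(iv$end, death_time)
      iv <- iv[iv$end > iv$start, ]
    }
    d <- seizure_diary(paste0(protocol, "-sim"), protocol, iv,
                       diazepam_time = dz, death_time = death_time)
  }
  structure(list(animal_id = NA_character_, protocol = protocol,
                 doses = doses, total_dose = sum(doses$mg_per_kg),
                 reached_stage3 = reached3, reached_stage5 = reached5,
                 died = died, diary = d),
            class = "animal_record")
}

#' Simulate a cohort
#'
#' @param n number of animals.
#' @param protocol `"RLD"` or `"SHD"`.
#' @inheritParams simulate_animal
#' @return list of `animal_record`s (class `cohort`).
#' @export
simulate_cohort <- function(n, protocol, model = outcome_model(),
                            diary = TRUE) {
  recs <- lapply(seq_len(n), function(i) {
    a <- simulate_animal(protocol, model, diary)
    a$animal_id <- sprintf("%s-%03d", protocol, i)
    a
  })
  structure(recs, class = "cohort")
}

#' Build a cohort from printed outcome counts
#'
#' Constructs the minimal animal records corresponding to a published
#' contingency: `n` animals of which `deaths` died, `stage5` reached stage
#' 5 and `stage3` reached stage 3 (deaths are assigned among stage-5
#' animals, as in the published cohorts).
#'
#' @param n,deaths,stage5,stage3 integer counts.
#' @param protocol protocol label.
#' @return a `cohort`.
#' @export
cohort_from_counts <- function(n, deaths, stage5, stage3 = stage5,
                               protocol = "RLD") {
  stopifnot(deaths <= stage5, stage5 <= stage3, stage3 <= n)
  recs <- lapply(seq_len(n), function(i) {
    structure(list(animal_id = sprintf("%s-%03d", protocol, i),
                   protocol = protocol, doses = NULL, total_dose = NA_real_,
                   reached_stage3 = i <= stage3, reached_stage5 = i <= stage5,
                   died = i <= deaths, diary = NULL),
              class = "animal_record")
  })
  structure(recs, class = "cohort")
}

.round_half_up <- function(x) floor(x + 0.5)

#' Summarize a cohort
#'
#' Counts, integer-rounded percentages (as printed), raw fractions, and —
#' when diaries are present — mean time in CMS and in stage 5 over the SE
#' window.
#'
#' @param records a `cohort`.
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(records) {
  n <- length(records)
  if (n < 1L) stop("empty cohort")
  deaths <- sum(vapply(records, `[[`, logical(1), "died"))
  s5 <- sum(vapply(records, `[[`, logical(1), "reached_stage5"))
  s3 <- sum(vapply(records, `[[`, logical(1), "reached_stage3"))
  tc <- ts5 <- NA_real_
  diaries <- Filter(Negate(is.null), lapply(records, `[[`, "diary"))
  if (length(diaries)) {
    sev <- lapply(diaries, function(d) {
      w <- se_window(d)
      if (!w$achieved) return(NULL)
      cumulative_severity(d, w)
    })
    sev <- Filter(Negate(is.null), sev)
    if (length(sev)) {
      tc <- mean(vapply(sev, `[[`, numeric(1), "time_in_cms_s"))
      ts5 <- mean(vapply(sev, `[[`, numeric(1), "time_in_stage5_s"))
    }
  }
  structure(list(n = n, deaths = deaths,
                 mortality_pct = .round_half_up(100 * deaths / n),
                 stage5_pct = .round_half_up(100 * s5 / n),
                 stage3_pct = .round_half_up(100 * s3 / n),
                 mortality_frac = deaths / n, stage5_frac = s5 / n,
                 stage3_frac = s3 / n,
                 mean_time_in_cms_s = tc, mean_time_in_stage5_s = ts5),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0("<cohort_summary> n = %d: mortality %d%%, ",
                     "stage-5 %d%%, stage-3 %d%%\n"),
              x$n, x$mortality_pct, x$stage5_pct, x$stage3_pct))
  invisible(x)
}

#' Binary-coded unpaired t-test
#'
#' Pooled-variance Student's t on 0/1-coded outcomes (died = 0, survived =
#' 1; or did not / did reach stage 5), as used to compare mortality and
#' attainment between protocols.
#'
#' @param group_a,group_b numeric 0/1 vectors, each of length >= 2.
#' @return list: `t`, `df`, `p` (two-sided); when both groups have zero
#'   variance the statistic is undefined and `t`/`p` are NA with
#'   `undefined = TRUE`.
#' @export
binary_t_test <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  ssq <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  if (ssq == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = NA_real_, df = df, p = NA_real_, undefined = TRUE))
    }
    return(list(t = Inf, df = df, p = 0, undefined = FALSE))
  }
  sp2 <- ssq / df
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), undefined = FALSE)
}

#' Two-way ANOVA on per-epoch spike rates
#'
#' Fits `rate ~ group * epoch` on a balanced two-factor layout (animals
#' nested in group, rates per 5-min epoch) and reports the group
#' main-effect F against the residual. For the published layout of 2
#' groups x 9 animals x 24 epochs the degrees of freedom are 1 and 384.
#'
#' @param rates_a,rates_b numeric matrices (animals x epochs) of spike
#'   rates for the two groups; must have identical dimensions.
#' @return list: `F`, `df1`, `df2`, `p`.
#' @export
spike_rate_anova <- function(rates_a, rates_b) {
  rates_a <- as.matrix(rates_a); rates_b <- as.matrix(rates_b)
  if (!all(dim(rates_a) == dim(rates_b))) {
    stop("unbalanced layout: both groups need the same animals x epochs")
  }
  if (any(!is.finite(rates_a)) || any(!is.finite(rates_b))) {
    stop("rates must be finite")
  }
  ne <- ncol(rates_a)
  dat <- data.frame(
    rate = c(as.vector(rates_a), as.vector(rates_b)),
    group = factor(rep(c("a", "b"), each = length(rates_a))),
    epoch = factor(rep(rep(seq_len(ne), each = nrow(rates_a)), 2)))
  an <- stats::anova(stats::lm(rate ~ group * epoch, data = dat))
  list(F = an["group", "F value"], df1 = an["group", "Df"],
       df2 = an["Residuals", "Df"], p = an["group", "Pr(>F)"])
}

#' Animal wastage between protocols
#'
#' Percentage-point reduction in animal wastage of the repeated-low-dose
#' protocol versus the single-high-dose protocol: the mortality-rate
#' difference plus the stage-5 attainment difference.
#'
#' @param summary_shd,summary_rld objects with `mortality_pct` and
#'   `stage5_pct` (e.g. [summarize_cohort()] output).
#' @return list: `total`, `mortality_component`, `attainment_component`
#'   (percentage points).
#' @export
wastage <- function(summary_shd, summary_rld) {
  m <- summary_shd$mortality_pct - summary_rld$mortality_pct
  s <- summary_rld$stage5_pct - summary_shd$stage5_pct
  list(total = m + s, mortality_component = m, attainment_component = s)
}
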