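#' Cohort generation profile
#'
#' Describes the marginal structure of a two-center PNET cohort: sample size,
#' center split, WHO grade mix, Ki-67 distribution per grade with a pinned
#' cohort median, functional-tumor and metastatic-organ counts, outcome
#' counts, and follow-up quantiles. The defaults emulate a 44-patient
#' two-center surgical cohort (grade mix 24/15/4, Ki-67 median 4.0%,
#' progression 16 of 43 evaluable, mortality 8, median follow-up 38 months).
#'
#' @param n_patients Total number of patients.
#' @param center_split Proportion of patients per center (length 2, sums to 1).
#' @param grade_counts Named counts for G1/G2/G3; may sum to less than
#'   `n_patients`, in which case the remaining patients have missing biopsy
#'   grade (as happens when fine-needle biopsy is non-diagnostic).
#' @param ki67_by_grade List with one `c(meanlog, sdlog)` pair per grade:
#'   log-scale location/scale of the per-grade Ki-67 (%) distribution.
#' @param ki67_median_pin Cohort median Ki-67 (%) the simulated values are
#'   monotonically rescaled to match exactly.
#' @param ki67_missing_count Number of patients with missing biopsy Ki-67
#'   (drawn among patients with observed grade and outcome where possible).
#' @param functional_count Number of functional (hormone-secreting) tumors.
#' @param metastatic_organ_dist Named counts over 0..3 metastatic organs at
#'   diagnosis; must sum to `n_patients`.
#' @param male_count Number of male patients.
#' @param age_quantiles `c(median, q1, q3)` of age in years.
#' @param size_quantiles `c(median, q1, q3)` of imaging tumor size in cm.
#' @param progression_count Number of progression events among evaluable
#'   patients.
#' @param outcome_association Log-odds weight linking the clinical
#'   aggressiveness score (standardized grade + log Ki-67) to which
#'   patients progress/die; counts stay exact (weighted sampling without
#'   replacement). 0 gives outcomes independent of biology.
#' @param evaluable_n Number of patients with known progression status.
#' @param mortality_count Number of deaths among evaluable patients.
#' @param followup_quantiles `c(median, q1, q3)` of follow-up in months.
#' @param seed Integer seed making generation deterministic.
#'
#' @return An object of class `cohort_profile`.
#' @seealso [generate_cohort()]
#' @export
cohort_profile <- function(n_patients = 44L,
                           center_split = c(A = 0.5, B = 0.5),
                           grade_counts = c(G1 = 24L, G2 = 15L, G3 = 4L),
                           ki67_by_grade = list(
                             G1 = c(meanlog = log(1.8), sdlog = 0.55),
                             G2 = c(meanlog = log(8.0), sdlog = 0.50),
                             G3 = c(meanlog = log(30.0), sdlog = 0.35)
                           ),
                           ki67_median_pin = 4.0,
                           ki67_missing_count = 5L,
                           functional_count = 6L,
                           metastatic_organ_dist = c(`0` = 22L, `1` = 14L,
                                                     `2` = 6L, `3` = 2L),
                           male_count = 25L,
                           age_quantiles = c(median = 62, q1 = 58, q3 = 68),
                           size_quantiles = c(median = 2.7, q1 = 1.5, q3 = 4.6),
                           progression_count = 16L,
                           evaluable_n = 43L,
                           mortality_count = 8L,
                           outcome_association = 1.2,
                           followup_quantiles = c(median = 38, q1 = 14, q3 = 59),
                           seed = 1L) {
  p <- list(
    n_patients = as.integer(n_patients),
    center_split = center_split,
    grade_counts = vapply(grade_counts, as.integer, integer(1)),
    ki67_by_grade = ki67_by_grade,
    ki67_median_pin = ki67_median_pin,
    ki67_missing_count = as.integer(ki67_missing_count),
    functional_count = as.integer(functional_count),
    metastatic_organ_dist = vapply(metastatic_organ_dist, as.integer, integer(1)),
    male_count = as.integer(male_count),
    age_quantiles = age_quantiles,
    size_quantiles = size_quantiles,
    progression_count = as.integer(progression_count),
    evaluable_n = as.integer(evaluable_n),
    mortality_count = as.integer(mortality_count),
    outcome_association = outcome_association,
    followup_quantiles = followup_quantiles,
    seed = as.integer(seed)
  )
  validate_cohort_profile(p)
  structure(p, class = "cohort_profile")
}

validate_cohort_profile <- function(p) {
  if (p$n_patients < 1) abort_field("n_patients", "must be >= 1")
  if (length(p$center_split) != 2 || abs(sum(p$center_split) - 1) > 1e-8) {
    abort_field("center_split", "needs 2 proportions summing to 1")
  }
  if (any(p$grade_counts < 0)) abort_field("grade_counts", "counts must be >= 0")
  if (sum(p$grade_counts) > p$n_patients) {
    abort_field("grade_counts",
                sprintf("sum %d exceeds n_patients %d", sum(p$grade_counts),
                        p$n_patients))
  }
  if (p$ki67_missing_count < 0 || p$ki67_missing_count > p$n_patients) {
    abort_field("ki67_missing_count", "must be in [0, n_patients]")
  }
  if (p$functional_count < 0 || p$functional_count > p$n_patients) {
    abort_field("functional_count", "must be in [0, n_patients]")
  }
  if (sum(p$metastatic_organ_dist) != p$n_patients) {
    abort_field("metastatic_organ_dist", "counts must sum to n_patients")
  }
  if (p$evaluable_n > p$n_patients) {
    abort_field("evaluable_n", "cannot exceed n_patients")
  }
  if (p$progression_count > p$evaluable_n || p$progression_count < 0) {
    abort_field("progression_count", "must be in [0, evaluable_n]")
  }
  if (p$mortality_count > p$evaluable_n || p$mortality_count < 0) {
    abort_field("mortality_count", "must be in [0, evaluable_n]")
  }
  invisible(p)
}

# Convert (median, q1, q3) to log-normal (meanlog, sdlog).
lnorm_from_quantiles <- function(q) {
  c(meanlog = log(q[["median"]]),
    sdlog = log(q[["q3"]] / q[["q1"]]) / (2 * stats::qnorm(0.75)))
}

# Assign exactly k of n rows to a condition, without replacement.
exact_assign <- function(n, k) {
  out <- rep(0L, n)
  if (k > 0) out[sample.int(n, k)] <- 1L
  out
}

#' Generate a synthetic PNET cohort
#'
#' Draws a patient-level clinical table whose categorical marginals (grade
#' mix, sex, functional status, metastatic-organ distribution, progression
#' and mortality counts) match the profile *exactly* (assignment by sampling
#' without replacement), and whose Ki-67 values are drawn log-normally per
#' grade and then monotonically rescaled so the cohort median equals the
#' profile's pin. When `evaluable_n = n_patients - 1`, exactly one patient
#' (chosen uniformly by seed) has missing progression status. Output is
#' deterministic given the profile seed.
#'
#' @param profile A [cohort_profile()].
#' @return A tibble with one row per patient: `patient_id`, `center`, `age`,
#'   `sex`, `grade`, `grade_numeric`, `ki67_pct`, `size_cm`, `functional`,
#'   `n_met_organs`, `followup_months`, `progression` (0/1, `NA` when
#'   unevaluable), `time_progression`, `mortality`, `time_mortality`.
#' @examples
#' cohort <- generate_cohort(cohort_profile(seed = 7))
#' table(cohort$grade)
#' @export
generate_cohort <- function(profile = cohort_profile()) {
  validate_cohort_profile(profile)
  n <- profile$n_patients
  with_seed_(profile$seed, {
    n_a <- round(profile$center_split[[1]] * n)
    center <- sample(rep(names(profile$center_split), c(n_a, n - n_a)))
    n_grade_missing <- n - sum(profile$grade_counts)
    grade <- sample(c(rep(names(profile$grade_counts), profile$grade_counts),
                      rep(NA_character_, n_grade_missing)))
    grade_numeric <- match(grade, c("G1", "G2", "G3"))

    # grade-missing patients draw Ki-67 from the middle (G2) parameters
    ki67 <- vapply(ifelse(is.na(grade), "G2", grade), function(g) {
      par <- profile$ki67_by_grade[[g]]
      stats::rlnorm(1, meanlog = par[["meanlog"]], sdlog = par[["sdlog"]])
    }, numeric(1))
    # (median pin applied after missingness is assigned, below)

    sex <- sample(rep(c("male", "female"),
                      c(profile$male_count, n - profile$male_count)))
    age_par <- c(mean = profile$age_quantiles[["median"]],
                 sd = (profile$age_quantiles[["q3"]] -
                         profile$age_quantiles[["q1"]]) / (2 * stats::qnorm(0.75)))
    age <- round(stats::rnorm(n, age_par[["mean"]], age_par[["sd"]]))
    size_par <- lnorm_from_quantiles(profile$size_quantiles)
    size_cm <- round(stats::rlnorm(n, size_par[["meanlog"]],
                                   size_par[["sdlog"]]), 1)

    functional <- exact_assign(n, profile$functional_count)
    n_met_organs <- sample(rep(as.integer(names(profile$metastatic_organ_dist)),
                               profile$metastatic_organ_dist))

    fu_par <- lnorm_from_quantiles(profile$followup_quantiles)
    followup <- stats::rlnorm(n, fu_par[["meanlog"]], fu_par[["sdlog"]])

    evaluable <- rep(TRUE, n)
    n_missing <- n - profile$evaluable_n
    if (n_missing > 0) evaluable[sample.int(n, n_missing)] <- FALSE

    # Ki-67 missingness, kept disjoint from grade/outcome missingness where
    # the counts allow, so the per-signature complete-case sizes mirror a
    # cohort in which each variable fails independently.
    if (profile$ki67_missing_count > 0) {
      pool <- which(!is.na(grade) & evaluable)
      if (length(pool) < profile$ki67_missing_count) pool <- seq_len(n)
      ki67[sample(pool, profile$ki67_missing_count)] <- NA_real_
    }
    # monotone rescale: multiplication by a positive constant pins the
    # observed-Ki-67 median exactly
    ki67 <- ki67 * (profile$ki67_median_pin /
                      stats::median(ki67, na.rm = TRUE))
    ki67 <- pmin(ki67, 95)

    # events keep exact counts but fall preferentially on aggressive disease
    bio <- biology_score(list(grade_numeric = grade_numeric, ki67_pct = ki67))
    weighted_assign <- function(k) {
      out <- rep(0L, n)
      pool <- which(evaluable)
      if (k > 0) {
        w <- exp(profile$outcome_association * bio[pool])
        out[sample(pool, k, prob = w)] <- 1L
      }
      out[!evaluable] <- NA_integer_
      out
    }
    progression <- weighted_assign(profile$progression_count)
    mortality <- weighted_assign(profile$mortality_count)

    # event times are a uniform fraction of follow-up; censored at follow-up
    time_progression <- followup
    prog_idx <- which(!is.na(progression) & progression == 1L)
    time_progression[prog_idx] <- followup[prog_idx] *
      stats::runif(length(prog_idx), 0.1, 0.95)
    time_mortality <- followup
    mort_idx <- which(!is.na(mortality) & mortality == 1L)
    time_mortality[mort_idx] <- followup[mort_idx] *
      stats::runif(length(mort_idx), 0.3, 1.0)

    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      center = center,
      age = age,
      sex = sex,
      grade = factor(grade, levels = c("G1", "G2", "G3")),
      grade_numeric = grade_numeric,
      ki67_pct = ki67,
      size_cm = size_cm,
      functional = functional,
      n_met_organs = n_met_organs,
      followup_months = followup,
      progression = progression,
      time_progression = time_progression,
      mortality = mortality,
      time_mortality = time_mortality
    )
  })
}

#' Attach proportional-hazards outcomes to a cohort
#'
#' Replaces the cohort's time-to-event columns with outcomes drawn from an
#' exponential proportional-hazards model: the event time for patient *i* is
#' exponential with rate `baseline_hazard * exp(linear_predictor[i])`;
#' censoring times are uniform on `[0, censoring_window]` (a window of `Inf`
#' disables censoring; a window of 0 censors everyone at time zero). The
#' observed time is the minimum of the two with the event flag set
#' accordingly.
#'
#' @param cohort A cohort tibble (one row per patient).
#' @param linear_predictor Per-patient log relative hazard (finite numeric).
#' @param baseline_hazard Baseline event rate per month (> 0).
#' @param censoring_window Upper bound of the uniform censoring distribution,
#'   in months (>= 0, may be `Inf`).
#' @param seed Optional seed for reproducibility.
#' @return The cohort with columns `time` (months) and `event` (0/1) added.
#' @export
attach_outcomes <- function(cohort, linear_predictor, baseline_hazard = 0.01,
                            censoring_window = Inf, seed = NULL) {
  n <- nrow(cohort)
  if (length(linear_predictor) != n) {
    abort_field("linear_predictor", "length must equal nrow(cohort)")
  }
  if (any(!is.finite(linear_predictor))) {
    abort_field("linear_predictor", "scores must be finite")
  }
  if (is.na(censoring_window) || censoring_window < 0) {
    abort_field("censoring_window", "must be >= 0")
  }
  if (baseline_hazard <= 0) abort_field("baseline_hazard", "must be > 0")
  with_seed_(seed, {
    t_event <- stats::rexp(n, rate = baseline_hazard * exp(linear_predictor))
    t_cens <- if (is.infinite(censoring_window)) {
      rep(Inf, n)
    } else {
      stats::runif(n, 0, censoring_window)
    }
    cohort$time <- pmin(t_event, t_cens)
    cohort$event <- as.integer(t_event <= t_cens)
    cohort
  })
}
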