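# Cohort configuration ---------------------------------------------------
#
# The generator emulates a cross-sectional survey of 384 startup managers and
# employees: three nominal demographics (gender, marital status, children),
# two duration variables (age, job experience), a 6-item COVID-19 stress sum
# (6-30), the 4-item BRCS resilience sum (4-20), and the three MBI-GS
# subscales scored as item means on 1-5 (exhaustion, cynicism, professional
# efficiency), plus a binary burnout label (1 = present, 2 = absent).

CONTINUOUS_VARS <- c(
  "age", "job_experience", "covid_stress", "resilience",
  "exhaustion", "cynicism", "professional_efficiency"
)

# Bounded supports and latent slopes for the logistic marginal transform
# x = lo + (hi - lo) * plogis(slope * z + b).  Slopes set the marginal spread
# (roughly, sd(x) ~ (hi-lo) * p(1-p) * slope at the mean); supports for the
# scale scores are the instruments' hard ranges, those for age and experience
# a realistic working-age envelope.
variable_support <- function() {
  data.frame(
    variable = CONTINUOUS_VARS,
    lo = c(20, 0, 6, 4, 1, 1, 1),
    hi = c(70, 40, 30, 20, 5, 5, 5),
    slope = c(0.7, 0.8, 1.3, 1.0, 0.8, 0.8, 0.8),
    stringsAsFactors = FALSE
  )
}

#' Default group-mean calibration targets
#'
#' Published gender-level means for age, job experience, COVID-19 stress and
#' resilience, and overall means for the three MBI-GS subscales. A row with
#' `NA` in a demographic column applies to every respondent; the most
#' specific matching row wins. The published married-with-children subgroup
#' means for stress and resilience are arithmetically incompatible with the
#' gender-level means on these scales' supports, so gender-level targets are
#' the defaults (see the methods vignette).
#'
#' @return Data frame with columns `variable`, `gender`, `marital_status`,
#'   `has_children`, `value`.
#' @export
default_mean_targets <- function() {
  data.frame(
    variable = c(
      "age", "age", "job_experience", "job_experience",
      "covid_stress", "covid_stress", "resilience", "resilience",
      "exhaustion", "cynicism", "professional_efficiency"
    ),
    gender = c(
      "female", "male", "female", "male",
      "female", "male", "female", "male",
      NA, NA, NA
    ),
    marital_status = NA_character_,
    has_children = NA_character_,
    value = c(
      40.43, 42.84, 11.86, 14.63,
      8.00, 6.24, 11.86, 13.73,
      3.99, 3.72, 2.97
    ),
    stringsAsFactors = FALSE
  )
}

#' Default Pearson correlation calibration targets
#'
#' The four correlations of the [burnout_composite()] with the MBI-GS
#' subscales and resilience, plus the four direct COVID-stress correlations.
#' Together they pin down the latent copula structure.
#'
#' @return Named numeric vector of observed-scale correlation targets.
#' @export
default_correlation_targets <- function() {
  c(
    comp_exhaustion = 0.594,
    comp_cynicism = 0.467,
    comp_professional_efficiency = -0.322,
    comp_resilience = -0.222,
    stress_exhaustion = 0.532,
    stress_cynicism = 0.427,
    stress_professional_efficiency = -0.200,
    stress_resilience = -0.306
  )
}

#' Default joint demographic cell counts
#'
#' Only per-gender marginals are published; children are placed within
#' married respondents, which reproduces every printed marginal (167/217
#' gender, 120/264 marital, 218/166 children) and matches the published
#' "married women with children" subgroup sizes.
#'
#' @return Data frame with columns `gender`, `marital_status`,
#'   `has_children`, `n` summing to 384.
#' @export
default_demographic_cells <- function() {
  data.frame(
    gender = c("female", "female", "female", "male", "male", "male"),
    marital_status = c("married", "married", "single", "married", "married", "single"),
    has_children = c("yes", "no", "no", "yes", "no", "no"),
    n = c(100L, 33L, 34L, 118L, 13L, 86L),
    stringsAsFactors = FALSE
  )
}

# Map correlation targets (stated on the observed scale, in terms of the
# burnout composite) to a latent 7x7 correlation matrix over the continuous
# variables.  Writing u = e + c - p for unit-variance latents, sd(u) = s
# satisfies s = t_e + t_c - t_p (sum of the three composite targets with the
# efficiency sign flipped), from which the three subscale inter-correlations
# follow uniquely; the resilience-composite target is allocated across the
# three subscales with fixed weights (0.5, 0.4, -0.1); stress targets map
# directly.  Age-experience correlation is a realistic fixed 0.7 (no published
# value); age and experience are otherwise latent-independent of the scales.
solve_latent_correlation <- function(targets = default_correlation_targets(),
                                     age_experience_r = 0.7) {
  t_e <- targets[["comp_exhaustion"]]
  t_c <- targets[["comp_cynicism"]]
  t_p <- targets[["comp_professional_efficiency"]]
  s <- t_e + t_c - t_p
  if (s <= 0) config_error("composite correlation targets imply non-positive composite variance")
  r_ep <- (1 + t_p * s - (t_e - t_c) * s) / 2
  r_cp <- (1 + t_p * s + (t_e - t_c) * s) / 2
  r_ec <- t_e * s - 1 + r_ep
  q <- targets[["comp_resilience"]] * s
  r_re <- 0.5 * q
  r_rc <- 0.4 * q
  r_rp <- -0.1 * q

  v <- CONTINUOUS_VARS
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  set_r <- function(R, a, b, val) {
    R[a, b] <- R[b, a] <- max(min(val, 0.95), -0.95)
    R
  }
  R <- set_r(R, "age", "job_experience", age_experience_r)
  R <- set_r(R, "exhaustion", "cynicism", r_ec)
  R <- set_r(R, "exhaustion", "professional_efficiency", r_ep)
  R <- set_r(R, "cynicism", "professional_efficiency", r_cp)
  R <- set_r(R, "resilience", "exhaustion", r_re)
  R <- set_r(R, "resilience", "cynicism", r_rc)
  R <- set_r(R, "resilience", "professional_efficiency", r_rp)
  R <- set_r(R, "covid_stress", "exhaustion", targets[["stress_exhaustion"]])
  R <- set_r(R, "covid_stress", "cynicism", targets[["stress_cynicism"]])
  R <- set_r(R, "covid_stress", "professional_efficiency", targets[["stress_professional_efficiency"]])
  R <- set_r(R, "covid_stress", "resilience", targets[["stress_resilience"]])
  pd_repair(R)
}

#' Configure a synthetic burnout survey cohort
#'
#' Builds the full calibration recipe for the synthetic cohort generator:
#' exact demographic cell counts, per-group mean targets, the latent Gaussian
#' copula correlation matrix, and the exact burnout prevalence. Defaults
#' reproduce the published study cohort: n = 384 (167 female / 217 male,
#' 120 single / 264 married, 218 with children / 166 without), 232 burnout
#' cases, published scale means and Pearson correlations.
#'
#' @param n_total Total number of respondents. Must equal the sum of
#'   `demographic_cells$n`.
#' @param demographic_cells Data frame with columns `gender`,
#'   `marital_status`, `has_children`, `n` giving exact cell counts.
#' @param mean_targets Data frame with columns `variable`, `gender`,
#'   `marital_status`, `has_children`, `value`; `NA` cells are wildcards and
#'   the most specific matching row wins.
#' @param correlation_targets Named vector of observed-scale Pearson targets
#'   (see [default_correlation_targets()]); mapped to a latent matrix and,
#'   when `calibrate = TRUE`, iteratively adjusted so *sample* correlations
#'   of generated cohorts hit the targets despite the attenuation of the
#'   bounded marginal transforms.
#' @param burnout_count Exact number of label-1 (burnout present) records.
#' @param seed Base random seed recorded with the config.
#' @param calibrate Run the iterative copula calibration (recommended; a few
#'   internally seeded simulation rounds).
#' @param calibration_rounds Number of calibration rounds (<= 10).
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(calibrate = FALSE)
#' cfg$n_total
#' @export
cohort_config <- function(n_total = 384L,
                          demographic_cells = default_demographic_cells(),
                          mean_targets = default_mean_targets(),
                          correlation_targets = default_correlation_targets(),
                          burnout_count = 232L,
                          seed = 1L,
                          calibrate = TRUE,
                          calibration_rounds = 10L) {
  assert_scalar_number(n_total, "n_total")
  assert_scalar_number(burnout_count, "burnout_count")
  assert_scalar_number(seed, "seed")
  req <- c("gender", "marital_status", "has_children", "n")
  if (!all(req %in% names(demographic_cells))) {
    config_error("demographic_cells must have columns %s", paste(req, collapse = ", "))
  }
  if (sum(demographic_cells$n) != n_total) {
    config_error("demographic cell counts sum to %d, not n_total = %d",
                 sum(demographic_cells$n), n_total)
  }
  if (any(demographic_cells$n < 0)) config_error("negative demographic cell count")
  if (burnout_count < 0 || burnout_count > n_total) {
    config_error("burnout_count must lie in [0, n_total]")
  }
  sup <- variable_support()
  for (i in seq_len(nrow(mean_targets))) {
    v <- mean_targets$variable[i]
    row <- sup[sup$variable == v, ]
    if (nrow(row) == 0L) config_error("unknown variable in mean_targets: %s", v)
    val <- mean_targets$value[i]
    if (val <= row$lo || val >= row$hi) {
      config_error("mean target %.3f for %s outside its open range (%g, %g)",
                   val, v, row$lo, row$hi)
    }
  }

  cfg <- structure(
    list(
      n_total = as.integer(n_total),
      demographic_cells = demographic_cells,
      mean_targets = mean_targets,
      correlation_targets = correlation_targets,
      latent_correlation = solve_latent_correlation(correlation_targets),
      burnout_count = as.integer(burnout_count),
      seed = as.integer(seed),
      support = sup
    ),
    class = "cohort_config"
  )
  if (isTRUE(calibrate) && n_total > 0L) {
    cfg <- calibrate_cohort_config(cfg, rounds = calibration_rounds)
  }
  cfg
}

#' @method print cohort_config
#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic burnout cohort configuration\n")
  cat(sprintf("  respondents: %d (%d burnout / %d not)\n",
              x$n_total, x$burnout_count, x$n_total - x$burnout_count))
  cat(sprintf("  demographic cells: %d, mean targets: %d, correlation targets: %d\n",
              nrow(x$demographic_cells), nrow(x$mean_targets),
              length(x$correlation_targets)))
  cat(sprintf("  copula calibrated: %s\n",
              if (isTRUE(attr(x, "calibrated"))) "yes" else "no"))
  invisible(x)
}

# Cache for calibrated default configs: calibration is deterministic, so one
# result per target-set is enough for a session.
.calibration_cache <- new.env(parent = emptyenv())

# Iterative copula calibration.  The logistic marginal transforms (and the
# strongly floor-skewed stress marginal in particular) attenuate Pearson
# correlations relative to the latent Gaussian scale.  Each round generates a
# size-scaled cohort under a fixed internal seed, measures the targeted sample
# correlations, and nudges the *effective* targets by a damped residual before
# re-solving the latent matrix.  Deterministic given the config.
calibrate_cohort_config <- function(config, rounds = 8L, size_factor = 4L,
                                    damping = 0.6) {
  if (rounds < 1L) return(config)
  key <- paste(
    utils::capture.output(utils::str(config$correlation_targets)),
    utils::capture.output(utils::str(config$mean_targets$value)),
    utils::capture.output(utils::str(config$demographic_cells$n)),
    rounds, size_factor, collapse = "|"
  )
  key <- paste(key, collapse = "|")
  if (!is.null(.calibration_cache[[key]])) {
    config$latent_correlation <- .calibration_cache[[key]]
    attr(config, "calibrated") <- TRUE
    return(config)
  }

  big <- config
  big$demographic_cells$n <- big$demographic_cells$n * size_factor
  big$n_total <- sum(big$demographic_cells$n)
  target <- config$correlation_targets
  eff <- target
  for (round in seq_len(rounds)) {
    big$latent_correlation <- solve_latent_correlation(eff)
    skel <- assign_demographics(big)
    scored <- sample_scores(skel, big, seed = 7000L + round)
    obs <- measure_correlations(scored)
    eff <- eff + damping * (target - obs)
    # Effective targets are clipped well inside unit correlation: beyond this
    # the solved latent matrix leaves the positive-definite cone and the
    # nearest-PD repair starts distorting the *attainable* targets.
    eff <- pmax(pmin(eff, 0.8), -0.8)
  }
  config$latent_correlation <- solve_latent_correlation(eff)
  attr(config, "calibrated") <- TRUE
  .calibration_cache[[key]] <- config$latent_correlation
  config
}

# Sample versions of the eight targeted correlations, on the observed scale.
measure_correlations <- function(cohort_df) {
  comp <- burnout_composite(
    cohort_df$exhaustion, cohort_df$cynicism, cohort_df$professional_efficiency
  )
  s <- cohort_df$covid_stress
  c(
    comp_exhaustion = cor(comp, cohort_df$exhaustion),
    comp_cynicism = cor(comp, cohort_df$cynicism),
    comp_professional_efficiency = cor(comp, cohort_df$professional_efficiency),
    comp_resilience = cor(comp, cohort_df$resilience),
    stress_exhaustion = cor(s, cohort_df$exhaustion),
    stress_cynicism = cor(s, cohort_df$cynicism),
    stress_professional_efficiency = cor(s, cohort_df$professional_efficiency),
    stress_resilience = cor(s, cohort_df$resilience)
  )
}
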