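# Synthetic cohort generation --------------------------------------------

#' Column schema of a cohort table
#' @return Character vector of the cohort CSV column names, in order.
#' @export
cohort_columns <- function() {
  c("id", "gender", "marital_status", "has_children", "age", "job_experience",
    "covid_stress", "resilience", "exhaustion", "cynicism",
    "professional_efficiency", "burnout_label")
}

#' Lay out the demographic skeleton of a cohort
#'
#' Expands the exact demographic cell counts of a [cohort_config()] into one
#' row per respondent (categorical fields only). Deterministic: rows are
#' emitted in cell order, so the categorical marginals match the configured
#' counts exactly, not in expectation.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `id`, `gender`, `marital_status`,
#'   `has_children`.
#' @export
assign_demographics <- function(config) {
  cells <- config$demographic_cells
  idx <- rep(seq_len(nrow(cells)), cells$n)
  out <- data.frame(
    id = seq_len(sum(cells$n)),
    gender = cells$gender[idx],
    marital_status = cells$marital_status[idx],
    has_children = cells$has_children[idx],
    stringsAsFactors = FALSE
  )
  if (nrow(out) != config$n_total) {
    config_error("demographic cells expand to %d rows, expected %d",
                 nrow(out), config$n_total)
  }
  out
}

# Solve the logistic-normal location offset b such that
# E[plogis(slope * Z + b)] = frac for Z ~ N(0,1).
calibrate_offset <- function(frac, slope) {
  if (frac <= 0 || frac >= 1) config_error("mean target fraction %.4f outside (0, 1)", frac)
  f <- function(b) {
    integrate(function(z) plogis(slope * z + b) * dnorm(z),
              -Inf, Inf, rel.tol = 1e-10)$value - frac
  }
  uniroot(f, c(-40, 40), tol = 1e-10)$root
}

# Most-specific mean target per row for one variable: NA columns in
# mean_targets are wildcards; the matching row with most non-NA cells wins.
resolve_mean_targets <- function(skeleton, mean_targets, variable, support_row) {
  rows <- mean_targets[mean_targets$variable == variable, , drop = FALSE]
  mid <- (support_row$lo + support_row$hi) / 2
  out <- rep(mid, nrow(skeleton))
  if (nrow(rows) == 0L) return(out)
  specificity <- rep(-1L, nrow(skeleton))
  for (i in seq_len(nrow(rows))) {
    match_i <- rep(TRUE, nrow(skeleton))
    spec_i <- 0L
    for (col in c("gender", "marital_status", "has_children")) {
      val <- rows[[col]][i]
      if (!is.na(val)) {
        match_i <- match_i & (skeleton[[col]] == val)
        spec_i <- spec_i + 1L
      }
    }
    take <- match_i & (spec_i > specificity)
    out[take] <- rows$value[i]
    specificity[take] <- spec_i
  }
  out
}

#' Draw continuous survey scores via a Gaussian copula
#'
#' Adds the seven continuous variables to a demographic skeleton. A latent
#' multivariate normal vector with the config's latent correlation matrix is
#' transformed per variable onto its bounded support by a scaled logistic
#' map, with per-group location offsets solved numerically so each targeted
#' group mean is matched in expectation. Job experience is constrained to
#' `age - 16` years at most by conditional redraw of its latent coordinate.
#'
#' @param skeleton Output of [assign_demographics()].
#' @param config The [cohort_config()].
#' @param seed Integer seed; identical seed reproduces identical scores.
#' @return The skeleton with the continuous columns appended.
#' @export
sample_scores <- function(skeleton, config, seed) {
  assert_scalar_number(seed, "seed")
  n <- nrow(skeleton)
  vars <- CONTINUOUS_VARS
  R <- config$latent_correlation[vars, vars]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) config_error("latent correlation is not positive-definite")

  if (n == 0L) {
    for (v in vars) skeleton[[v]] <- numeric(0)
    return(skeleton)
  }

  U <- chol(R)
  Z <- withr::with_seed(
    derive_seed(seed, "scores"),
    matrix(rnorm(n * length(vars)), nrow = n) %*% U
  )
  colnames(Z) <- vars

  sup <- config$support
  offset_cache <- new.env(parent = emptyenv())
  X <- matrix(NA_real_, nrow = n, ncol = length(vars), dimnames = list(NULL, vars))
  B <- matrix(NA_real_, nrow = n, ncol = length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    srow <- sup[sup$variable == v, ]
    targets <- resolve_mean_targets(skeleton, config$mean_targets, v, srow)
    frac <- (targets - srow$lo) / (srow$hi - srow$lo)
    b <- vapply(frac, function(f) {
      key <- sprintf("%s|%.12f", v, f)
      if (is.null(offset_cache[[key]])) {
        offset_cache[[key]] <- calibrate_offset(f, srow$slope)
      }
      offset_cache[[key]]
    }, numeric(1))
    B[, v] <- b
    X[, v] <- srow$lo + (srow$hi - srow$lo) * plogis(srow$slope * Z[, v] + b)
  }

  # Plausibility: experience at most age - 16.  Redraw the experience latent
  # from its conditional normal given the other coordinates (correlation
  # structure preserved); after max_tries, pin to the boundary.
  viol <- which(X[, "job_experience"] > X[, "age"] - 16)
  if (length(viol) > 0L) {
    j <- match("job_experience", vars)
    s12 <- R[j, -j, drop = FALSE]
    s22i <- solve(R[-j, -j])
    w <- s12 %*% s22i
    cond_sd <- sqrt(max(1 - (w %*% t(s12))[1, 1], 1e-12))
    srow <- sup[sup$variable == "job_experience", ]
    withr::with_seed(derive_seed(seed, "rejection"), {
      for (i in viol) {
        mu <- (w %*% Z[i, -j])[1, 1]
        ok <- FALSE
        for (try in seq_len(50L)) {
          z_new <- mu + cond_sd * rnorm(1L)
          x_new <- srow$lo + (srow$hi - srow$lo) *
            plogis(srow$slope * z_new + B[i, "job_experience"])
          if (x_new <= X[i, "age"] - 16) {
            X[i, "job_experience"] <- x_new
            ok <- TRUE
            break
          }
        }
        if (!ok) X[i, "job_experience"] <- max(srow$lo, X[i, "age"] - 16)
      }
    })
  }

  for (v in vars) skeleton[[v]] <- X[, v]
  skeleton
}

#' Burnout severity composite
#'
#' Continuous burnout proxy combining the three MBI-GS subscales: high
#' exhaustion, high cynicism, and low professional efficiency all raise it.
#' Defined as `(exhaustion + cynicism + (6 - professional_efficiency)) / 3`,
#' so it lives on the same 1-5 scale as its inputs.
#'
#' @param exhaustion,cynicism,professional_efficiency Numeric vectors in
#'   `[1, 5]`.
#' @return Numeric vector in `[1, 5]`.
#' @examples
#' burnout_composite(5, 5, 1) # maximal burnout
#' @export
burnout_composite <- function(exhaustion, cynicism, professional_efficiency) {
  for (nm in c("exhaustion", "cynicism", "professional_efficiency")) {
    x <- get(nm)
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 1 | x > 5)) {
      validation_error("`%s` must be numeric in [1, 5]", nm)
    }
  }
  (exhaustion + cynicism + (6 - professional_efficiency)) / 3
}

#' Assign burnout labels by top-k composite ranking
#'
#' The `burnout_count` records with the highest [burnout_composite()] receive
#' label 1 (burnout present); all others label 2. Ranking ties are broken by
#' record index (ascending), so the configured prevalence is met exactly and
#' deterministically.
#'
#' @param cohort Data frame with the continuous score columns populated.
#' @param burnout_count Number of label-1 records.
#' @return `cohort` with a `burnout_label` column in `{1, 2}`.
#' @export
assign_burnout_labels <- function(cohort, burnout_count) {
  n <- nrow(cohort)
  if (burnout_count < 0 || burnout_count > n) {
    config_error("burnout_count %d outside [0, %d]", burnout_count, n)
  }
  label <- rep(2L, n)
  if (n > 0L && burnout_count > 0L) {
    comp <- burnout_composite(
      cohort$exhaustion, cohort$cynicism, cohort$professional_efficiency
    )
    ord <- order(-comp, seq_len(n))
    label[ord[seq_len(burnout_count)]] <- 1L
  }
  cohort$burnout_label <- label
  cohort
}

#' Generate a complete synthetic survey cohort
#'
#' Composes [assign_demographics()], [sample_scores()], and
#' [assign_burnout_labels()]. The output is byte-identical for identical
#' `(config, seed)`; different seeds share the (deterministic) categorical
#' fields and differ only in the continuous scores and labels.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to the config's seed.
#' @return A `cohort` data frame with the full column schema (see
#'   [read_cohort_csv()]).
#' @examples
#' cfg <- cohort_config(calibrate = FALSE)
#' coh <- generate_cohort(cfg, seed = 1)
#' table(coh$gender)
#' sum(coh$burnout_label == 1)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  skeleton <- assign_demographics(config)
  scored <- sample_scores(skeleton, config, seed = seed)
  labeled <- assign_burnout_labels(scored, config$burnout_count)
  out <- labeled[, cohort_columns()]
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("cohort", "data.frame")
  out
}
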