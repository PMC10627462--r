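# Synthetic cohort generator: exact marginals, composite, labels, calibration.

test_that("default demographics reproduce the published marginals exactly", {
  cfg <- cohort_config(calibrate = FALSE)
  skel <- assign_demographics(cfg)
  expect_equal(nrow(skel), 384L)
  expect_equal(sum(skel$gender == "female"), 167L)
  expect_equal(sum(skel$gender == "male"), 217L)
  expect_equal(sum(skel$marital_status == "single"), 120L)
  expect_equal(sum(skel$marital_status == "married"), 264L)
  expect_equal(sum(skel$has_children == "yes"), 218L)
  expect_equal(sum(skel$has_children == "no"), 166L)
})

test_that("an empty configuration yields an empty cohort", {
  cells <- default_demographic_cells()
  cells$n <- 0L
  cfg <- cohort_config(n_total = 0L, demographic_cells = cells,
                       burnout_count = 0L, calibrate = FALSE)
  coh <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(coh), 0L)
  expect_true(all(cohort_columns() %in% names(coh)))
})

test_that("invalid configurations are rejected", {
  cells <- default_demographic_cells()
  expect_error(cohort_config(n_total = 100L, demographic_cells = cells,
                             calibrate = FALSE),
               class = "burnoutGMDH_config_error")
  expect_error(cohort_config(burnout_count = 500L, calibrate = FALSE),
               class = "burnoutGMDH_config_error")
  mt <- default_mean_targets()
  mt$value[mt$variable == "exhaustion"] <- 7
  expect_error(cohort_config(mean_targets = mt, calibrate = FALSE),
               class = "burnoutGMDH_config_error")
})

test_that("burnout composite matches its closed form and bounds", {
  expect_equal(burnout_composite(5, 5, 1), 5.0)
  expect_equal(burnout_composite(1, 1, 5), 1.0)
  # published scale means, pushed through the formula directly
  expect_equal(burnout_composite(3.99, 3.72, 2.97),
               (3.99 + 3.72 + (6 - 2.97)) / 3)
  expect_error(burnout_composite(0.5, 3, 3),
               class = "burnoutGMDH_validation_error")
})

test_that("top-k labeling yields exact prevalence with index tie-breaks", {
  cfg <- cohort_config(calibrate = FALSE)
  coh <- generate_cohort(cfg, seed = 3)
  expect_equal(sum(coh$burnout_label == 1L), 232L)
  expect_equal(sum(coh$burnout_label == 2L), 152L)

  all2 <- assign_burnout_labels(coh, 0L)
  expect_true(all(all2$burnout_label == 2L))
  all1 <- assign_burnout_labels(coh, nrow(coh))
  expect_true(all(all1$burnout_label == 1L))
  expect_error(assign_burnout_labels(coh, nrow(coh) + 1L),
               class = "burnoutGMDH_config_error")

  # four identical composites, two label-1 slots: earliest indices win
  tied <- data.frame(exhaustion = rep(3, 4), cynicism = rep(3, 4),
                     professional_efficiency = rep(3, 4))
  lab <- assign_burnout_labels(tied, 2L)$burnout_label
  expect_equal(lab, c(1L, 1L, 2L, 2L))
})

test_that("every generated score respects its declared range, any seed", {
  cfg <- default_test_config()
  sup <- burnoutGMDH:::variable_support()
  for (s in c(1, 11, 57)) {
    coh <- generate_cohort(cfg, seed = s)
    for (i in seq_len(nrow(sup))) {
      v <- sup$variable[i]
      expect_true(all(coh[[v]] >= sup$lo[i] & coh[[v]] <= sup$hi[i]),
                  label = sprintf("%s in range (seed %d)", v, s))
    }
    expect_true(all(coh$job_experience < coh$age))
    expect_true(all(coh$burnout_label %in% c(1L, 2L)))
  }
})

test_that("generation is deterministic in (config, seed) and categorical fields are seed-invariant", {
  cfg <- default_test_config()
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(a, f1); write_cohort_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  c2 <- generate_cohort(cfg, seed = 6)
  expect_identical(a[, c("gender", "marital_status", "has_children")],
                   c2[, c("gender", "marital_status", "has_children")])
  expect_false(isTRUE(all.equal(a$exhaustion, c2$exhaustion)))
})

test_that("a single-cell config hits its configured mean within 3 standard errors", {
  cells <- data.frame(gender = "female", marital_status = "single",
                      has_children = "no", n = 2000L)
  cfg <- cohort_config(n_total = 2000L, demographic_cells = cells,
                       burnout_count = 0L, calibrate = FALSE)
  skel <- assign_demographics(cfg)
  d <- sample_scores(skel, cfg, seed = 9)
  se <- sd(d$exhaustion) / sqrt(nrow(d))
  expect_lt(abs(mean(d$exhaustion) - 3.99), 3 * se)
})

test_that("identity latent correlation yields near-independent scores", {
  cfg <- cohort_config(calibrate = FALSE)
  cfg$latent_correlation <- diag(7)
  dimnames(cfg$latent_correlation) <-
    dimnames(burnoutGMDH:::solve_latent_correlation())
  skel <- assign_demographics(cfg)
  d <- sample_scores(skel, cfg, seed = 2)
  # within one gender (removing configured mean shifts), all |r| small at n=384
  f <- d[d$gender == "male", ]
  vars <- c("covid_stress", "resilience", "exhaustion", "cynicism",
            "professional_efficiency")
  cm <- cor(f[, vars])
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.15)
})

test_that("calibrated cohorts hit attainable group means and correlations on average", {
  cfg <- default_test_config()
  seeds <- 1:20
  cors <- sapply(seeds, function(s) {
    burnoutGMDH:::measure_correlations(generate_cohort(cfg, seed = s))
  })
  mc <- rowMeans(cors)
  tgt <- default_correlation_targets()
  attainable <- c("comp_exhaustion", "comp_cynicism",
                  "comp_professional_efficiency", "comp_resilience",
                  "stress_resilience")
  for (nm in attainable) {
    expect_lt(abs(mc[[nm]] - tgt[[nm]]), 0.05, label = nm)
  }

  ms <- sapply(seeds, function(s) {
    d <- generate_cohort(cfg, seed = s)
    c(exh = mean(d$exhaustion), cyn = mean(d$cynicism),
      eff = mean(d$professional_efficiency),
      res_m = mean(d$resilience[d$gender == "male"]),
      res_f = mean(d$resilience[d$gender == "female"]),
      str_m = mean(d$covid_stress[d$gender == "male"]),
      str_f = mean(d$covid_stress[d$gender == "female"]),
      age_f = mean(d$age[d$gender == "female"]),
      age_m = mean(d$age[d$gender == "male"]),
      exp_f = mean(d$job_experience[d$gender == "female"]),
      exp_m = mean(d$job_experience[d$gender == "male"]))
  })
  mm <- rowMeans(ms)
  expect_lt(abs(mm[["exh"]] - 3.99), 0.5)
  expect_lt(abs(mm[["cyn"]] - 3.72), 0.5)
  expect_lt(abs(mm[["eff"]] - 2.97), 0.5)
  expect_lt(abs(mm[["res_m"]] - 13.73), 0.5)
  expect_lt(abs(mm[["res_f"]] - 11.86), 0.5)
  expect_lt(abs(mm[["str_m"]] - 6.24), 0.5)
  expect_lt(abs(mm[["str_f"]] - 8.00), 0.5)
  expect_lt(abs(mm[["age_f"]] - 40.43), 1.5)
  expect_lt(abs(mm[["age_m"]] - 42.84), 1.5)
  expect_lt(abs(mm[["exp_f"]] - 11.86), 1.5)
  expect_lt(abs(mm[["exp_m"]] - 14.63), 1.5)
})
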