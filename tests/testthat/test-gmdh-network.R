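# Full network growth, prediction, classification, feature readout.

test_that("an exact quadratic target is recovered with its generating pair, any seed", {
  for (s in 1:5) {
    d <- make_quadratic_data(n = 80, n_noise = 3, seed = s)
    tr <- 1:56; va <- 57:80
    model <- fit_gmdh(d$X[tr, ], d$y[tr], d$X[va, ], d$y[va])
    expect_equal(length(model$layers), 1L)
    expect_lt(model$layer_best[1], 1e-8)
    expect_equal(selected_features(model), c("x1", "x2"))
    expect_lt(max(abs(predict_continuous(model, d$X[tr, ]) - d$y[tr])), 1e-6)
  }
})

test_that("a constant target yields a one-layer constant model", {
  withr::with_seed(3, X <- matrix(runif(60 * 4), 60, 4))
  colnames(X) <- paste0("x", 1:4)
  y <- rep(7, 60)
  model <- fit_gmdh(X[1:40, ], y[1:40], X[41:60, ], y[41:60])
  expect_equal(length(model$layers), 1L)
  expect_lt(max(abs(predict_continuous(model, X) - 7)), 1e-8)
})

test_that("best criterion is non-increasing across kept layers", {
  cfg <- default_test_config()
  coh <- generate_cohort(cfg, seed = 2)
  X <- encode_features(coh)
  y <- as.numeric(coh$burnout_label)
  sp <- split_70_15_15(nrow(X), seed = 2)
  model <- fit_gmdh(X[sp$train, ], y[sp$train], X[sp$val, ], y[sp$val])
  expect_true(all(diff(model$layer_best) <= 0))
})

test_that("prediction equals manual topological evaluation of a hand-built model", {
  pd <- function(a, b, coefs) {
    structure(list(input_a = a, input_b = b, coefficients = coefs,
                   criterion = 0), class = "partial_description")
  }
  # layer 1: n1 on raw (x1, x2), n2 on raw (x3, x4); layer 2 combines them
  c1 <- c(0.5, 1, -1, 0.2, 0, 0.1)
  c2 <- c(-0.3, 0.7, 0.4, 0, 0.05, 0)
  c3 <- c(0.1, 0.9, 0.6, 0.01, -0.02, 0.03)
  model <- structure(
    list(feature_names = paste0("x", 1:4),
         layers = list(list(pd(1L, 2L, c1), pd(3L, 4L, c2)),
                       list(pd(1L, 2L, c3))),
         output_neuron = c(layer = 2L, neuron = 1L),
         layer_best = c(0, 0), cutoff = 1.5, class_labels = c(1L, 2L),
         config = NULL),
    class = "gmdh_model"
  )
  withr::with_seed(8, X <- matrix(rnorm(5 * 4), 5, 4))
  q <- function(co, xa, xb) {
    co[1] + co[2] * xa + co[3] * xb + co[4] * xa^2 + co[5] * xb^2 + co[6] * xa * xb
  }
  z1 <- q(c1, X[, 1], X[, 2]); z2 <- q(c2, X[, 3], X[, 4])
  expect_equal(predict_continuous(model, X), q(c3, z1, z2))
  expect_equal(selected_features(model), paste0("x", 1:4))
})

test_that("classification thresholds at 1.5 inclusive on the burnout side", {
  X <- matrix(0, 3, 2)
  expect_equal(classify(constant_model(1.0), X), rep(1L, 3))
  expect_equal(classify(constant_model(1.5), X), rep(1L, 3))
  expect_equal(classify(constant_model(1.5000001), X), rep(2L, 3))
  expect_error(classify(constant_model(1), matrix(0, 2, 5)),
               class = "burnoutGMDH_validation_error")
})

test_that("predictions are a row-wise map", {
  d <- make_quadratic_data(n = 40, n_noise = 2, seed = 12)
  model <- fit_gmdh(d$X[1:30, ], d$y[1:30], d$X[31:40, ], d$y[31:40])
  perm <- c(5, 1, 4, 2, 3)
  expect_equal(predict_continuous(model, d$X[perm, ]),
               predict_continuous(model, d$X[1:5, ])[perm])
})

test_that("fitting is deterministic and stable under feature permutation", {
  cfg <- default_test_config()
  coh <- generate_cohort(cfg, seed = 4)
  X <- encode_features(coh)
  y <- as.numeric(coh$burnout_label)
  sp <- split_70_15_15(nrow(X), seed = 4)
  fitted <- function(Xm) {
    fit_gmdh(Xm[sp$train, ], y[sp$train], Xm[sp$val, ], y[sp$val],
             feature_names = colnames(Xm))
  }
  m1 <- fitted(X); m2 <- fitted(X)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_model_json(m1, f1); write_model_json(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  perm <- c(3, 1, 10, 4, 2, 8, 5, 9, 6, 7)
  m3 <- fitted(X[, perm])
  expect_lt(abs(min(m1$layer_best) - min(m3$layer_best)), 1e-9)
})

test_that("pruning keeps only neurons reachable from the output", {
  d <- make_quadratic_data(n = 100, n_noise = 4, seed = 21)
  tr <- 1:70; va <- 71:100
  y <- d$y + withr::with_seed(22, rnorm(100, sd = 0.5))
  model <- fit_gmdh(d$X[tr, ], y[tr], d$X[va, ], y[va])
  L <- length(model$layers)
  expect_equal(length(model$layers[[L]]), 1L)
  if (L > 1) {
    for (l in 2:L) {
      used <- sort(unique(unlist(lapply(model$layers[[l]], function(p) {
        c(p$input_a, p$input_b)
      }))))
      expect_equal(used, seq_along(model$layers[[l - 1]]))
    }
  }
})
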