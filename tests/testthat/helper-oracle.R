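# Independent oracles used across tests.

# Brute-force GMDH layer: enumerate every input pair, solve the quadratic
# normal equations directly (solve(), not the package's QR path), score by
# validation MSE.  Returns candidates ordered by (criterion, a, b).
brute_force_layer <- function(X_tr, y_tr, X_val, y_val) {
  m <- ncol(X_tr)
  rows <- list()
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      D <- cbind(1, X_tr[, a], X_tr[, b], X_tr[, a]^2, X_tr[, b]^2,
                 X_tr[, a] * X_tr[, b])
      beta <- solve(t(D) %*% D, t(D) %*% y_tr)
      Dv <- cbind(1, X_val[, a], X_val[, b], X_val[, a]^2, X_val[, b]^2,
                  X_val[, a] * X_val[, b])
      mse <- mean((y_val - Dv %*% beta)^2)
      rows[[length(rows) + 1]] <- data.frame(a = a, b = b, criterion = mse)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$criterion, out$a, out$b), ]
}

# Data whose target is exactly quadratic in features 1 and 2, with extra
# pure-noise features appended.
make_quadratic_data <- function(n = 60, n_noise = 3, seed = 1,
                                coefs = c(1, 2, 3, 4, 5, 6)) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * (2 + n_noise), -1, 1), nrow = n)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    y <- coefs[1] + coefs[2] * X[, 1] + coefs[3] * X[, 2] +
      coefs[4] * X[, 1]^2 + coefs[5] * X[, 2]^2 + coefs[6] * X[, 1] * X[, 2]
    list(X = X, y = y)
  })
}

# Default calibrated config, built once per test run (cached in the package).
default_test_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- cohort_config()
    cfg
  }
})

# A tiny hand-built one-neuron model predicting a constant.
constant_model <- function(value, n_features = 2) {
  structure(
    list(
      feature_names = paste0("x", seq_len(n_features)),
      layers = list(list(structure(
        list(input_a = 1L, input_b = 2L,
             coefficients = c(value, 0, 0, 0, 0, 0), criterion = 0),
        class = "partial_description"
      ))),
      output_neuron = c(layer = 1L, neuron = 1L),
      layer_best = 0,
      cutoff = 1.5, class_labels = c(1L, 2L), config = NULL
    ),
    class = "gmdh_model"
  )
}
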