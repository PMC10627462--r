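# GMDH network fitting -----------------------------------------------------
#
# The network is grown layer by layer from quadratic two-input neurons
# ("partial descriptions") z = c1 + c2*xa + c3*xb + c4*xa^2 + c5*xb^2 +
# c6*xa*xb, each fitted by ordinary least squares on the training split and
# scored by mean squared error on the validation split (the external
# criterion).  Retained neurons feed the next layer; growth stops when the
# best criterion no longer improves.  The layered composition realizes a
# high-order Kolmogorov-Gabor polynomial without ever fitting it directly.

#' Control parameters for GMDH fitting
#'
#' @param max_layers Maximum network depth (default 10).
#' @param neurons_kept Either `"adaptive"` (retain neurons whose validation
#'   criterion is at or below the layer median, minimum 2) or a fixed integer
#'   count per layer (>= 2). Adaptive retention is additionally capped at
#'   `max_width` neurons so the candidate count cannot grow combinatorially
#'   across layers.
#' @param max_width Cap on retained neurons per layer under adaptive
#'   retention; `NULL` (default) means the raw feature count at fit time.
#' @param min_improvement Minimum decrease in best validation MSE required to
#'   accept a new layer (default `1e-6`).
#' @param ridge_epsilon Ridge added to the normal equations when a pair's
#'   design matrix is rank-deficient (default `1e-8`).
#' @param seed Recorded for provenance (fitting itself is deterministic).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(max_layers = 10L, neurons_kept = "adaptive",
                       max_width = NULL, min_improvement = 1e-6,
                       ridge_epsilon = 1e-8, seed = 1L) {
  if (!is.numeric(max_layers) || max_layers < 1) {
    config_error("max_layers must be >= 1")
  }
  if (is.numeric(neurons_kept) && neurons_kept < 2) {
    config_error("fixed neurons_kept must be >= 2")
  }
  if (min_improvement < 0 || ridge_epsilon < 0) {
    config_error("min_improvement and ridge_epsilon must be non-negative")
  }
  structure(
    list(max_layers = as.integer(max_layers), neurons_kept = neurons_kept,
         max_width = max_width, min_improvement = min_improvement,
         ridge_epsilon = ridge_epsilon, seed = as.integer(seed)),
    class = "fit_config"
  )
}

#' Quadratic design row of a partial description
#'
#' @param xa,xb Finite numeric vectors (recycled scalars allowed).
#' @return Matrix with columns `[1, xa, xb, xa^2, xb^2, xa*xb]` in that fixed
#'   order; a single row when the inputs are scalars.
#' @examples
#' design_row(2, 3) # 1 2 3 4 9 6
#' @export
design_row <- function(xa, xb) {
  if (any(!is.finite(xa)) || any(!is.finite(xb))) {
    validation_error("design_row inputs must be finite")
  }
  cbind(1, xa, xb, xa^2, xb^2, xa * xb, deparse.level = 0)
}

#' Fit one partial description by least squares
#'
#' Solves for the six coefficients of the quadratic neuron minimizing the sum
#' of squared residuals, via QR factorization; if the design matrix is
#' rank-deficient (e.g. two binary inputs), the normal equations are solved
#' with a `ridge_epsilon` ridge instead. Deterministic.
#'
#' @param xa,xb,y Equal-length numeric columns, at least 6 samples.
#' @param ridge_epsilon Ridge used for rank-deficient designs.
#' @param input_a,input_b Input indices recorded on the neuron.
#' @return An object of class `partial_description` with fields `input_a`,
#'   `input_b`, `coefficients` (length 6), `criterion` (`NA` until scored).
#' @export
fit_partial_description <- function(xa, xb, y, ridge_epsilon = 1e-8,
                                    input_a = 1L, input_b = 2L) {
  n <- length(y)
  if (length(xa) != n || length(xb) != n) {
    validation_error("xa, xb, y must have equal length")
  }
  if (n < 6L) {
    insufficient_data_error("need at least 6 samples to fit 6 coefficients, got %d", n)
  }
  X <- design_row(xa, xb)
  qx <- qr(X)
  if (qx$rank == 6L) {
    beta <- qr.coef(qx, y)
  } else {
    XtX <- crossprod(X) + diag(ridge_epsilon, 6L)
    beta <- tryCatch(
      solve(XtX, crossprod(X, y))[, 1],
      error = function(e) degenerate_pair_error(
        "design matrix for pair (%d, %d) is singular even with ridge",
        input_a, input_b
      )
    )
    if (any(!is.finite(beta))) {
      degenerate_pair_error("non-finite coefficients for pair (%d, %d)",
                            input_a, input_b)
    }
  }
  structure(
    list(input_a = as.integer(input_a), input_b = as.integer(input_b),
         coefficients = unname(beta), criterion = NA_real_),
    class = "partial_description"
  )
}

pd_predict <- function(pd, xa, xb) {
  as.vector(design_row(xa, xb) %*% pd$coefficients)
}

#' Score a partial description on validation data
#'
#' The external selection criterion: mean squared error of the neuron's
#' predictions on held-out validation columns.
#'
#' @param pd A fitted `partial_description`.
#' @param xa,xb,y Validation columns (non-empty, equal length).
#' @return Non-negative scalar MSE.
#' @export
evaluate_criterion <- function(pd, xa, xb, y) {
  if (length(y) == 0L) validation_error("empty validation set")
  if (length(xa) != length(y) || length(xb) != length(y)) {
    validation_error("validation columns must have equal length")
  }
  mean((y - pd_predict(pd, xa, xb))^2)
}

#' Build one GMDH layer
#'
#' Fits a partial description for every pair of the `m` input columns
#' (`choose(m, 2)` candidates; degenerate pairs are skipped), scores each on
#' the validation columns, and retains neurons per the config: adaptive
#' (criterion at or below the layer median, minimum 2, capped at
#' `max_width`) or a fixed count. Ties in the criterion are broken by
#' lexicographic `(input_a, input_b)`; retained neurons are sorted by
#' ascending criterion.
#'
#' @param X_train,X_val Numeric matrices of input columns (train/validation).
#' @param y_train,y_val Target columns.
#' @param config A [fit_config()].
#' @param max_width Resolved width cap (used when `config$max_width` is
#'   `NULL`).
#' @return List of retained `partial_description`s, attribute `n_candidates`.
#' @export
build_layer <- function(X_train, y_train, X_val, y_val, config = fit_config(),
                        max_width = ncol(X_train)) {
  m <- ncol(X_train)
  if (m < 2L) validation_error("need at least 2 input columns, got %d", m)
  candidates <- list()
  for (a in seq_len(m - 1L)) {
    for (b in seq((a + 1L), m)) {
      pd <- tryCatch(
        fit_partial_description(X_train[, a], X_train[, b], y_train,
                                ridge_epsilon = config$ridge_epsilon,
                                input_a = a, input_b = b),
        burnoutGMDH_degenerate_pair_error = function(e) NULL
      )
      if (is.null(pd)) next
      pd$criterion <- evaluate_criterion(pd, X_val[, a], X_val[, b], y_val)
      if (!is.finite(pd$criterion)) next
      candidates[[length(candidates) + 1L]] <- pd
    }
  }
  if (length(candidates) == 0L) {
    degenerate_pair_error("all %d candidate pairs were degenerate", choose(m, 2))
  }
  crit <- vapply(candidates, `[[`, numeric(1), "criterion")
  ia <- vapply(candidates, `[[`, integer(1), "input_a")
  ib <- vapply(candidates, `[[`, integer(1), "input_b")
  ord <- order(crit, ia, ib)
  candidates <- candidates[ord]
  crit <- crit[ord]

  keep <- config$neurons_kept
  width_cap <- if (is.null(config$max_width)) max_width else config$max_width
  if (identical(keep, "adaptive")) {
    n_keep <- max(2L, sum(crit <= median(crit)))
    n_keep <- min(n_keep, width_cap, length(candidates))
  } else {
    n_keep <- min(as.integer(keep), length(candidates))
  }
  retained <- candidates[seq_len(n_keep)]
  attr(retained, "n_candidates") <- length(candidates)
  retained
}

# Outputs of every neuron in a layer.  Values are clamped to a large finite
# range so repeated squaring across layers cannot overflow to Inf/NaN on
# extrapolated inputs; on-scale predictions (labels live in [1, 2]) are
# unaffected.  Used identically during fitting and prediction.
layer_outputs <- function(layer, X) {
  out <- vapply(layer, function(pd) {
    pd_predict(pd, X[, pd$input_a], X[, pd$input_b])
  }, numeric(nrow(X)))
  out <- pmax(pmin(out, 1e6), -1e6)
  matrix(out, nrow = nrow(X))
}

#' Fit a self-organizing GMDH polynomial network
#'
#' Grows layers of quadratic partial descriptions: layer 1 takes the raw
#' features, every later layer the retained outputs of the previous layer.
#' A new layer is accepted only if its best validation criterion improves on
#' the previous layer's best by more than `min_improvement`; otherwise growth
#' stops and the best neuron of the last accepted layer becomes the model
#' output. Neurons not reachable from the output neuron are pruned, so the
#' surviving composition graph is exactly the fitted model and
#' [selected_features()] reads the automatically chosen raw inputs off it.
#'
#' @param X_train,y_train Training features (matrix, named columns) and
#'   numeric target (class labels 1/2 for classification use).
#' @param X_val,y_val External validation split used only for neuron
#'   selection and stopping, never for coefficient fitting.
#' @param feature_names Names of the raw input columns.
#' @param config A [fit_config()].
#' @param cutoff Classification threshold on the continuous output
#'   (default 1.5; predictions `<= cutoff` are class 1).
#' @return An object of class `gmdh_model`.
#' @export
fit_gmdh <- function(X_train, y_train, X_val, y_val,
                     feature_names = colnames(X_train),
                     config = fit_config(), cutoff = 1.5) {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  if (nrow(X_train) == 0L || nrow(X_val) == 0L) {
    insufficient_data_error("train and validation sets must be non-empty")
  }
  if (ncol(X_train) < 2L) validation_error("need at least 2 features")
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X_train)))
  width_cap <- ncol(X_train)

  layers <- list()
  layer_best <- numeric(0)
  cur_train <- X_train
  cur_val <- X_val
  for (depth in seq_len(config$max_layers)) {
    layer <- tryCatch(
      build_layer(cur_train, y_train, cur_val, y_val, config,
                  max_width = width_cap),
      burnoutGMDH_degenerate_pair_error = function(e) NULL
    )
    if (is.null(layer)) {
      if (depth == 1L) degenerate_pair_error("no valid neuron in the first layer")
      break
    }
    best <- layer[[1L]]$criterion
    if (depth > 1L && best >= layer_best[depth - 1L] - config$min_improvement) {
      break
    }
    layers[[depth]] <- layer
    layer_best[depth] <- best
    if (ncol(cur_train) < 2L) break
    cur_train <- layer_outputs(layer, cur_train)
    cur_val <- layer_outputs(layer, cur_val)
    if (ncol(cur_train) < 2L) break
  }

  model <- structure(
    list(feature_names = feature_names, layers = layers,
         output_neuron = c(layer = length(layers), neuron = 1L),
         layer_best = layer_best, cutoff = cutoff, class_labels = c(1L, 2L),
         config = config),
    class = "gmdh_model"
  )
  prune_model(model)
}

# Drop neurons unreachable from the output neuron and remap input indices.
prune_model <- function(model) {
  L <- length(model$layers)
  keep <- vector("list", L)
  keep[[L]] <- model$output_neuron[["neuron"]]
  if (L > 1L) {
    for (l in seq(L, 2L)) {
      parents <- model$layers[[l]][keep[[l]]]
      kids <- sort(unique(unlist(lapply(parents, function(pd) c(pd$input_a, pd$input_b)))))
      keep[[l - 1L]] <- kids
    }
  }
  for (l in seq_len(L)) {
    model$layers[[l]] <- model$layers[[l]][keep[[l]]]
  }
  # remap indices: layer l+1 neurons referenced positions in the old layer l
  if (L > 1L) {
    for (l in seq(2L, L)) {
      old_idx <- keep[[l - 1L]]
      model$layers[[l]] <- lapply(model$layers[[l]], function(pd) {
        pd$input_a <- match(pd$input_a, old_idx)
        pd$input_b <- match(pd$input_b, old_idx)
        pd
      })
    }
  }
  model$output_neuron <- c(layer = L, neuron = 1L)
  model
}
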