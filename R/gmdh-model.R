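# GMDH model methods -------------------------------------------------------

#' Continuous network output
#'
#' Evaluates the layered composition of partial descriptions on new data.
#'
#' @param model A fitted [fit_gmdh()] model.
#' @param X Numeric matrix with the model's raw feature count.
#' @return Numeric vector of continuous predictions (one per row).
#' @export
predict_continuous <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$feature_names)) {
    validation_error("X has %d columns, model expects %d features",
                     ncol(X), length(model$feature_names))
  }
  cur <- X
  for (layer in model$layers) {
    cur <- layer_outputs(layer, cur)
  }
  cur[, model$output_neuron[["neuron"]]]
}

#' Classify at the 1.5 cutoff
#'
#' The network regresses on the numeric labels `{1, 2}`; continuous outputs
#' at or below the cutoff (default 1.5) are class 1 (burnout present), above
#' it class 2 (absent).
#'
#' @inheritParams predict_continuous
#' @return Integer vector of labels in `{1, 2}`.
#' @export
classify <- function(model, X) {
  pred <- predict_continuous(model, X)
  ifelse(pred <= model$cutoff, model$class_labels[1], model$class_labels[2])
}

#' @export
predict.gmdh_model <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (type == "response") predict_continuous(object, newdata) else classify(object, newdata)
}

#' Raw features selected by the network
#'
#' Backtracks the composition graph from the output neuron to the raw
#' inputs; the reachable raw features are the network's automatic feature
#' selection.
#'
#' @param model A fitted [fit_gmdh()] model.
#' @return Character vector of raw feature names (in input order).
#' @export
selected_features <- function(model) {
  L <- length(model$layers)
  if (L == 0L) return(character(0))
  # After pruning every neuron is reachable, so the union of layer-1 inputs
  # is exactly the reachable raw feature set.
  idx <- sort(unique(unlist(lapply(model$layers[[1L]], function(pd) {
    c(pd$input_a, pd$input_b)
  }))))
  model$feature_names[idx]
}

#' @method print gmdh_model
#' @export
print.gmdh_model <- function(x, ...) {
  widths <- vapply(x$layers, length, integer(1))
  cat("GMDH polynomial network\n")
  cat(sprintf("  layers: %d (%s neurons after pruning)\n",
              length(x$layers), paste(widths, collapse = ", ")))
  cat(sprintf("  best validation MSE by layer: %s\n",
              paste(signif(x$layer_best, 4), collapse = ", ")))
  sel <- selected_features(x)
  cat(sprintf("  selected raw features (%d/%d): %s\n",
              length(sel), length(x$feature_names), paste(sel, collapse = ", ")))
  cat(sprintf("  classification cutoff: %g\n", x$cutoff))
  invisible(x)
}
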