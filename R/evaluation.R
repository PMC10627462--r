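# Evaluation: splits, confusion matrices, k-fold CV ------------------------

#' Random 70/15/15 train/validation/test split
#'
#' Train and validation sizes are `round(0.70 n)` and `round(0.15 n)`
#' (half-up); the remainder is the test set. Membership is random under the
#' seed and deterministic per seed.
#'
#' @param n Number of records (>= 10).
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `val`, `test` and the
#'   `seed`; class `data_split`.
#' @export
split_70_15_15 <- function(n, seed) {
  assert_scalar_number(n, "n")
  if (n < 10) insufficient_data_error("need at least 10 records to split, got %d", n)
  n_train <- round_half_up(0.70 * n)
  n_val <- round_half_up(0.15 * n)
  n_test <- n - n_train - n_val
  perm <- withr::with_seed(derive_seed(seed, "split"), sample.int(n))
  structure(
    list(train = sort(perm[seq_len(n_train)]),
         val = sort(perm[n_train + seq_len(n_val)]),
         test = sort(perm[n_train + n_val + seq_len(n_test)]),
         seed = as.integer(seed)),
    class = "data_split"
  )
}

#' Confusion matrix for 1/2 labels
#'
#' @param y_true,y_pred Equal-length vectors with labels in `{1, 2}`.
#' @return 2x2 integer matrix; rows are true class 1/2, columns predicted
#'   class 1/2.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    validation_error("y_true and y_pred must have equal length")
  }
  if (!all(c(y_true, y_pred) %in% c(1L, 2L))) {
    validation_error("labels must be in {1, 2}")
  }
  m <- matrix(0L, 2L, 2L,
              dimnames = list(true = c("1", "2"), predicted = c("1", "2")))
  for (i in 1:2) for (j in 1:2) {
    m[i, j] <- sum(y_true == i & y_pred == j)
  }
  m
}

#' Accuracy from a confusion matrix
#' @param cm A 2x2 confusion matrix.
#' @return Fraction of agreeing labels (trace over total).
#' @export
accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' Disjoint k folds
#'
#' Random partition of `1:n` into `K` folds whose sizes differ by at most
#' one; deterministic per seed.
#'
#' @param n Number of records.
#' @param K Number of folds (2 <= K <= n).
#' @param seed Integer seed.
#' @return List of `K` integer index vectors.
#' @export
kfold_indices <- function(n, K, seed) {
  if (K < 2) validation_error("K must be >= 2")
  if (n < K) validation_error("n (%d) must be >= K (%d)", n, K)
  sizes <- rep(n %/% K, K)
  extra <- n %% K
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  perm <- withr::with_seed(derive_seed(seed, "kfold"), sample.int(n))
  split(perm, rep(seq_len(K), sizes))[as.character(seq_len(K))] |>
    lapply(sort) |>
    unname()
}

#' Sample Pearson correlation
#'
#' Product-moment correlation with explicit precondition checks (length >= 3,
#' non-zero variance in both arguments).
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) validation_error("x and y must have equal length")
  if (length(x) < 3L) validation_error("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) {
    stop_burnout("burnoutGMDH_undefined_correlation_error",
                 "correlation undefined for zero-variance input")
  }
  cor(x, y)
}

#' Fit and evaluate one model on a 70/15/15 split
#'
#' @param cohort A cohort data frame with labels.
#' @param config A [fit_config()].
#' @param seed Split seed.
#' @return List with the fitted `model`, the `split`, per-split confusion
#'   matrices and accuracies; class `gmdh_evaluation`.
#' @export
evaluate_split <- function(cohort, config = fit_config(), seed = 1L) {
  X <- encode_features(cohort)
  y <- as.numeric(cohort$burnout_label)
  split <- split_70_15_15(nrow(X), seed)
  model <- fit_gmdh(X[split$train, , drop = FALSE], y[split$train],
                    X[split$val, , drop = FALSE], y[split$val],
                    feature_names = colnames(X), config = config)
  cms <- lapply(split[c("train", "val", "test")], function(idx) {
    confusion_matrix(y[idx], classify(model, X[idx, , drop = FALSE]))
  })
  structure(
    list(model = model, split = split, confusion = cms,
         accuracy = vapply(cms, accuracy, numeric(1)),
         selected_features = selected_features(model), seed = as.integer(seed)),
    class = "gmdh_evaluation"
  )
}

#' @method print gmdh_evaluation
#' @export
print.gmdh_evaluation <- function(x, ...) {
  cat("GMDH split evaluation\n")
  cat(sprintf("  accuracy  train %.3f | validation %.3f | test %.3f\n",
              x$accuracy[["train"]], x$accuracy[["val"]], x$accuracy[["test"]]))
  cat(sprintf("  selected features: %s\n", paste(x$selected_features, collapse = ", ")))
  invisible(x)
}

#' K-fold cross-validation of the full GMDH pipeline
#'
#' Each fold in turn is held out as the test set; the remainder is split
#' internally into training and validation parts in 70:15 proportion (the
#' validation part is the external criterion for neuron selection), a model
#' is fitted, and the held-out misclassification rate and selected feature
#' set are recorded. Whether every fold selected the same features is
#' reported as an observation, not enforced.
#'
#' @param cohort A labeled cohort data frame.
#' @param config A [fit_config()].
#' @param K Number of folds (default 20).
#' @param seed Integer seed; fold membership and the per-fold internal
#'   sub-splits derive from it.
#' @return Object of class `gmdh_cv` with `fold_errors`,
#'   `fold_features`, `features_agree`, and summary statistics.
#' @export
run_kfold <- function(cohort, config = fit_config(), K = 20L, seed = 1L) {
  X <- encode_features(cohort)
  y <- as.numeric(cohort$burnout_label)
  folds <- kfold_indices(nrow(X), K, seed)
  fold_errors <- numeric(K)
  fold_features <- vector("list", K)
  for (k in seq_len(K)) {
    test_idx <- folds[[k]]
    rest <- setdiff(seq_len(nrow(X)), test_idx)
    n_rest <- length(rest)
    n_train <- round_half_up(n_rest * 70 / 85)
    perm <- withr::with_seed(derive_seed(seed + 7919L * k, "split"),
                             sample(rest))
    tr <- perm[seq_len(n_train)]
    va <- perm[(n_train + 1L):n_rest]
    model <- fit_gmdh(X[tr, , drop = FALSE], y[tr],
                      X[va, , drop = FALSE], y[va],
                      feature_names = colnames(X), config = config)
    pred <- classify(model, X[test_idx, , drop = FALSE])
    fold_errors[k] <- mean(pred != y[test_idx])
    fold_features[[k]] <- selected_features(model)
  }
  agree <- length(unique(lapply(fold_features, sort))) == 1L
  structure(
    list(K = as.integer(K), seed = as.integer(seed),
         fold_errors = fold_errors, fold_features = fold_features,
         features_agree = agree,
         mean_error = mean(fold_errors), sd_error = stats::sd(fold_errors)),
    class = "gmdh_cv"
  )
}

#' @method print gmdh_cv
#' @export
print.gmdh_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$K))
  cat(sprintf("  misclassification: mean %.4f, sd %.4f, range [%.4f, %.4f]\n",
              x$mean_error, x$sd_error, min(x$fold_errors), max(x$fold_errors)))
  cat(sprintf("  identical feature set in every fold: %s\n", x$features_agree))
  invisible(x)
}
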