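# CSV / JSON / YAML interfaces and the end-to-end pipeline -----------------

#' Write a cohort to CSV
#'
#' Schema: `id,gender,marital_status,has_children,age,job_experience,
#' covid_stress,resilience,exhaustion,cynicism,professional_efficiency,
#' burnout_label`; UTF-8, comma separator, `.` decimal, lowercase category
#' strings, label as integer 1/2. Numeric columns are written at full
#' precision so a write/read round trip is lossless.
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_columns()]
  num_cols <- setdiff(CONTINUOUS_VARS, character(0))
  for (v in num_cols) df[[v]] <- format(df[[v]], digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Validates the full schema; every violation is reported with its row and
#' column (category values, score ranges, the 1/2 label coding, and the
#' experience-below-age rule).
#'
#' @param path Path to a cohort CSV (see [write_cohort_csv()]).
#' @return A `cohort` data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) schema_error("cohort file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing) > 0L) {
    schema_error("missing column(s): %s", paste(missing, collapse = ", "))
  }
  df <- df[, cohort_columns()]
  cats <- list(gender = c("female", "male"),
               marital_status = c("single", "married"),
               has_children = c("yes", "no"))
  for (col in names(cats)) {
    bad <- which(!(df[[col]] %in% cats[[col]]))
    if (length(bad) > 0L) {
      schema_error("row %d, column %s: invalid category '%s'",
                   bad[1], col, df[[col]][bad[1]])
    }
  }
  sup <- variable_support()
  for (v in CONTINUOUS_VARS) {
    x <- df[[v]]
    row <- sup[sup$variable == v, ]
    bad <- which(!is.finite(x) | x < row$lo | x > row$hi)
    if (length(bad) > 0L) {
      schema_error("row %d, column %s: value %s outside range [%g, %g]",
                   bad[1], v, format(x[bad[1]]), row$lo, row$hi)
    }
  }
  bad <- which(!(df$burnout_label %in% c(1L, 2L)))
  if (length(bad) > 0L) {
    schema_error("row %d, column burnout_label: label must be 1 or 2, got %s",
                 bad[1], format(df$burnout_label[bad[1]]))
  }
  bad <- which(df$job_experience >= df$age)
  if (length(bad) > 0L) {
    schema_error("row %d: job_experience %.2f not below age %.2f",
                 bad[1], df$job_experience[bad[1]], df$age[bad[1]])
  }
  df$burnout_label <- as.integer(df$burnout_label)
  class(df) <- c("cohort", "data.frame")
  df
}

MODEL_JSON_VERSION <- "1.0"

#' Serialize a GMDH model to JSON
#'
#' Versioned document with feature names, per-layer neurons (1-based input
#' indices, six coefficients at full precision, validation criterion), the
#' output-neuron reference, and the cutoff. [read_model_json()] reproduces
#' predictions bit for bit on the same platform.
#'
#' @param model A `gmdh_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    format = "burnoutGMDH model",
    version = MODEL_JSON_VERSION,
    feature_names = model$feature_names,
    cutoff = model$cutoff,
    class_labels = model$class_labels,
    layer_best = model$layer_best,
    output_neuron = as.list(model$output_neuron),
    layers = lapply(model$layers, function(layer) {
      lapply(layer, function(pd) {
        list(input_a = pd$input_a, input_b = pd$input_b,
             coefficients = pd$coefficients, criterion = pd$criterion)
      })
    })
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Load a GMDH model from JSON
#' @param path Path written by [write_model_json()].
#' @return A `gmdh_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) schema_error("model file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "burnoutGMDH model")) {
    schema_error("not a burnoutGMDH model JSON: %s", path)
  }
  layers <- lapply(doc$layers, function(layer) {
    lapply(layer, function(nd) {
      structure(
        list(input_a = as.integer(nd$input_a), input_b = as.integer(nd$input_b),
             coefficients = as.numeric(unlist(nd$coefficients)),
             criterion = as.numeric(nd$criterion)),
        class = "partial_description"
      )
    })
  })
  structure(
    list(feature_names = as.character(unlist(doc$feature_names)),
         layers = layers,
         output_neuron = c(layer = as.integer(doc$output_neuron$layer),
                           neuron = as.integer(doc$output_neuron$neuron)),
         layer_best = as.numeric(unlist(doc$layer_best)),
         cutoff = as.numeric(doc$cutoff),
         class_labels = as.integer(unlist(doc$class_labels)),
         config = NULL),
    class = "gmdh_model"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Flat key-value document mirroring the [cohort_config()] and
#' [fit_config()] fields plus evaluation settings. The shipped
#' `default_study.yaml` (in `inst/extdata`) encodes the published study's
#' calibration targets.
#'
#' @param path YAML file; `NULL` loads the packaged default.
#' @return List with elements `cohort`, `fit`, `evaluation`.
#' @export
read_pipeline_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_study.yaml", package = "burnoutGMDH")
  }
  if (!file.exists(path)) schema_error("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  cohort_args <- list(calibrate = TRUE)
  if (!is.null(raw$cohort)) {
    rc <- raw$cohort
    if (!is.null(rc$n_total)) cohort_args$n_total <- rc$n_total
    if (!is.null(rc$burnout_count)) cohort_args$burnout_count <- rc$burnout_count
    if (!is.null(rc$seed)) cohort_args$seed <- rc$seed
    if (!is.null(rc$calibrate)) cohort_args$calibrate <- rc$calibrate
    if (!is.null(rc$demographic_cells)) {
      cohort_args$demographic_cells <- as.data.frame(
        do.call(rbind, lapply(rc$demographic_cells, as.data.frame)),
        stringsAsFactors = FALSE
      )
    }
    if (!is.null(rc$mean_targets)) {
      mt <- do.call(rbind, lapply(rc$mean_targets, function(r) {
        data.frame(
          variable = r$variable,
          gender = if (is.null(r$gender)) NA_character_ else r$gender,
          marital_status = if (is.null(r$marital_status)) NA_character_ else r$marital_status,
          has_children = if (is.null(r$has_children)) NA_character_ else r$has_children,
          value = r$value, stringsAsFactors = FALSE
        )
      }))
      cohort_args$mean_targets <- mt
    }
    if (!is.null(rc$correlation_targets)) {
      cohort_args$correlation_targets <- unlist(rc$correlation_targets)
    }
  }
  fit_args <- if (is.null(raw$fit)) list() else raw$fit
  eval_cfg <- if (is.null(raw$evaluation)) list() else raw$evaluation
  if (is.null(eval_cfg$K)) eval_cfg$K <- 20L
  list(cohort_args = cohort_args, fit_args = fit_args, evaluation = eval_cfg)
}

#' Run the full generate / fit / evaluate / cross-validate pipeline
#'
#' Generates the synthetic cohort, fits a GMDH model on a 70/15/15 split,
#' evaluates confusion matrices on all three splits, runs K-fold
#' cross-validation, and writes `cohort.csv`, `model.json`, `report.json`,
#' and `manifest.json` to `out_dir`. Artifacts are reproducible byte for
#' byte from `(config, seed)`.
#'
#' @param config_path YAML pipeline configuration (`NULL` for the packaged
#'   default).
#' @param seed Top-level integer seed for every stage.
#' @param out_dir Output directory (created if needed).
#' @param run_cv Include the K-fold cross-validation stage.
#' @return The report list, invisibly; side effect: artifacts on disk.
#' @export
run_pipeline <- function(config_path = NULL, seed = 1L, out_dir = ".",
                         run_cv = TRUE) {
  stage <- "configuration"
  result <- tryCatch({
    pc <- read_pipeline_config(config_path)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "generate"
    t0 <- proc.time()[["elapsed"]]
    cohort_cfg <- do.call(cohort_config, pc$cohort_args)
    cohort <- generate_cohort(cohort_cfg, seed = seed)
    cohort_path <- file.path(out_dir, "cohort.csv")
    write_cohort_csv(cohort, cohort_path)
    t_gen <- proc.time()[["elapsed"]] - t0

    stage <- "fit"
    t0 <- proc.time()[["elapsed"]]
    fcfg <- do.call(fit_config, c(pc$fit_args, list(seed = seed)))
    ev <- evaluate_split(cohort, fcfg, seed = seed)
    model_path <- file.path(out_dir, "model.json")
    write_model_json(ev$model, model_path)
    t_fit <- proc.time()[["elapsed"]] - t0

    stage <- "crossval"
    t0 <- proc.time()[["elapsed"]]
    cv <- NULL
    if (isTRUE(run_cv)) {
      cv <- run_kfold(cohort, fcfg, K = as.integer(pc$evaluation$K), seed = seed)
    }
    t_cv <- proc.time()[["elapsed"]] - t0

    stage <- "report"
    report <- list(
      seed = as.integer(seed),
      selected_features = ev$selected_features,
      n_selected_features = length(ev$selected_features),
      accuracy = as.list(ev$accuracy),
      confusion = lapply(ev$confusion, function(m) {
        list(true_1 = as.integer(m[1, ]), true_2 = as.integer(m[2, ]))
      }),
      cross_validation = if (is.null(cv)) NULL else list(
        K = cv$K, fold_errors = cv$fold_errors,
        mean_error = cv$mean_error, sd_error = cv$sd_error,
        features_agree = cv$features_agree,
        fold_features = cv$fold_features
      )
    )
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    manifest <- list(
      seed = as.integer(seed),
      config = if (is.null(config_path)) "default_study.yaml" else basename(config_path),
      config_md5 = unname(tools::md5sum(
        if (is.null(config_path)) {
          system.file("extdata", "default_study.yaml", package = "burnoutGMDH")
        } else config_path
      )),
      artifacts = c("cohort.csv", "model.json", "report.json")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    message(sprintf(
      "pipeline complete: generate %.2fs, fit %.2fs, crossval %.2fs; %d features selected",
      t_gen, t_fit, t_cv, length(ev$selected_features)
    ))
    report
  }, burnoutGMDH_error = function(e) {
    stop_burnout("burnoutGMDH_pipeline_error",
                 "pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}
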