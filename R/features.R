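# Feature encoding --------------------------------------------------------

#' Fixed model feature order
#' @return Character vector of the ten raw feature names, in network input
#'   order.
#' @export
feature_names <- function() {
  c("gender", "age", "marital_status", "has_children", "job_experience",
    "covid_stress", "resilience", "exhaustion", "cynicism",
    "professional_efficiency")
}

#' Encode respondents as a numeric feature matrix
#'
#' Maps the three nominal variables to 0/1 (`female`/`single`/`no` are the
#' zero reference levels) and passes the continuous scores through unchanged,
#' in the fixed order of [feature_names()].
#'
#' @param cohort A cohort data frame (label column optional).
#' @return Numeric matrix with one row per respondent and ten named columns.
#' @export
encode_features <- function(cohort) {
  enc_cat <- function(x, levels, col) {
    bad <- !(x %in% levels)
    if (any(bad)) {
      validation_error("unknown %s value '%s'", col, x[which(bad)[1]])
    }
    as.numeric(x == levels[2])
  }
  X <- cbind(
    gender = enc_cat(cohort$gender, c("female", "male"), "gender"),
    age = as.numeric(cohort$age),
    marital_status = enc_cat(cohort$marital_status, c("single", "married"), "marital_status"),
    has_children = enc_cat(cohort$has_children, c("no", "yes"), "has_children"),
    job_experience = as.numeric(cohort$job_experience),
    covid_stress = as.numeric(cohort$covid_stress),
    resilience = as.numeric(cohort$resilience),
    exhaustion = as.numeric(cohort$exhaustion),
    cynicism = as.numeric(cohort$cynicism),
    professional_efficiency = as.numeric(cohort$professional_efficiency)
  )
  if (any(!is.finite(X))) validation_error("non-finite value in encoded features")
  X
}

#' Decode the categorical columns of an encoded feature matrix
#'
#' Inverse of [encode_features()] on the three nominal columns (continuous
#' columns are returned unchanged).
#'
#' @param X Matrix from [encode_features()].
#' @return Data frame with categorical string columns restored.
#' @export
decode_features <- function(X) {
  data.frame(
    gender = ifelse(X[, "gender"] == 1, "male", "female"),
    age = X[, "age"],
    marital_status = ifelse(X[, "marital_status"] == 1, "married", "single"),
    has_children = ifelse(X[, "has_children"] == 1, "yes", "no"),
    job_experience = X[, "job_experience"],
    covid_stress = X[, "covid_stress"],
    resilience = X[, "resilience"],
    exhaustion = X[, "exhaustion"],
    cynicism = X[, "cynicism"],
    professional_efficiency = X[, "professional_efficiency"],
    stringsAsFactors = FALSE
  )
}
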