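## Plain-CSV and YAML interfaces: subjects.csv (subject_id, sex, age),
## exposures.csv in long format (subject_id, subscale, age, score),
## outcomes.csv, predictors.csv, and a YAML serialization of the synthetic
## spec including its seed.

#' Write a generated cohort to CSV files
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- cohort$outcomes[, c("subject_id", "sex", "age")]
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             exposures = file.path(dir, "exposures.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             predictors = file.path(dir, "predictors.csv"))
  utils::write.csv(subjects, paths["subjects"], row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$exposures), paths["exposures"], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths["outcomes"], row.names = FALSE)
  utils::write.csv(cohort$predictors, paths["predictors"], row.names = FALSE)
  invisible(paths)
}

#' Read a long-format exposure table
#'
#' @param path CSV with columns `subject_id`, `subscale`, `age`, `score`.
#' @return `mace_exposures` data frame.
#' @export
read_exposures <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "subscale", "age", "score")
  if (!all(need %in% names(out)))
    stop("exposures file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  class(out) <- c("mace_exposures", "data.frame")
  out
}

#' Read an outcome table
#'
#' @param path CSV with T-score and diagnosis columns.
#' @return data frame.
#' @export
read_outcomes <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Serialize a synthetic spec to YAML (including the seed)
#'
#' @param spec a [synthetic_spec()].
#' @param path output file.
#' @export
write_spec <- function(spec, path) {
  s <- unclass(spec)
  s$prevalence_curve <- apply(spec$prevalence_curve, 1, as.numeric, simplify = FALSE)
  s$co_occurrence <- apply(spec$co_occurrence, 1, as.numeric, simplify = FALSE)
  s$effect_map <- as.list(spec$effect_map)
  s$logistic_intercept <- as.list(spec$logistic_intercept)
  yaml::write_yaml(s, path, precision = 15L)
}

#' Read a synthetic spec from YAML
#'
#' @param path file written by [write_spec()].
#' @return a validated [synthetic_spec()].
#' @export
read_spec <- function(path) {
  s <- yaml::read_yaml(path)
  pc <- do.call(rbind, lapply(s$prevalence_curve, as.numeric))
  dimnames(pc) <- list(MACE_SUBSCALES, paste0("age_", MACE_AGES))
  co <- do.call(rbind, lapply(s$co_occurrence, as.numeric))
  dimnames(co) <- list(MACE_SUBSCALES, MACE_SUBSCALES)
  synthetic_spec(
    n_subjects = s$n_subjects, prevalence_curve = pc,
    persistence = s$persistence, co_occurrence = co,
    severity_given_exposure = s$severity_given_exposure,
    effect_map = unlist(s$effect_map) %||% numeric(0),
    noise_sd = s$noise_sd,
    logistic_intercept = unlist(s$logistic_intercept),
    logistic_slope = s$logistic_slope, sex_ratio = s$sex_ratio,
    age_mean = s$age_mean, age_sd = s$age_sd, seed = s$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
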