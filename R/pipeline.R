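## End-to-end orchestration: simulate (or load) a cohort, score it, estimate
## importance per outcome, calibrate against the reshuffled-outcome null,
## compare global vs specific measures, and validate selected predictors
## against diagnosis status.

OUTCOME_COLUMNS <- c(total = "t_total",
                     internalizing = "t_internalizing",
                     externalizing = "t_externalizing")
DX_COLUMNS <- c(total = "dx_any",
                internalizing = "dx_internalizing",
                externalizing = "dx_externalizing")

#' Pipeline run configuration
#'
#' @param spec optional [synthetic_spec()]; when supplied the pipeline runs
#'   in simulate mode, otherwise `exposures_path` / `outcomes_path` must
#'   point to existing CSV files.
#' @param exposures_path,outcomes_path input CSVs for non-simulate mode.
#' @param forest a [forest_config()]; its seed is overridden per outcome by a
#'   counter scheme derived from `seed`, so adding an outcome never perturbs
#'   the others.
#' @param thresholds a [threshold_table()].
#' @param n_null_reps outcome reshuffles per outcome (full fidelity 5000).
#' @param null_split_reps splits per null replicate (see [build_null()]).
#' @param alpha significance level.
#' @param outcomes subset of `c("total", "internalizing", "externalizing")`.
#' @param seed master seed recorded in every output.
#' @return object of class `mace_run_config`.
#' @export
run_config <- function(spec = NULL, exposures_path = NULL, outcomes_path = NULL,
                       forest = forest_config(), thresholds = threshold_table(),
                       n_null_reps = 500, null_split_reps = 2, alpha = 0.05,
                       outcomes = c("total", "internalizing", "externalizing"),
                       seed = 1L) {
  bad <- setdiff(outcomes, names(OUTCOME_COLUMNS))
  if (length(bad) > 0)
    stop("unknown outcome(s): ", paste(bad, collapse = ", "),
         "; valid choices are: ", paste(names(OUTCOME_COLUMNS), collapse = ", "),
         call. = FALSE)
  if (is.null(spec)) {
    if (is.null(exposures_path) || is.null(outcomes_path) ||
        !file.exists(exposures_path) || !file.exists(outcomes_path))
      stop("non-simulate mode needs existing exposures_path and outcomes_path",
           call. = FALSE)
  }
  structure(list(spec = spec, exposures_path = exposures_path,
                 outcomes_path = outcomes_path, forest = forest,
                 thresholds = thresholds, n_null_reps = n_null_reps,
                 null_split_reps = null_split_reps, alpha = alpha,
                 outcomes = outcomes, seed = as.integer(seed)),
            class = "mace_run_config")
}

#' Run the full analysis pipeline
#'
#' Writes, per outcome, `vi_table_<outcome>.csv` and
#' `vi_profile_<outcome>.csv`; plus `glm_results.csv`, `descriptives.csv`,
#' `prevalence.csv`, and a `manifest.json` with the seed and config hash.
#' Reruns with an identical configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the per-outcome VI tables, competitive
#'   comparisons, GLM results, and descriptives.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "mace_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$spec)) {
    cohort <- generate_cohort(config$spec, thresholds = config$thresholds)
    exposures <- cohort$exposures
    outcomes_df <- cohort$outcomes
    predictors <- cohort$predictors
  } else {
    exposures <- read_exposures(config$exposures_path)
    outcomes_df <- read_outcomes(config$outcomes_path)
    predictors <- build_predictor_matrix(exposures, subjects = outcomes_df,
                                         thresholds = config$thresholds)
  }

  x <- predictors[, setdiff(names(predictors), "subject_id")]
  vi_tables <- list(); comparisons <- list(); glms <- list(); desc <- list()

  for (i in seq_along(config$outcomes)) {
    oc <- config$outcomes[i]
    ## per-outcome seed: counter scheme on the outcome label, not the loop
    ## index, so the seed stream is stable under outcome subsetting
    oc_index <- match(oc, names(OUTCOME_COLUMNS))
    fc <- config$forest
    fc$seed <- derive_seed(config$seed, "outcome", oc_index)
    y <- outcomes_df[[OUTCOME_COLUMNS[[oc]]]]

    vi <- estimate_vi(x, y, fc)
    null <- build_null(x, y, fc, n_null_reps = config$n_null_reps,
                       null_split_reps = config$null_split_reps)
    tab <- vi_table(vi, null, alpha = config$alpha)
    vi_tables[[oc]] <- tab
    comparisons[[oc]] <- competitive_compare(tab)

    utils::write.csv(as.data.frame(tab),
                     file.path(out_dir, paste0("vi_table_", oc, ".csv")),
                     row.names = FALSE)
    utils::write.csv(render_vi_profile(tab),
                     file.path(out_dir, paste0("vi_profile_", oc, ".csv")),
                     row.names = FALSE)

    ## validate the strongest significant predictor per type, plus the
    ## significant global measures, against the matching diagnosis status
    dx <- DX_COLUMNS[[oc]]
    sel <- select_top_per_type(tab)$predictor
    sel <- c(sel, tab$predictor[tab$predictor %in% GLOBAL_MEASURES &
                                  !is.na(tab$significant) & tab$significant])
    glm_data <- cbind(predictors, outcomes_df[, setdiff(names(outcomes_df),
                                                        names(predictors))])
    if (length(unique(outcomes_df[[dx]])) == 2) {
      for (pr in sel)
        glms[[paste(oc, pr)]] <- cbind(analysis_outcome = oc,
                                       as.data.frame(fit_disorder_glm(glm_data, pr, dx)))
    }

    ## descriptive group contrast: T-scores by diagnosis status
    g1 <- y[outcomes_df[[dx]] == 0]; g2 <- y[outcomes_df[[dx]] == 1]
    if (length(g1) >= 2 && length(g2) >= 2 && stats::sd(g1) > 0 && stats::sd(g2) > 0) {
      wc <- welch_cohen(mean(g1), stats::sd(g1), length(g1),
                        mean(g2), stats::sd(g2), length(g2))
      desc[[oc]] <- data.frame(outcome = oc, n_no_dx = length(g1),
                               n_dx = length(g2), mean_no_dx = mean(g1),
                               mean_dx = mean(g2), t = wc$t, df = wc$df,
                               p = wc$p, d = wc$d)
    }
  }

  glm_results <- if (length(glms) > 0) do.call(rbind, glms) else data.frame()
  descriptives <- if (length(desc) > 0) do.call(rbind, desc) else data.frame()
  rownames(glm_results) <- NULL; rownames(descriptives) <- NULL
  utils::write.csv(glm_results, file.path(out_dir, "glm_results.csv"),
                   row.names = FALSE)
  utils::write.csv(descriptives, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(prevalence_by_age(exposures, config$thresholds),
                   file.path(out_dir, "prevalence.csv"), row.names = FALSE)

  manifest <- list(seed = config$seed,
                   outcomes = as.list(config$outcomes),
                   alpha = config$alpha,
                   n_null_reps = config$n_null_reps,
                   null_split_reps = config$null_split_reps,
                   forest = unclass(config$forest),
                   config_hash = config_hash(config),
                   simulate_mode = !is.null(config$spec),
                   package_version = as.character(utils::packageVersion("maceforest")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(out_dir, "manifest.json"))

  invisible(list(vi_tables = vi_tables, comparisons = comparisons,
                 glm_results = glm_results, descriptives = descriptives))
}

#' Tidy long-format importance profile for plotting
#'
#' One row per predictor with its class (`type_age`, `global`, `covariate`),
#' CM type, and age; global measures and covariates carry `NA` age and are
#' suitable as age-invariant reference rows.
#'
#' @param table a [vi_table()].
#' @return data frame `predictor`, `class`, `type`, `age`, `vi_mean`, `z`,
#'   `p`, `significant`, ordered type-by-age first (by type then age), then
#'   global measures, then covariates; ordering is deterministic.
#' @export
render_vi_profile <- function(table) {
  cls <- predictor_class(table$predictor)
  type <- ifelse(cls == "type_age", sub("_\\d{2}$", "", table$predictor),
                 table$predictor)
  age <- rep(NA_integer_, nrow(table))
  age[cls == "type_age"] <-
    as.integer(sub("^.*_(\\d{2})$", "\\1", table$predictor[cls == "type_age"]))
  out <- data.frame(predictor = table$predictor, class = cls, type = type,
                    age = age, vi_mean = table$vi_mean, z = table$z,
                    p = table$p, significant = table$significant,
                    stringsAsFactors = FALSE)
  ord <- order(match(cls, c("type_age", "global", "covariate")),
               match(type, c(MACE_TYPES, GLOBAL_MEASURES)), age, out$predictor)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
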