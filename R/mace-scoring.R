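## Scoring of exposure chronologies into the predictor set used by the
## forests: weighted type-by-age scores (ages 3-18 after the
## infantile-amnesia exclusion) plus the three global burden indices.

#' Per-subscale exposure thresholds
#'
#' A subscale-year (or a subscale overall) counts as exposed when its
#' weighted severity exceeds the threshold. Published validation thresholds
#' can be supplied; the default is 0.5 for every subscale, i.e. any
#' non-negligible score on the 0-10 scale counts.
#'
#' @param values numeric vector of length 10 in `[0, 10]`, optionally named
#'   by subscale (order of [MACE_SUBSCALES] otherwise).
#' @return named numeric vector of class `mace_thresholds`.
#' @export
threshold_table <- function(values = rep(0.5, 10)) {
  if (length(values) != 10)
    stop("threshold_table needs one threshold per each of the 10 subscales",
         call. = FALSE)
  if (any(values < 0 | values > 10))
    stop("thresholds must lie in [0, 10]", call. = FALSE)
  if (is.null(names(values))) names(values) <- MACE_SUBSCALES
  if (!setequal(names(values), MACE_SUBSCALES))
    stop("threshold names must match the 10 MACE subscales", call. = FALSE)
  structure(values[MACE_SUBSCALES], class = "mace_thresholds")
}

#' Read a threshold table from a key/value config file
#'
#' @param path YAML file mapping subscale names to thresholds.
#' @return a [threshold_table()].
#' @export
read_thresholds <- function(path) {
  threshold_table(unlist(yaml::read_yaml(path)))
}

## exposures long df -> n x 10 x 18 array (subjects sorted)
exposures_array <- function(exposures) {
  stopifnot(all(c("subject_id", "subscale", "age", "score") %in% names(exposures)))
  bad <- setdiff(unique(exposures$subscale), MACE_SUBSCALES)
  if (length(bad) > 0)
    stop("unknown subscale label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(exposures$score < 0 | exposures$score > 10))
    stop("exposure scores must lie in [0, 10]", call. = FALSE)
  ids <- sort(unique(exposures$subject_id))
  arr <- array(0, dim = c(length(ids), 10, 18),
               dimnames = list(NULL, MACE_SUBSCALES, paste0("age_", MACE_AGES)))
  i <- match(exposures$subject_id, ids)
  j <- match(exposures$subscale, MACE_SUBSCALES)
  k <- match(exposures$age, MACE_AGES)
  keep <- !is.na(k)
  arr[cbind(i[keep], j[keep], k[keep])] <- exposures$score[keep]
  attr(arr, "subject_id") <- ids
  arr
}

#' Aggregate subscale chronologies to the four CM types
#'
#' Each type-year score is the mean of its constituent subscale-year scores
#' (ABUSE: 5 subscales, NEGLECT: 2, PEER: 2, SEXA: 1), which preserves the
#' `[0, 10]` range so the four types stay comparable.
#'
#' @param exposures long exposure data frame (see [generate_exposures()]).
#' @param agg aggregation rule, `"mean"` (default) or `"max"`.
#' @return long data frame `subject_id`, `type`, `age`, `score`.
#' @export
aggregate_to_types <- function(exposures, agg = c("mean", "max")) {
  agg <- match.arg(agg)
  arr <- exposures_array(exposures)
  ids <- attr(arr, "subject_id")
  n <- length(ids)
  out <- vector("list", length(MACE_TYPES))
  for (ti in seq_along(MACE_TYPES)) {
    ty <- MACE_TYPES[ti]
    subs <- names(MACE_TYPE_MAP)[MACE_TYPE_MAP == ty]
    block <- arr[, subs, , drop = FALSE]  # n x |subs| x 18
    sc <- apply(block, c(1, 3), if (agg == "mean") mean else max)  # n x 18
    out[[ti]] <- data.frame(
      subject_id = rep(ids, times = 18),
      type = ty,
      age = rep(MACE_AGES, each = n),
      score = as.vector(sc),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$subject_id, match(res$type, MACE_TYPES), res$age), ]
  rownames(res) <- NULL
  res
}

#' Drop the unreliable infancy years from a type-by-age table
#'
#' Retrospective reports for ages 1-2 are excluded from the predictors
#' (infantile amnesia); the global indices keep their own age window.
#' Idempotent on already-restricted input.
#'
#' @param type_scores long table from [aggregate_to_types()].
#' @param keep_ages ages retained (default 3-18).
#' @return the table restricted to `keep_ages`.
#' @export
exclude_infantile_years <- function(type_scores, keep_ages = PREDICTOR_AGES) {
  out <- type_scores[type_scores$age %in% keep_ages, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## per-subscale overall severity: mean of the per-year scores over `ages`
subscale_overall <- function(arr, ages) {
  apply(arr[, , ages, drop = FALSE], c(1, 2), mean)  # n x 10, each in [0,10]
}

#' Global severity index (SEVERITY, 0-100)
#'
#' Sum over the 10 subscales of each subscale's overall severity (the mean of
#' its per-year weighted scores over the age window).
#'
#' @param exposures long exposure data frame.
#' @param ages age window (default 1-18; the infancy exclusion applies to the
#'   type-by-age predictors, not the global indices).
#' @return numeric vector, one value in `[0, 100]` per subject.
#' @export
compute_severity <- function(exposures, ages = MACE_AGES) {
  arr <- exposures_array(exposures)
  unname(rowSums(subscale_overall(arr, ages)))
}

#' Global multiplicity index (MULTI, 0-10)
#'
#' Number of the 10 subscales whose overall severity exceeds its threshold.
#'
#' @inheritParams compute_severity
#' @param thresholds a [threshold_table()].
#' @return integer vector in `0..10`.
#' @export
compute_multiplicity <- function(exposures, thresholds = threshold_table(),
                                 ages = MACE_AGES) {
  arr <- exposures_array(exposures)
  ov <- subscale_overall(arr, ages)
  as.integer(rowSums(sweep(ov, 2, unclass(thresholds)[colnames(ov)], `>`)))
}

#' Global duration index (DURATION, 0-18)
#'
#' Number of age-years in which at least one subscale-year score exceeds its
#' threshold.
#'
#' @inheritParams compute_multiplicity
#' @return integer vector in `0..18`.
#' @export
compute_duration <- function(exposures, thresholds = threshold_table(),
                             ages = MACE_AGES) {
  arr <- exposures_array(exposures)
  th <- unclass(thresholds)[dimnames(arr)[[2]]]
  over <- sweep(arr[, , ages, drop = FALSE], 2, th, `>`)
  any_year <- apply(over, c(1, 3), any)  # n x |ages|
  as.integer(rowSums(any_year))
}

#' Above-threshold exposure prevalence by type and age
#'
#' Proportion of subjects with at least one constituent subscale above its
#' threshold, per CM type and age.
#'
#' @inheritParams compute_multiplicity
#' @param level `"type"` (default) or `"subscale"`.
#' @return long data frame `type` (or `subscale`), `age`, `prevalence`.
#' @export
prevalence_by_age <- function(exposures, thresholds = threshold_table(),
                              level = c("type", "subscale")) {
  level <- match.arg(level)
  if (nrow(exposures) == 0 || length(unique(exposures$subject_id)) == 0)
    stop("prevalence_by_age: empty cohort", call. = FALSE)
  arr <- exposures_array(exposures)
  th <- unclass(thresholds)[dimnames(arr)[[2]]]
  over <- sweep(arr, 2, th, `>`)
  if (level == "subscale") {
    pr <- apply(over, c(2, 3), mean)  # 10 x 18
    out <- data.frame(subscale = rep(rownames(pr), times = 18),
                      age = rep(MACE_AGES, each = 10),
                      prevalence = as.vector(pr))
  } else {
    res <- lapply(MACE_TYPES, function(ty) {
      subs <- names(MACE_TYPE_MAP)[MACE_TYPE_MAP == ty]
      anyexp <- apply(over[, subs, , drop = FALSE], c(1, 3), any)
      data.frame(type = ty, age = MACE_AGES, prevalence = colMeans(anyexp))
    })
    out <- do.call(rbind, res)
  }
  rownames(out) <- NULL
  out
}

#' Build the predictor matrix consumed by the forest engine
#'
#' One row per subject: 64 type-by-age weighted scores (`ABUSE_03` ...
#' `SEXA_18`), the three global indices `SEVERITY`, `MULTI`, `DURATION`, and
#' optionally `sex`/`age` covariates when a subject table is supplied.
#'
#' @param exposures long exposure data frame.
#' @param subjects optional data frame with `subject_id`, `sex`, `age`.
#' @param thresholds a [threshold_table()].
#' @param predictor_ages ages retained as type-by-age predictors (default
#'   3-18, the infantile-amnesia exclusion).
#' @param global_ages age window for the global indices (default 1-18).
#' @param agg type aggregation rule passed to [aggregate_to_types()].
#' @return data frame with `subject_id` plus 64 + 3 (+ 2) predictor columns.
#' @export
build_predictor_matrix <- function(exposures, subjects = NULL,
                                   thresholds = threshold_table(),
                                   predictor_ages = PREDICTOR_AGES,
                                   global_ages = MACE_AGES,
                                   agg = "mean") {
  ts <- exclude_infantile_years(aggregate_to_types(exposures, agg = agg),
                                keep_ages = predictor_ages)
  ids <- sort(unique(exposures$subject_id))
  wide <- data.frame(subject_id = ids)
  for (ty in MACE_TYPES) {
    for (a in predictor_ages) {
      col <- sprintf("%s_%02d", ty, a)
      sel <- ts[ts$type == ty & ts$age == a, ]
      wide[[col]] <- sel$score[match(ids, sel$subject_id)]
    }
  }
  wide$SEVERITY <- compute_severity(exposures, ages = global_ages)
  wide$MULTI    <- compute_multiplicity(exposures, thresholds, ages = global_ages)
  wide$DURATION <- compute_duration(exposures, thresholds, ages = global_ages)
  if (!is.null(subjects)) {
    m <- match(ids, subjects$subject_id)
    wide$sex <- subjects$sex[m]
    wide$age <- subjects$age[m]
  }
  wide
}

#' Proportion of subjects with any CM type above threshold
#'
#' @inheritParams compute_multiplicity
#' @return scalar proportion in `[0, 1]`.
#' @export
any_cm_prevalence <- function(exposures, thresholds = threshold_table(),
                              ages = MACE_AGES) {
  mean(compute_multiplicity(exposures, thresholds, ages) > 0)
}
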