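## Permute-and-refit variable importance.
##
## For one train/test split, the importance of predictor j is
##   dMSE_j = MSE_test(forest refit after permuting column j across the whole
##            cohort) - MSE_test(forest fit on intact data),
## both forests sharing the split, the tree seed, and every hyperparameter.
## Importances are averaged over `n_split_reps` random 75/25 splits.
## Negative dMSE from sampling noise is retained so the null stays unbiased.

#' Forest and resampling configuration
#'
#' @param n_trees trees per forest.
#' @param predictors_per_node candidate predictors at each node; `NULL` means
#'   `ceiling(sqrt(p))`. A fraction in (0,1) is interpreted as a share of p.
#' @param min_node_size minimal terminal node size.
#' @param split_criterion `"maxstat"` (default; unbiased association-test
#'   splits in the conditional-inference style) or `"variance"`.
#' @param train_fraction share of subjects in the training set (default 0.75).
#' @param n_split_reps number of random train/test splits averaged (default
#'   100).
#' @param seed integer master seed for splits, permutations, and trees.
#' @return object of class `mace_forest_config`.
#' @export
forest_config <- function(n_trees = 500, predictors_per_node = NULL,
                          min_node_size = 5,
                          split_criterion = c("maxstat", "variance"),
                          train_fraction = 0.75, n_split_reps = 100,
                          seed = 1L) {
  split_criterion <- match.arg(split_criterion)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  if (n_trees < 1 || min_node_size < 1 || n_split_reps < 1)
    stop("counts in forest_config must be positive", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees),
                 predictors_per_node = predictors_per_node,
                 min_node_size = as.integer(min_node_size),
                 split_criterion = split_criterion,
                 train_fraction = train_fraction,
                 n_split_reps = as.integer(n_split_reps),
                 seed = as.integer(seed)),
            class = "mace_forest_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

as_predictor_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), "subject_id"), drop = FALSE]
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) stop("predictors must be numeric", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

#' Draw one train/test split
#'
#' @param n cohort size (or a data frame / matrix whose rows are subjects).
#' @param config a [forest_config()].
#' @param rep_index which split replicate (1-based); the partition is a
#'   deterministic function of `(seed, rep_index)`.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive; `ceiling(train_fraction * n)` training rows).
#' @export
split_train_test <- function(n, config, rep_index = 1L) {
  if (!is.numeric(n) || length(n) > 1) n <- nrow(n)
  if (n < 8) stop("cohort too small to split (need >= 8 subjects)", call. = FALSE)
  set.seed(derive_seed(config$seed, "split", rep_index))
  n_train <- ceiling(config$train_fraction * n)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Fit a regression forest
#'
#' Thin wrapper around [ranger::ranger()] satisfying a plain
#' predict-on-matrix contract; a constant outcome short-circuits to a
#' constant predictor (no trees needed).
#'
#' @param x predictor matrix or data frame (training rows).
#' @param y numeric outcome (training rows).
#' @param config a [forest_config()].
#' @param seed tree seed; defaults to `config$seed`.
#' @return object of class `mace_forest` with a [predict()] method.
#' @export
fit_forest <- function(x, y, config = forest_config(), seed = config$seed) {
  x <- as_predictor_matrix(x)
  if (anyNA(x) || anyNA(y))
    stop("missing values in predictors or outcome; impute or drop before fitting",
         call. = FALSE)
  if (stats::var(y) == 0) {
    fit <- list(constant = y[1])
  } else {
    p <- ncol(x)
    mtry <- config$predictors_per_node
    if (is.null(mtry)) mtry <- ceiling(sqrt(p))
    else if (mtry < 1) mtry <- max(1L, ceiling(mtry * p))
    args <- list(x = x, y = y, num.trees = config$n_trees,
                 mtry = min(as.integer(mtry), p),
                 min.node.size = config$min_node_size,
                 num.threads = 1L, seed = seed)
    if (config$split_criterion == "maxstat") {
      args$splitrule <- "maxstat"; args$alpha <- 0.5; args$minprop <- 0.1
    }
    fit <- list(ranger = do.call(ranger::ranger, args))
  }
  structure(list(fit = fit, config = config), class = "mace_forest")
}

#' @export
predict.mace_forest <- function(object, newdata, ...) {
  newdata <- as_predictor_matrix(newdata)
  if (!is.null(object$fit$constant))
    return(rep(object$fit$constant, nrow(newdata)))
  stats::predict(object$fit$ranger, data = newdata, num.threads = 1L)$predictions
}

## Core kernel: dMSE for every predictor on one split.
## Returns a p-vector. The intact forest is fit once; each permuted refit
## reuses the same split and tree seed so the only difference is the broken
## predictor-outcome association.
vi_one_split <- function(x, y, config, split_seed, perm_seed) {
  n <- nrow(x)
  set.seed(split_seed)
  n_train <- ceiling(config$train_fraction * n)
  train <- sample.int(n, n_train)
  test <- setdiff(seq_len(n), train)

  base <- fit_forest(x[train, , drop = FALSE], y[train], config, seed = split_seed)
  mse0 <- mean((y[test] - predict(base, x[test, , drop = FALSE]))^2)

  p <- ncol(x)
  out <- numeric(p)
  for (j in seq_len(p)) {
    colj <- x[, j]
    if (length(unique(colj)) == 1L) { out[j] <- 0; next }  # permutation is identity
    set.seed(derive_seed(perm_seed, "perm", j))
    xp <- x
    xp[, j] <- colj[sample.int(n)]   # shuffled over the full cohort
    fj <- fit_forest(xp[train, , drop = FALSE], y[train], config, seed = split_seed)
    out[j] <- mean((y[test] - predict(fj, xp[test, , drop = FALSE]))^2) - mse0
  }
  names(out) <- colnames(x)
  out
}

#' Permute-and-refit importance of one predictor on one split
#'
#' @param x predictor matrix or data frame (full cohort).
#' @param y numeric outcome (full cohort).
#' @param predictor column name.
#' @param config a [forest_config()].
#' @param rep_index split replicate index.
#' @return scalar dMSE (may be negative by sampling noise).
#' @export
permute_refit_delta <- function(x, y, predictor, config = forest_config(),
                                rep_index = 1L) {
  x <- as_predictor_matrix(x)
  if (!predictor %in% colnames(x))
    stop("predictor not found: ", predictor, call. = FALSE)
  split_seed <- derive_seed(config$seed, "split", rep_index)
  perm_seed <- derive_seed(config$seed, "permbase", rep_index)
  vi_one_split(x, y, config, split_seed, perm_seed)[[predictor]]
}

#' Estimate variable importance for every predictor
#'
#' Runs the permute-and-refit procedure on `n_split_reps` random
#' train/test splits and averages the per-split dMSE values.
#'
#' @param x predictor matrix or data frame (a `subject_id` column is
#'   dropped); covariates such as `sex` and `age` are treated like any other
#'   predictor.
#' @param y numeric outcome vector.
#' @param config a [forest_config()].
#' @return object of class `mace_vi`: data frame `predictor`, `vi_mean`, with
#'   the per-split matrix in `attr(, "vi_per_rep")` (p x n_split_reps) and
#'   the configuration hash in `attr(, "config_hash")`.
#' @export
estimate_vi <- function(x, y, config = forest_config()) {
  x <- as_predictor_matrix(x)
  if (anyNA(x) || anyNA(y))
    stop("missing values detected; this pipeline refuses to impute - ",
         "complete the data upstream", call. = FALSE)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  R <- config$n_split_reps
  per_rep <- matrix(NA_real_, nrow = ncol(x), ncol = R,
                    dimnames = list(colnames(x), NULL))
  for (r in seq_len(R)) {
    per_rep[, r] <- vi_one_split(
      x, y, config,
      split_seed = derive_seed(config$seed, "split", r),
      perm_seed = derive_seed(config$seed, "permbase", r))
  }
  out <- data.frame(predictor = colnames(x), vi_mean = rowMeans(per_rep),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, vi_per_rep = per_rep, config_hash = config_hash(config),
            class = c("mace_vi", "data.frame"))
}
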