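## Reshuffled-outcome null distribution and Z-tests.
##
## Each null replicate permutes the outcome vector across subjects and reruns
## the permute-and-refit VI procedure on the identical predictor matrix and
## settings. Because the observed statistic is an average over R splits while
## a null replicate uses k splits (k << R for cost), the raw SD of null
## replicate means is on the wrong scale. With k >= 2 the two variance
## components are separable:
##   Var(rep mean)            = V_shuffle + V_split / k
##   E(within-rep variance)   = V_split
## and the null SD of an R-split average is
##   sqrt(max(Var(rep means) - V_split (1/k - 1/R), V_split / R)).
## With k = 1 the components are confounded and the raw SD is used (warned).

#' Build the reshuffled-outcome null distribution
#'
#' @param x predictor matrix or data frame, identical to the observed run.
#' @param y numeric outcome vector (reshuffled internally).
#' @param config the same [forest_config()] as the observed run; its
#'   `n_split_reps` defines the scale on which `null_sd` is reported.
#' @param n_null_reps number of outcome reshuffles (the full-fidelity
#'   analysis uses 5000; scaled-down runs use fewer).
#' @param null_split_reps splits per null replicate (default 2, the minimum
#'   allowing the variance decomposition above).
#' @return object of class `mace_null`: data frame `predictor`, `null_mean`,
#'   `null_sd` (scale of an `n_split_reps`-average), `null_sd_rep` (raw SD of
#'   replicate means), with per-replicate means in `attr(, "rep_means")`.
#' @export
build_null <- function(x, y, config = forest_config(), n_null_reps = 500,
                       null_split_reps = 2) {
  x <- as_predictor_matrix(x)
  if (n_null_reps < 2) stop("n_null_reps must be >= 2", call. = FALSE)
  k <- as.integer(null_split_reps)
  if (k < 1) stop("null_split_reps must be >= 1", call. = FALSE)
  if (k == 1L)
    warning("null_split_reps = 1: null SD cannot be rescaled to the ",
            "n_split_reps average and will be conservative", call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  R <- config$n_split_reps
  rep_means <- matrix(NA_real_, p, n_null_reps, dimnames = list(colnames(x), NULL))
  within_var <- matrix(NA_real_, p, n_null_reps)
  for (b in seq_len(n_null_reps)) {
    set.seed(derive_seed(config$seed, "null-shuffle", b))
    yb <- y[sample.int(n)]
    vis <- matrix(NA_real_, p, k)
    for (s in seq_len(k)) {
      vis[, s] <- vi_one_split(
        x, yb, config,
        split_seed = derive_seed(config$seed, "null-split", b * 1009L + s),
        perm_seed = derive_seed(config$seed, "null-perm", b * 1013L + s))
    }
    rep_means[, b] <- rowMeans(vis)
    if (k >= 2) within_var[, b] <- apply(vis, 1, stats::var)
  }
  null_mean <- rowMeans(rep_means)
  v_rep <- apply(rep_means, 1, stats::var)
  if (k >= 2) {
    v_split <- rowMeans(within_var)
    null_var <- pmax(v_rep - v_split * (1 / k - 1 / R), v_split / R)
  } else {
    null_var <- v_rep
  }
  out <- data.frame(predictor = colnames(x), null_mean = null_mean,
                    null_sd = sqrt(null_var), null_sd_rep = sqrt(v_rep),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, rep_means = rep_means, n_null_reps = n_null_reps,
            null_split_reps = k, config_hash = config_hash(config),
            class = c("mace_null", "data.frame"))
}

#' One-sided Z-test of an observed importance against its null
#'
#' @param vi_mean observed importance (dMSE units).
#' @param null_mean,null_sd null moments for the same predictor.
#' @return list with `z` and the upper-tail `p`; both `NA` (degenerate) when
#'   `null_sd` is 0.
#' @export
z_test <- function(vi_mean, null_mean, null_sd) {
  if (any(null_sd < 0, na.rm = TRUE)) stop("null_sd must be >= 0", call. = FALSE)
  z <- ifelse(null_sd > 0, (vi_mean - null_mean) / null_sd, NA_real_)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Assemble the per-predictor importance table with significance
#'
#' @param vi a `mace_vi` from [estimate_vi()].
#' @param null a `mace_null` from [build_null()]; must stem from the same
#'   configuration (asserted by config hash).
#' @param alpha significance level for the `significant` flag.
#' @param adjust `"none"` (default; the analysis reports raw per-predictor
#'   p-values) or `"BH"` for Benjamini-Hochberg.
#' @return data frame of class `mace_vi_table`: `predictor`, `vi_mean`,
#'   `null_mean`, `null_sd`, `z`, `p`, `significant`, `degenerate`.
#' @export
vi_table <- function(vi, null, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!identical(attr(vi, "config_hash"), attr(null, "config_hash")))
    stop("observed VI and null were produced under different configurations",
         call. = FALSE)
  m <- merge(as.data.frame(vi), as.data.frame(null)[, c("predictor", "null_mean", "null_sd")],
             by = "predictor", sort = FALSE)
  m <- m[match(vi$predictor, m$predictor), ]
  zt <- z_test(m$vi_mean, m$null_mean, m$null_sd)
  m$z <- zt$z
  m$p <- if (adjust == "BH") stats::p.adjust(zt$p, "BH") else zt$p
  m$degenerate <- m$null_sd == 0
  m$significant <- !m$degenerate & !is.na(m$p) & m$p < alpha
  rownames(m) <- NULL
  class(m) <- c("mace_vi_table", "data.frame")
  attr(m, "alpha") <- alpha
  m
}

## classify predictor names into global / type-by-age / covariate
predictor_class <- function(predictor) {
  ifelse(predictor %in% GLOBAL_MEASURES, "global",
         ifelse(grepl(paste0("^(", paste(MACE_TYPES, collapse = "|"), ")_\\d{2}$"),
                      predictor), "type_age", "covariate"))
}

#' Competitive comparison of global versus type- and timing-specific measures
#'
#' Contrasts the largest importance among the global burden indices with the
#' largest among the type-by-age predictors.
#'
#' @param table a [vi_table()] (a plain data frame with `predictor` and
#'   `vi_mean` also works).
#' @param global predictor names forming the global group.
#' @param specific predictor names forming the specific group; default all
#'   `TYPE_dd` columns present.
#' @return list: `best_global`, `best_specific` (one-row data frames),
#'   `verdict` (`"global dominates"`, `"specific dominates"`, or `"tie"`),
#'   `tie` flag, and the overall `rank` of each winner within the compared
#'   predictors. Ties break lexicographically and are flagged.
#' @export
competitive_compare <- function(table, global = GLOBAL_MEASURES,
                                specific = NULL) {
  if (is.null(specific))
    specific <- table$predictor[predictor_class(table$predictor) == "type_age"]
  g <- table[table$predictor %in% global, , drop = FALSE]
  s <- table[table$predictor %in% specific, , drop = FALSE]
  if (nrow(g) == 0 || nrow(s) == 0)
    stop("both comparison groups must be nonempty", call. = FALSE)
  top <- function(d) {
    d <- d[order(-d$vi_mean, d$predictor), , drop = FALSE]
    d[1, , drop = FALSE]
  }
  bg <- top(g); bs <- top(s)
  tie <- isTRUE(all.equal(bg$vi_mean, bs$vi_mean))
  verdict <- if (tie) "tie"
             else if (bg$vi_mean > bs$vi_mean) "global dominates"
             else "specific dominates"
  both <- rbind(g, s)
  both <- both[order(-both$vi_mean, both$predictor), ]
  list(best_global = bg, best_specific = bs, verdict = verdict, tie = tie,
       rank = c(global = match(bg$predictor, both$predictor),
                specific = match(bs$predictor, both$predictor)))
}

#' Strongest significant predictor per CM type
#'
#' Among the significant type-by-age predictors of each CM type, selects the
#' one with maximal importance; types with no significant predictor are
#' omitted.
#'
#' @param table a [vi_table()].
#' @return data frame (possibly 0 rows) with one row per represented type,
#'   plus a `type` column.
#' @export
select_top_per_type <- function(table) {
  ta <- table[predictor_class(table$predictor) == "type_age" &
                !is.na(table$significant) & table$significant, , drop = FALSE]
  if (nrow(ta) == 0) {
    out <- table[0, , drop = FALSE]
    out$type <- character(0)
    return(out)
  }
  ta$type <- sub("_\\d{2}$", "", ta$predictor)
  picked <- lapply(split(ta, ta$type), function(d) {
    d[order(-d$vi_mean, d$predictor), ][1, , drop = FALSE]
  })
  out <- do.call(rbind, picked[intersect(MACE_TYPES, names(picked))])
  rownames(out) <- NULL
  out
}
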