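## Validation of selected predictors against interview-based diagnosis
## status, plus the descriptive statistics of the analysis (Welch t-tests
## with Cohen's d, Pearson correlation matrices).

#' Binomial GLM of diagnosis status on a selected predictor
#'
#' Logistic regression of a binary diagnosis indicator on one (by default
#' standardized) predictor while controlling for sex and age; one model per
#' predictor, reported as log-odds, SE, odds ratio, and Wald p.
#'
#' @param data data frame holding the predictor, outcome, and covariates.
#' @param predictor name of the predictor column.
#' @param outcome name of the binary outcome column (0/1).
#' @param covariates covariate columns (default `c("sex", "age")`; use
#'   `character(0)` for none).
#' @param standardize z-score the predictor so the OR is per SD (default);
#'   `FALSE` keeps the raw scale.
#' @return one-row data frame of class `mace_glm_fit`: `predictor`,
#'   `outcome`, `beta`, `se`, `or`, `p`, `separation` (quasi-separation
#'   flag), `n`.
#' @export
fit_disorder_glm <- function(data, predictor, outcome,
                             covariates = c("sex", "age"),
                             standardize = TRUE) {
  for (v in c(predictor, outcome, covariates))
    if (!v %in% names(data)) stop("column not found: ", v, call. = FALSE)
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("outcome is constant; both classes must be present", call. = FALSE)
  xv <- data[[predictor]]
  if (standardize) {
    s <- stats::sd(xv)
    if (s == 0) stop("predictor is constant; cannot standardize", call. = FALSE)
    xv <- (xv - mean(xv)) / s
  }
  df <- data.frame(.y = y, .x = xv)
  for (v in covariates) df[[v]] <- data[[v]]
  fml <- stats::as.formula(paste(".y ~ .x",
                                 if (length(covariates) > 0)
                                   paste("+", paste(covariates, collapse = " + "))
                                 else ""))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation)
    warning("possible separation: fitted probabilities of 0 or 1 occurred for ",
            predictor, call. = FALSE)
  co <- summary(fit)$coefficients
  out <- data.frame(predictor = predictor, outcome = outcome,
                    beta = co[".x", "Estimate"], se = co[".x", "Std. Error"],
                    or = exp(co[".x", "Estimate"]), p = co[".x", "Pr(>|z|)"],
                    separation = separation, n = nrow(df),
                    stringsAsFactors = FALSE)
  class(out) <- c("mace_glm_fit", "data.frame")
  out
}

#' Welch t-test and Cohen's d from group summary statistics
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `t` (Welch statistic), `df` (Satterthwaite degrees of
#'   freedom), `p` (two-sided), and `d` (Cohen's d with the pooled SD
#'   `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`).
#' @examples
#' welch_cohen(48.97, 9.45, 73, 57.46, 10.31, 112)$d  # approximately -0.85
#' @export
welch_cohen <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("group SDs must be positive", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       d = (mean1 - mean2) / pooled)
}

#' Pearson correlation matrix with zero-variance masking
#'
#' @param data numeric data frame or matrix (>= 3 rows, finite values).
#' @return symmetric correlation matrix; rows/columns of zero-variance
#'   inputs are `NA` off the diagonal (diagonal stays 1).
#' @export
pearson_matrix <- function(data) {
  m <- as.matrix(data)
  if (nrow(m) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite values in input", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  r
}
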