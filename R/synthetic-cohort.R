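## Synthetic cohort generator.
##
## Exposure model: for each subscale s and age t, a subject is exposed with
## marginal probability prevalence_curve[s, t]. Cross-subscale dependence
## within a year comes from a Gaussian copula with correlation `co_occurrence`;
## within-subscale dependence across years is a two-state Markov chain whose
## conditionals are chosen so the marginal prevalence is hit exactly:
##   P(exposed_t | exposed_{t-1})  = p_t + rho * (1 - p_t)
##   P(exposed_t | unexposed_{t-1}) solves the marginal constraint (clamped).
## `rho` (persistence) is the excess continuation probability beyond baseline.
## Severity given exposure is drawn from a scaled, left-truncated Beta so that
## every exposed subscale-year scores above the default exposure threshold.

#' Specify a synthetic maltreatment cohort
#'
#' Defaults emulate a high-risk residential-care cohort: neglect near ceiling
#' at every age, sexual abuse rare throughout, peer violence rare before age
#' six and rising through adolescence, parental abuse peaking in childhood;
#' strong year-to-year persistence and positive cross-subscale co-occurrence.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param prevalence_curve 10 x 18 matrix of per-subscale, per-age exposure
#'   probabilities (rows named by subscale, columns ages 1-18).
#' @param persistence excess probability in `[0,1]` that exposure in year t
#'   continues in year t+1 within a subscale.
#' @param co_occurrence symmetric positive-semidefinite 10 x 10 latent
#'   correlation matrix with unit diagonal.
#' @param severity_given_exposure list with either `value` (degenerate score
#'   in (0,10]) or `shape1`, `shape2`, `min` for a Beta on `(min, 10]`.
#' @param effect_map named numeric vector of linear weights on standardized
#'   predictors (names must resolve against [build_predictor_matrix()] columns
#'   plus `sex` and `age`); acts on the T-score scale.
#' @param noise_sd residual SD of the T-score outcomes, in T-score units.
#' @param logistic_intercept scalar or named vector (`any`, `internalizing`,
#'   `externalizing`) of diagnosis-link intercepts on the log-odds scale.
#' @param logistic_slope multiplier applied to the planted linear predictor in
#'   the diagnosis link.
#' @param sex_ratio proportion female in `[0,1]` (sex coded 1 = female).
#' @param age_mean,age_sd adult age distribution, years.
#' @param seed integer master seed; fixed seed gives bit-identical cohorts.
#' @return object of class `mace_spec`.
#' @examples
#' spec <- synthetic_spec(n_subjects = 50, seed = 1)
#' exp <- generate_exposures(spec)
#' @export
synthetic_spec <- function(n_subjects = 185,
                           prevalence_curve = default_prevalence_curve(),
                           persistence = 0.9,
                           co_occurrence = default_co_occurrence(),
                           severity_given_exposure = list(shape1 = 2, shape2 = 5, min = 0.5),
                           effect_map = numeric(0),
                           noise_sd = 10,
                           logistic_intercept = c(any = stats::qlogis(0.61),
                                                  internalizing = stats::qlogis(0.32),
                                                  externalizing = stats::qlogis(0.54)),
                           logistic_slope = 1,
                           sex_ratio = 0.34,
                           age_mean = 26.38,
                           age_sd = 3.49,
                           seed = 1L) {
  spec <- structure(
    list(n_subjects = n_subjects, prevalence_curve = prevalence_curve,
         persistence = persistence, co_occurrence = co_occurrence,
         severity_given_exposure = severity_given_exposure,
         effect_map = effect_map, noise_sd = noise_sd,
         logistic_intercept = logistic_intercept,
         logistic_slope = logistic_slope, sex_ratio = sex_ratio,
         age_mean = age_mean, age_sd = age_sd, seed = as.integer(seed)),
    class = "mace_spec")
  validate_spec(spec)
  spec
}

#' Default per-subscale, per-age exposure prevalence curve
#'
#' Neglect ~0.90 flat across ages; sexual abuse 0.06 flat; peer violence 0.04
#' before age 6 ramping to ~0.30 in mid-adolescence; parental-abuse subscales
#' humped in early/middle childhood.
#'
#' @return 10 x 18 matrix, rows named by subscale, columns `age_1 ... age_18`.
#' @export
default_prevalence_curve <- function() {
  ages <- MACE_AGES
  curve <- matrix(0, nrow = 10, ncol = 18,
                  dimnames = list(MACE_SUBSCALES, paste0("age_", ages)))
  abuse_hump <- 0.25 + 0.20 * exp(-((ages - 7)^2) / 30)   # peaks ~0.45 at age 7
  for (s in names(MACE_TYPE_MAP)[MACE_TYPE_MAP == "ABUSE"]) curve[s, ] <- abuse_hump
  curve["emotional_neglect", ] <- 0.90
  curve["physical_neglect", ]  <- 0.90
  peer <- ifelse(ages <= 5, 0.04, pmin(0.04 + 0.04 * (ages - 5), 0.30))
  curve["peer_emotional", ] <- peer
  curve["peer_physical", ]  <- peer * 0.8
  curve["sexual_abuse", ]   <- 0.06
  curve
}

#' Default latent co-occurrence matrix
#'
#' Unit diagonal, 0.5 between subscales of the same CM type, 0.25 across
#' types; verified positive semidefinite.
#'
#' @return 10 x 10 correlation-like matrix.
#' @export
default_co_occurrence <- function() {
  ty <- MACE_TYPE_MAP[MACE_SUBSCALES]
  m <- outer(ty, ty, function(a, b) ifelse(a == b, 0.5, 0.25))
  diag(m) <- 1
  dimnames(m) <- list(MACE_SUBSCALES, MACE_SUBSCALES)
  m
}

validate_spec <- function(spec) {
  stopifnot(inherits(spec, "mace_spec"))
  if (!is.numeric(spec$n_subjects) || spec$n_subjects < 2)
    stop("invalid spec: n_subjects must be >= 2", call. = FALSE)
  pc <- spec$prevalence_curve
  if (!is.matrix(pc) || !all(dim(pc) == c(10, 18)))
    stop("invalid spec: prevalence_curve must be a 10 x 18 matrix", call. = FALSE)
  if (any(pc < 0 | pc > 1))
    stop("invalid spec: prevalence_curve has probabilities outside [0, 1]", call. = FALSE)
  if (spec$persistence < 0 || spec$persistence > 1)
    stop("invalid spec: persistence must lie in [0, 1]", call. = FALSE)
  co <- spec$co_occurrence
  if (!is.matrix(co) || !all(dim(co) == c(10, 10)))
    stop("invalid spec: co_occurrence must be a 10 x 10 matrix", call. = FALSE)
  if (max(abs(co - t(co))) > 1e-8 || any(abs(diag(co) - 1) > 1e-8))
    stop("invalid spec: co_occurrence must be symmetric with unit diagonal", call. = FALSE)
  if (min(eigen(co, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("invalid spec: co_occurrence is not positive semidefinite", call. = FALSE)
  if (any(co < -1 | co > 1))
    stop("invalid spec: co_occurrence entries outside [-1, 1]", call. = FALSE)
  sev <- spec$severity_given_exposure
  if (is.null(sev$value) && (is.null(sev$shape1) || is.null(sev$shape2)))
    stop("invalid spec: severity_given_exposure needs `value` or `shape1`/`shape2`", call. = FALSE)
  if (!is.null(sev$value) && (sev$value <= 0 || sev$value > 10))
    stop("invalid spec: severity_given_exposure$value must lie in (0, 10]", call. = FALSE)
  if (spec$noise_sd < 0)
    stop("invalid spec: noise_sd must be non-negative", call. = FALSE)
  if (spec$sex_ratio < 0 || spec$sex_ratio > 1)
    stop("invalid spec: sex_ratio must lie in [0, 1]", call. = FALSE)
  invisible(spec)
}

## Draw severities for `n` exposed subscale-years.
draw_severity <- function(n, sev) {
  if (!is.null(sev$value)) return(rep(sev$value, n))
  lo <- if (is.null(sev$min)) 0 else sev$min
  ## left-truncate the Beta so scores stay above `lo` on the 0-10 scale
  plo <- stats::pbeta(lo / 10, sev$shape1, sev$shape2)
  u <- stats::runif(n, plo, 1)
  10 * stats::qbeta(u, sev$shape1, sev$shape2)
}

#' Generate exposure chronologies
#'
#' Draws, for every subject, a 10-subscale by 18-age matrix of weighted
#' severity scores in `[0, 10]` (0 = unexposed) under the spec's prevalence,
#' persistence, and co-occurrence structure.
#'
#' @param spec a [synthetic_spec()].
#' @return `mace_exposures`: long data frame with columns `subject_id`,
#'   `subscale`, `age`, `score`, one row per subject x subscale x age.
#' @export
generate_exposures <- function(spec) {
  validate_spec(spec)
  n <- spec$n_subjects
  pc <- spec$prevalence_curve
  rho <- spec$persistence
  ## Cholesky-like root of the copula correlation (PSD-safe via eigen)
  eg <- eigen(spec$co_occurrence, symmetric = TRUE)
  root <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 10) %*% t(eg$vectors)

  set.seed(derive_seed(spec$seed, "exposures"))
  exposed <- array(FALSE, dim = c(n, 10, 18))
  for (t in MACE_AGES) {
    z <- matrix(stats::rnorm(n * 10), n, 10) %*% root
    u <- stats::pnorm(z)
    p_t <- pc[, t]
    if (t == 1L) {
      cond <- matrix(p_t, n, 10, byrow = TRUE)
    } else {
      p_prev <- pc[, t - 1L]
      q1 <- p_t + rho * (1 - p_t)
      q0 <- ifelse(p_prev >= 1 - 1e-12, 0,
                   (p_t - p_prev * q1) / (1 - p_prev))
      q0 <- pmin(pmax(q0, 0), 1)
      prev <- exposed[, , t - 1L]
      cond <- prev * matrix(q1, n, 10, byrow = TRUE) +
        (!prev) * matrix(q0, n, 10, byrow = TRUE)
    }
    exposed[, , t] <- u < cond
  }
  scores <- array(0, dim = c(n, 10, 18))
  idx <- which(exposed)
  scores[idx] <- draw_severity(length(idx), spec$severity_given_exposure)

  out <- data.frame(
    subject_id = rep(seq_len(n), times = 10 * 18),
    subscale   = rep(rep(MACE_SUBSCALES, each = n), times = 18),
    age        = rep(MACE_AGES, each = n * 10),
    score      = as.vector(scores),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$subject_id, match(out$subscale, MACE_SUBSCALES), out$age), ]
  rownames(out) <- NULL
  class(out) <- c("mace_exposures", "data.frame")
  out
}

#' Generate outcome records for a cohort of exposure chronologies
#'
#' Scores the chronologies into the standard predictor set, applies the
#' spec's planted effects on standardized predictors, and draws ASEBA-style
#' T-scores (population mean 50) plus binary diagnosis indicators through a
#' logistic link sharing the same linear predictor.
#'
#' @param exposures output of [generate_exposures()].
#' @param spec the same [synthetic_spec()].
#' @param thresholds a [threshold_table()] used when planted effects involve
#'   the global indices.
#' @return data frame with `subject_id`, `sex` (1 = female), `age`,
#'   `t_total`, `t_internalizing`, `t_externalizing`, `dx_any`,
#'   `dx_internalizing`, `dx_externalizing`.
#' @export
generate_outcomes <- function(exposures, spec, thresholds = threshold_table()) {
  validate_spec(spec)
  n <- length(unique(exposures$subject_id))

  set.seed(derive_seed(spec$seed, "subjects"))
  sex <- stats::rbinom(n, 1, spec$sex_ratio)
  age <- stats::rnorm(n, spec$age_mean, spec$age_sd)

  pm <- build_predictor_matrix(exposures, thresholds = thresholds)
  pm$sex <- sex
  pm$age <- age

  em <- spec$effect_map
  valid <- setdiff(names(pm), "subject_id")
  if (length(em) > 0) {
    bad <- setdiff(names(em), valid)
    if (length(bad) > 0)
      stop("unknown predictor name(s) in effect_map: ",
           paste(bad, collapse = ", "),
           "; valid names are: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  zscore <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  linpred <- rep(0, n)
  for (nm in names(em)) linpred <- linpred + em[[nm]] * zscore(pm[[nm]])

  set.seed(derive_seed(spec$seed, "outcomes"))
  t_total         <- 50 + linpred + stats::rnorm(n, 0, spec$noise_sd)
  t_internalizing <- 50 + linpred + stats::rnorm(n, 0, spec$noise_sd)
  t_externalizing <- 50 + linpred + stats::rnorm(n, 0, spec$noise_sd)

  ic <- spec$logistic_intercept
  pick <- function(key) {
    if (length(ic) == 1L && is.null(names(ic))) return(unname(ic))
    if (!is.null(names(ic)) && key %in% names(ic)) return(unname(ic[[key]]))
    unname(ic[[1L]])
  }
  dx_draw <- function(key) {
    pr <- stats::plogis(pick(key) + spec$logistic_slope * linpred)
    stats::rbinom(n, 1, pr)
  }
  dx_any  <- dx_draw("any")
  dx_int  <- dx_draw("internalizing")
  dx_ext  <- dx_draw("externalizing")

  data.frame(subject_id = sort(unique(exposures$subject_id)),
             sex = sex, age = age,
             t_total = t_total, t_internalizing = t_internalizing,
             t_externalizing = t_externalizing,
             dx_any = dx_any, dx_internalizing = dx_int,
             dx_externalizing = dx_ext)
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: exposures, outcomes, and the scored predictor matrix
#' (type-by-age columns, global indices, sex, age) in one call.
#'
#' @inheritParams generate_outcomes
#' @param spec a [synthetic_spec()].
#' @return list with elements `exposures`, `outcomes`, `predictors`.
#' @export
generate_cohort <- function(spec, thresholds = threshold_table()) {
  exposures <- generate_exposures(spec)
  outcomes <- generate_outcomes(exposures, spec, thresholds = thresholds)
  predictors <- build_predictor_matrix(exposures, thresholds = thresholds)
  predictors$sex <- outcomes$sex
  predictors$age <- outcomes$age
  list(exposures = exposures, outcomes = outcomes, predictors = predictors)
}
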