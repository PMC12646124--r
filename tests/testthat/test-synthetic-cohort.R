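test_that("spec validation names the offending field", {
  expect_error(synthetic_spec(n_subjects = 1), "n_subjects")
  bad_curve <- flat_curve(0.5); bad_curve[3, 7] <- 1.2
  expect_error(synthetic_spec(prevalence_curve = bad_curve), "prevalence_curve")
  expect_error(synthetic_spec(persistence = 1.5), "persistence")
  co <- default_co_occurrence()
  co[1, 2] <- co[2, 1] <- 1; co[1, 3] <- co[3, 1] <- 1; co[2, 3] <- co[3, 2] <- -1
  expect_error(synthetic_spec(co_occurrence = co), "positive semidefinite")
  co2 <- default_co_occurrence(); co2[1, 2] <- 0.9
  expect_error(synthetic_spec(co_occurrence = co2), "symmetric")
  expect_error(synthetic_spec(sex_ratio = -0.1), "sex_ratio")
})

test_that("degenerate prevalence gives all-zero and all-ceiling chronologies", {
  zero <- generate_exposures(synthetic_spec(n_subjects = 20,
                                            prevalence_curve = flat_curve(0),
                                            seed = 7))
  expect_true(all(zero$score == 0))
  full <- generate_exposures(synthetic_spec(
    n_subjects = 20, prevalence_curve = flat_curve(1),
    severity_given_exposure = list(value = 10), seed = 7))
  expect_true(all(full$score == 10))
})

test_that("marginal exposure rates match the prevalence curve", {
  curve <- flat_curve(0)
  curve["emotional_neglect", ] <- 0.9
  spec <- synthetic_spec(n_subjects = 2000, prevalence_curve = curve,
                         persistence = 0.5, seed = 11)
  exp <- generate_exposures(spec)
  negl <- exp[exp$subscale == "emotional_neglect", ]
  rate_by_age <- tapply(negl$score > 0, negl$age, mean)
  expect_true(all(abs(rate_by_age - 0.9) < 0.03))
  expect_true(all(exp$score[exp$subscale != "emotional_neglect"] == 0))
})

test_that("fixed seed reproduces cohorts bit-identically", {
  spec <- synthetic_spec(n_subjects = 40, seed = 123)
  expect_identical(generate_exposures(spec), generate_exposures(spec))
  e <- generate_exposures(spec)
  expect_identical(generate_outcomes(e, spec), generate_outcomes(e, spec))
})

test_that("persistence raises the continuation probability; zero persistence and identity co-occurrence give independence", {
  spec_dep <- synthetic_spec(n_subjects = 1500, prevalence_curve = flat_curve(0.3),
                             persistence = 0.8, seed = 5)
  e <- generate_exposures(spec_dep)
  sub1 <- e[e$subscale == SUBSCALES[1], ]
  w <- reshape(sub1[, c("subject_id", "age", "score")], idvar = "subject_id",
               timevar = "age", direction = "wide")
  exp_mat <- as.matrix(w[, -1]) > 0
  cont <- mean(exp_mat[exp_mat[, 9], 10])        # P(exposed age 10 | exposed age 9)
  fresh <- mean(exp_mat[!exp_mat[, 9], 10])
  expect_gt(cont, fresh + 0.3)

  spec_ind <- synthetic_spec(n_subjects = 1500, prevalence_curve = flat_curve(0.3),
                             persistence = 0, co_occurrence = diag(10), seed = 5)
  e2 <- generate_exposures(spec_ind)
  g <- function(sub, age) e2$score[e2$subscale == sub & e2$age == age] > 0
  expect_gt(chisq.test(table(g(SUBSCALES[1], 9), g(SUBSCALES[1], 10)))$p.value, 0.01)
  expect_gt(chisq.test(table(g(SUBSCALES[1], 9), g(SUBSCALES[2], 9)))$p.value, 0.01)
})

test_that("positive co-occurrence induces cross-subscale dependence", {
  co <- diag(10); co[1, 2] <- co[2, 1] <- 0.8
  spec <- synthetic_spec(n_subjects = 1500, prevalence_curve = flat_curve(0.4),
                         persistence = 0, co_occurrence = co, seed = 9)
  e <- generate_exposures(spec)
  a <- e$score[e$subscale == SUBSCALES[1] & e$age == 5] > 0
  b <- e$score[e$subscale == SUBSCALES[2] & e$age == 5] > 0
  expect_gt(cor(a, b), 0.3)
})

test_that("null outcome model returns exact population values", {
  spec <- synthetic_spec(n_subjects = 50, noise_sd = 0,
                         logistic_intercept = 0, logistic_slope = 0, seed = 2)
  out <- generate_outcomes(generate_exposures(spec), spec)
  expect_true(all(out$t_total == 50))
  expect_true(all(out$t_internalizing == 50))
  spec2 <- synthetic_spec(n_subjects = 4000, logistic_intercept = 0,
                          logistic_slope = 0, seed = 2)
  out2 <- generate_outcomes(generate_exposures(spec2), spec2)
  expect_lt(abs(mean(out2$dx_any) - 0.5), 0.03)
})

test_that("a planted effect produces the analytic predictor-outcome correlation", {
  spec <- synthetic_spec(n_subjects = 2000, effect_map = c(ABUSE_03 = 5),
                         noise_sd = 10, seed = 31)
  coh <- generate_cohort(spec)
  r <- cor(coh$predictors$ABUSE_03, coh$outcomes$t_total)
  expect_lt(abs(r - 5 / sqrt(25 + 100)), 0.05)
})

test_that("unknown effect-map names are rejected with the valid choices", {
  spec <- synthetic_spec(n_subjects = 30, seed = 1)
  spec$effect_map <- c(NOT_A_PREDICTOR = 1)
  e <- generate_exposures(spec)
  expect_error(generate_outcomes(e, spec), "NOT_A_PREDICTOR")
  expect_error(generate_outcomes(e, spec), "valid names")
})

test_that("planted-effect strength is monotone in the realized correlation", {
  rs <- vapply(c(1, 3, 6), function(w) {
    spec <- synthetic_spec(n_subjects = 800, effect_map = c(PEER_14 = w),
                           noise_sd = 10, seed = 77)
    coh <- generate_cohort(spec)
    cor(coh$predictors$PEER_14, coh$outcomes$t_total)
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})
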