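abuse_subs <- SUBSCALES[1:5]

test_that("type aggregation averages constituent subscales and preserves range", {
  e0 <- make_exposures(1)
  t0 <- aggregate_to_types(e0)
  expect_equal(t0$score[t0$type == "ABUSE" & t0$age == 7], 0)

  cells <- lapply(abuse_subs, function(s) list(subject = 1, subscale = s, age = 7, score = 10))
  e1 <- make_exposures(1, cells)
  t1 <- aggregate_to_types(e1)
  expect_equal(t1$score[t1$type == "ABUSE" & t1$age == 7], 10)

  sc <- c(10, 5, 0, 0, 0)
  e2 <- make_exposures(1, lapply(1:5, function(i)
    list(subject = 1, subscale = abuse_subs[i], age = 7, score = sc[i])))
  t2 <- aggregate_to_types(e2)
  expect_equal(t2$score[t2$type == "ABUSE" & t2$age == 7], 3.0)
  ## single-subscale type passes through
  e3 <- make_exposures(1, list(list(subject = 1, subscale = "sexual_abuse",
                                    age = 12, score = 4)))
  t3 <- aggregate_to_types(e3)
  expect_equal(t3$score[t3$type == "SEXA" & t3$age == 12], 4)
})

test_that("unknown subscale labels are rejected", {
  e <- make_exposures(1)
  e$subscale[1] <- "not_a_subscale"
  expect_error(aggregate_to_types(e), "not_a_subscale")
})

test_that("infancy exclusion keeps ages 3-18 and is idempotent", {
  ts <- aggregate_to_types(make_exposures(2))
  r1 <- exclude_infantile_years(ts)
  expect_setequal(unique(r1$age), 3:18)
  expect_identical(exclude_infantile_years(r1), r1)
})

test_that("predictor matrix has 64 type-by-age columns plus globals and covariates", {
  spec <- synthetic_spec(n_subjects = 15, seed = 4)
  coh <- generate_cohort(spec)
  ta <- grep("^(ABUSE|NEGLECT|PEER|SEXA)_\\d{2}$", names(coh$predictors), value = TRUE)
  expect_length(ta, 64)
  expect_identical(ta, type_age_names())
  expect_true(all(c("SEVERITY", "MULTI", "DURATION", "sex", "age") %in%
                    names(coh$predictors)))
  expect_equal(ncol(coh$predictors), 1 + 64 + 3 + 2)
})

test_that("SEVERITY sums per-subscale overall severities on the 0-100 scale", {
  expect_equal(compute_severity(make_exposures(1)), 0)
  allmax <- make_exposures(1, unlist(lapply(SUBSCALES, function(s)
    lapply(1:18, function(a) list(subject = 1, subscale = s, age = a, score = 10))),
    recursive = FALSE))
  expect_equal(compute_severity(allmax), 100)
  two5 <- make_exposures(1, unlist(lapply(SUBSCALES[1:2], function(s)
    lapply(1:18, function(a) list(subject = 1, subscale = s, age = a, score = 5))),
    recursive = FALSE))
  expect_equal(compute_severity(two5), 10)
})

test_that("MULTI counts subscales above threshold", {
  expect_equal(compute_multiplicity(make_exposures(1)), 0L)
  allmax <- make_exposures(1, unlist(lapply(SUBSCALES, function(s)
    lapply(1:18, function(a) list(subject = 1, subscale = s, age = a, score = 10))),
    recursive = FALSE))
  expect_equal(compute_multiplicity(allmax), 10L)
  three <- make_exposures(1, lapply(SUBSCALES[c(1, 6, 10)], function(s)
    list(subject = 1, subscale = s, age = 5, score = 10)))  # overall 10/18 > 0.5
  expect_equal(compute_multiplicity(three), 3L)
})

test_that("DURATION counts years with any above-threshold exposure", {
  expect_equal(compute_duration(make_exposures(1)), 0L)
  every_year <- make_exposures(1, lapply(1:18, function(a)
    list(subject = 1, subscale = "physical_neglect", age = a, score = 1)))
  expect_equal(compute_duration(every_year), 18L)
  three_years <- make_exposures(1, lapply(c(4, 5, 9), function(a)
    list(subject = 1, subscale = "peer_physical", age = a, score = 2)))
  expect_equal(compute_duration(three_years), 3L)
})

test_that("prevalence_by_age counts exposed subjects over the cohort", {
  e <- make_exposures(10, lapply(1:9, function(i)
    list(subject = i, subscale = "emotional_neglect", age = 6, score = 5)))
  pr <- prevalence_by_age(e)
  expect_equal(pr$prevalence[pr$type == "NEGLECT" & pr$age == 6], 0.9)
  expect_true(all(pr$prevalence[pr$type == "NEGLECT" & pr$age != 6] == 0))
  e0 <- make_exposures(3)
  expect_true(all(prevalence_by_age(e0)$prevalence == 0))
  full_long <- do.call(rbind, lapply(SUBSCALES, function(s) data.frame(
    subject_id = rep(1:2, 18), subscale = s, age = rep(1:18, each = 2), score = 9)))
  expect_true(all(prevalence_by_age(full_long)$prevalence == 1))
  expect_error(prevalence_by_age(make_exposures(1)[0, ]), "empty cohort")
})

test_that("global indices respect ranges and grow monotonically with added exposure", {
  for (s in 1:3) {
    spec <- synthetic_spec(n_subjects = 30, seed = s)
    e <- generate_exposures(spec)
    pm <- build_predictor_matrix(e)
    ta <- as.matrix(pm[, type_age_names()])
    expect_true(all(ta >= 0 & ta <= 10))
    expect_true(all(pm$SEVERITY >= 0 & pm$SEVERITY <= 100))
    expect_true(all(pm$MULTI %in% 0:10))
    expect_true(all(pm$DURATION %in% 0:18))

    ## raise one previously unexposed subscale-year for every subject
    e2 <- e
    set.seed(s)
    for (id in unique(e2$subject_id)) {
      zero_rows <- which(e2$subject_id == id & e2$score == 0)
      e2$score[sample(zero_rows, 1)] <- 8
    }
    expect_true(all(compute_severity(e2) >= compute_severity(e)))
    expect_true(all(compute_multiplicity(e2) >= compute_multiplicity(e)))
    expect_true(all(compute_duration(e2) >= compute_duration(e)))
  }
})

test_that("any-CM prevalence equals the brute-force union over subjects", {
  spec <- synthetic_spec(n_subjects = 40, seed = 6)
  e <- generate_exposures(spec)
  th <- threshold_table()
  ids <- sort(unique(e$subject_id))
  brute <- vapply(ids, function(id) {
    any(vapply(SUBSCALES, function(s) {
      sc <- e$score[e$subject_id == id & e$subscale == s]
      mean(sc) > unclass(th)[[s]]
    }, logical(1)))
  }, logical(1))
  expect_equal(any_cm_prevalence(e), mean(brute))
})
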