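test_that("score_scale sums items, stays fractional, and propagates blanks", {
  a <- assessment_spec("sdq_sub", "caregiver", n_items = 5, item_min = 0,
                       item_max = 2)
  expect_equal(score_scale(rep(2, 5), a), 10)  # the 0-10 subscale ceiling
  expect_equal(score_scale(rep(0, 5), a), 0)
  a3 <- assessment_spec("toy", "self", n_items = 3, item_min = 0, item_max = 2)
  expect_equal(score_scale(c(1, 1.4, 2), a3), 4.4)  # unrounded post-imputation
  expect_true(is.na(score_scale(c(1, NA, 2), a3)))
  expect_error(score_scale(c(1, 5, 0), a3), "outside")
  expect_error(score_scale(c(1, 2), a3), "expected 3 items")
})

test_that("standardize matches the direct z formula and flags degenerate input", {
  st <- data.frame(participant = 1:3, wave = "T1", assessment = "a",
                   score = c(1, 2, 3))
  tn <- standardize(st, waves = "T1")
  # sample-SD convention (n-1): population-SD z would be -1.2247/0/1.2247
  expect_equal(as.numeric(tn$values[, 1, 1]), c(-1, 0, 1))

  st2 <- data.frame(participant = 1:4, wave = "T1", assessment = "a",
                    score = c(0, 0, 1, 3))
  tn2 <- standardize(st2, waves = "T1")
  z_oracle <- (c(0, 0, 1, 3) - mean(c(0, 0, 1, 3))) / sd(c(0, 0, 1, 3))
  expect_equal(as.numeric(tn2$values[, 1, 1]), z_oracle)

  stc <- data.frame(participant = 1:4, wave = "T1", assessment = "flat",
                    score = 2)
  expect_error(standardize(stc, waves = "T1"), "flat")
})

test_that("standardization is idempotent and sets the mask from observedness", {
  co <- study_cohort()
  tn <- standardize(co$scale_table)
  for (j in seq_along(tn$assessment_names)) {
    obs <- tn$values[, , j][tn$mask[, , j] == 1]
    expect_equal(mean(obs), 0, tolerance = 1e-8)
    expect_equal(sd(obs), 1, tolerance = 1e-8)
  }
  # re-standardizing the standardized scores changes nothing
  st2 <- data.frame(
    participant = rep(tn$participant_ids, times = prod(dim(tn$values)[2:3])),
    wave = rep(rep(tn$wave_labels, each = dim(tn$values)[1]),
               times = dim(tn$values)[3]),
    assessment = rep(tn$assessment_names, each = prod(dim(tn$values)[1:2])),
    score = as.vector(tn$values))
  st2 <- st2[!is.na(st2$score), ]
  tn2 <- standardize(st2)
  expect_equal(tn2$values[tn2$mask == 1], tn$values[tn$mask == 1],
               tolerance = 1e-8)
  # structurally absent waves stay masked
  expect_true(all(tn$mask[, "T3", "somatic_caregiver"] == 0))
  expect_true(all(tn$mask[, "T1", "selfharm_self"] == 0))
})

test_that("missforest_impute honours its contracts", {
  set.seed(42)
  full <- matrix(rnorm(60), 20, 3)
  out <- missforest_impute(full, n_trees = 10, seed = 1)
  expect_equal(unclass(out)[seq_along(full)], as.vector(full))
  expect_equal(attr(out, "iterations_used"), 0L)

  # all-blank rows are excluded and stay blank; observed cells inviolate
  X <- matrix(rnorm(200), 40, 5)
  X[3, ] <- NA
  X[cbind(5:14, 2)] <- NA
  out <- missforest_impute(X, n_trees = 25, seed = 2)
  expect_true(all(is.na(out[3, ])))
  expect_equal(out[!is.na(X)], X[!is.na(X)])
  expect_false(anyNA(out[-3, ]))

  expect_error(missforest_impute(matrix(NA_real_, 3, 3)), "no responses")
})

test_that("missforest recovers a correlated column within 0.5 RMSE", {
  rmses <- vapply(1:10, function(s) {
    set.seed(s)
    x1 <- rnorm(200)
    X <- cbind(x1, rnorm(200), rnorm(200), rnorm(200), x1 + rnorm(200, 0, 0.1))
    truth <- X
    mis <- sample(200, 20)
    X[mis, 5] <- NA
    out <- missforest_impute(X, n_trees = 50, seed = s)
    sqrt(mean((out[mis, 5] - truth[mis, 5])^2))
  }, numeric(1))
  expect_lt(mean(rmses), 0.5)
})

test_that("cohort item imputation reduces missingness without touching observed data", {
  co <- study_cohort()
  res <- impute_cohort_items(co$item_table, co$spec_echo$assessments,
                             n_trees = 20, seed = 3)
  rep <- res$report
  expect_lte(rep$fraction_missing_after, rep$fraction_missing_before)
  obs <- !is.na(co$item_table$value)
  expect_equal(res$item_table$value[obs], as.numeric(co$item_table$value[obs]))
  # imputed values are fractional-friendly and within item bounds
  for (a_name in names(co$spec_echo$assessments)) {
    a <- co$spec_echo$assessments[[a_name]]
    v <- res$item_table$value[res$item_table$assessment == a_name]
    v <- v[!is.na(v)]
    expect_gte(min(v), a$item_min)
    expect_lte(max(v), a$item_max)
  }
})

test_that("attrition_report reproduces printed follow-up rates", {
  rep <- attrition_report(c(T1 = 3171, T2 = 3007, T3 = 2667, T4 = 2616))
  expect_equal(rep$followup_pct, c(100.0, 94.8, 84.1, 82.5))
  expect_equal(attrition_report(c(T1 = 10, T2 = 10))$followup_pct, c(100, 100))
  expect_error(attrition_report(c(T1 = 0, T2 = 5)), "baseline")
})
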