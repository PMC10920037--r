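make_reg_spec <- function(beta_main = 0.7) {
  catalog <- data.frame(
    name = c("exposure", "noise_cont"),
    type = c("binary", "continuous"),
    p1 = c(0.3, 0), p2 = c(NA, 1), flip = c(FALSE, FALSE),
    stringsAsFactors = FALSE)
  beta <- matrix(0, 3, 4,
                 dimnames = list(c("(Intercept)", "exposure", "noise_cont"),
                                 c("internalizing", "discrepant",
                                   "externalizing", "severe")))
  beta["exposure", "internalizing"] <- beta_main
  cohort_spec(n_participants = 3000, covariate_catalog = catalog,
              true_beta = beta, seed = 1, calibrate = TRUE)
}

test_that("screening matches the hand formulas and screens by p < 0.05", {
  # 2x2 table (10,20 / 20,10): uncorrected chi-square = 6.667
  x <- rep(c(0, 1), c(30, 30))
  g <- c(rep(c("a", "b"), c(10, 20)), rep(c("a", "b"), c(20, 10)))
  res <- screen_predictors(data.frame(v = x), g, types = c(v = "binary"))
  expect_equal(res$statistic, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)
  expect_equal(res$statistic, 6.667, tolerance = 1e-3)
  expect_true(res$selected)

  # identical group means: F near 0, not selected
  set.seed(1)
  v <- rnorm(300)
  g2 <- rep(c("a", "b", "c"), 100)
  v <- v - ave(v, g2)  # remove group differences entirely
  res2 <- screen_predictors(data.frame(v = v), g2)
  expect_equal(res2$test, "one-way ANOVA F")
  expect_lt(res2$statistic, 1e-10)
  expect_false(res2$selected)

  # ANOVA F equals the direct between/within formula on a small fixture
  v3 <- c(1, 2, 3, 6, 7, 9, 2, 4, 5)
  g3 <- rep(c("a", "b", "c"), each = 3)
  res3 <- screen_predictors(data.frame(v = v3), g3)
  gm <- mean(v3)
  ssb <- sum(3 * (tapply(v3, g3, mean) - gm)^2)
  ssw <- sum((v3 - ave(v3, g3))^2)
  expect_equal(res3$statistic, (ssb / 2) / (ssw / 6), tolerance = 1e-12)

  # 1-SD cluster mean shift at n=500: essentially always detected
  set.seed(2)
  g4 <- sample(c("a", "b"), 500, replace = TRUE)
  v4 <- rnorm(500) + (g4 == "b")
  expect_true(screen_predictors(data.frame(v = v4), g4)$selected)

  # single observed level is excluded with a reason
  res5 <- screen_predictors(data.frame(v = rep(1, 60)), rep(c("a", "b"), 30))
  expect_false(res5$selected)
  expect_match(res5$note, "single")
})

test_that("chained-equation imputation honours its contracts", {
  set.seed(9)
  n <- 200
  tab <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4), x3 = rnorm(n))
  labels <- sample(c("u", "v"), n, replace = TRUE)
  # no missing cells: m identical copies
  st0 <- mice_impute(tab, labels, m = 3, iterations = 2, seed = 1)
  expect_identical(st0$imputations[[1]], tab)
  expect_identical(st0$imputations[[2]], tab)

  tab_m <- tab
  tab_m$x1[sample(n, 30)] <- NA
  tab_m$x2[sample(n, 20)] <- NA
  st <- mice_impute(tab_m, labels, m = 4, iterations = 3, seed = 2)
  for (d in st$imputations) {
    expect_false(anyNA(d))
    # observed cells identical across imputations
    expect_equal(d$x1[!is.na(tab_m$x1)], tab_m$x1[!is.na(tab_m$x1)])
    expect_equal(d$x2[!is.na(tab_m$x2)], tab_m$x2[!is.na(tab_m$x2)])
    # PMM imputes observed donor values only
    expect_true(all(d$x1[is.na(tab_m$x1)] %in% tab_m$x1[!is.na(tab_m$x1)]))
    expect_true(all(d$x2 %in% c(0, 1)))
  }
  expect_error(mice_impute(data.frame(x = rep(NA_real_, 5)),
                           rep("a", 5)), "no observed values")
})

test_that("MCAR imputation keeps the pooled coefficient near the complete-data fit", {
  set.seed(4)
  n <- 800
  x <- rnorm(n)
  w <- rbinom(n, 1, 0.5)
  eta <- cbind(0, -0.5 + 0.8 * x + 0.4 * w)
  p <- exp(eta) / rowSums(exp(eta))
  y <- ifelse(runif(n) < p[, 2], "case", "ref")
  tab <- data.frame(x = x, w = w)
  full_fit <- fit_multinomial(tab, y, "ref", standardize_continuous = FALSE)
  tab_m <- tab
  tab_m$x[sample(n, 80)] <- NA
  st <- mice_impute(tab_m, y, m = 10, iterations = 5, seed = 5)
  fits <- lapply(st$imputations, function(d)
    fit_multinomial(d, y, "ref", standardize_continuous = FALSE))
  pooled <- pool_rubin(fits)
  b_full <- full_fit$estimate[full_fit$term == "x"]
  b_pool <- pooled$estimate[pooled$term == "x"]
  expect_lt(abs(b_pool - b_full), 0.1)
})

test_that("single-binary-predictor ORs equal the contingency ad/bc", {
  set.seed(6)
  n <- 600
  v <- rbinom(n, 1, 0.4)
  g <- ifelse(runif(n) < plogis(-0.3 + 0.9 * v), "case", "ref")
  fit <- fit_multinomial(data.frame(v = v), g, "ref")
  tab <- table(v, g)
  or_hand <- (tab["1", "case"] * tab["0", "ref"]) /
    (tab["0", "case"] * tab["1", "ref"])
  expect_equal(exp(fit$estimate[fit$term == "v"]), or_hand, tolerance = 1e-4)
  expect_error(fit_multinomial(data.frame(v = v, v2 = v), g, "ref"),
               "rank deficient")
  expect_error(fit_multinomial(data.frame(v = v), g, "nonexistent"),
               "reference_cluster")
})

test_that("Rubin pooling reproduces the worked example and its degenerate case", {
  f1 <- data.frame(cluster = "c2", term = "x", estimate = 1.0, se = 0.5)
  f2 <- data.frame(cluster = "c2", term = "x", estimate = 2.0, se = 0.5)
  pooled <- pool_rubin(list(f1, f2))
  expect_equal(pooled$estimate, 1.5)
  expect_equal(pooled$W, 0.25)
  expect_equal(pooled$B, 0.5)
  expect_equal(pooled$T, 1.0)
  expect_true(pooled$ci_lo < pooled$or && pooled$or < pooled$ci_hi)

  # identical estimates: B = 0, T = W, normal-theory CI
  same <- replicate(5, f1, simplify = FALSE)
  p2 <- pool_rubin(same)
  expect_equal(p2$B, 0)
  expect_equal(p2$T, p2$W)
  expect_equal(p2$df, Inf)
  expect_equal(log(p2$ci_hi), 1.0 + qnorm(0.975) * 0.5, tolerance = 1e-9)

  expect_warning(pool_rubin(list(f1)), "one imputation")
  f3 <- data.frame(cluster = "c2", term = "y", estimate = 1, se = 0.5)
  expect_error(pool_rubin(list(f1, f3)), "differ")
})

test_that("pooled inference holds its nominal type-I error on a null covariate", {
  set.seed(12)
  reps <- 200
  pvals <- vapply(seq_len(reps), function(r) {
    n <- 150
    x <- rnorm(n)
    g <- sample(c("a", "b"), n, replace = TRUE)  # label independent of x
    f <- fit_multinomial(data.frame(x = x), g, "a")
    # two pseudo-imputations of identical complete data
    pool_rubin(list(f, f))$p_value[f$term == "x"]
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
})

test_that("Nagelkerke R2 matches the two-line formula and its limits", {
  expect_equal(nagelkerke_r2(-100, -100, 50), 0)
  # independent two-line evaluation on a small fixture
  set.seed(7)
  x <- rnorm(120)
  g <- ifelse(runif(120) < plogis(1.5 * x), "b", "a")
  fit <- fit_multinomial(data.frame(x = x), g, "a")
  l1 <- attr(fit, "loglik"); l0 <- attr(fit, "loglik_null")
  r2_cs <- 1 - exp(2 * (l0 - l1) / 120)
  expect_equal(nagelkerke_r2(l1, l0, 120), r2_cs / (1 - exp(2 * l0 / 120)))
  # near-perfect separation pushes the statistic to 1
  expect_gt(nagelkerke_r2(-1e-6, -80, 120), 0.999)
  expect_error(nagelkerke_r2(-10, -5, 120), "loglik")
  expect_error(nagelkerke_r2(-5, -10, 0), "n")
})

test_that("VIF matches closed forms, orthogonality and collinearity", {
  set.seed(8)
  n <- 4000
  x1 <- rnorm(n)
  # build an exactly r = 0.6 pair: VIF = 1 / (1 - 0.36) = 1.5625
  x2r <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  # orthogonalize empirically to hit r exactly
  e <- residuals(lm(x2r ~ x1))
  x2 <- 0.6 * scale(x1)[, 1] + sqrt(1 - 0.36) * scale(e)[, 1]
  v <- compute_vif(data.frame(x1 = scale(x1)[, 1], x2 = x2))
  expect_equal(v$vif, rep(1 / (1 - 0.36), 2), tolerance = 1e-6)

  ortho <- compute_vif(data.frame(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1),
                                  c = c(1, -1, -1, 1)))
  expect_equal(ortho$vif, rep(1, 3))

  dup <- data.frame(a = rnorm(50))
  dup$b <- dup$a
  dup$c <- rnorm(50)
  expect_true(any(!is.finite(compute_vif(dup)$vif)))
})

test_that("true log-odds are recovered end to end from generated cohorts", {
  # single replicate here (the multi-replicate coverage study lives in
  # the acceptance suite): estimate close to truth, CI covers it
  sp <- make_reg_spec()
  set.seed(21)
  cov <- draw_covariates(sp)
  lab <- draw_classes(sp, cov)
  fit <- fit_multinomial(cov[c("exposure", "noise_cont")], lab, "unaffected")
  est <- fit$estimate[fit$term == "exposure" & fit$cluster == "internalizing"]
  se <- fit$se[fit$term == "exposure" & fit$cluster == "internalizing"]
  expect_lt(abs(est - 0.7), 0.3)
  expect_true(est - 1.96 * se < 0.7 && 0.7 < est + 1.96 * se)
})

test_that("pooled OR table is invariant to the ordering of non-reference clusters", {
  set.seed(13)
  n <- 400
  v <- rbinom(n, 1, 0.5)
  g <- sample(c("ref", "b", "c"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  f1 <- fit_multinomial(data.frame(v = v), factor(g, levels = c("ref", "b", "c")), "ref")
  f2 <- fit_multinomial(data.frame(v = v), factor(g, levels = c("c", "b", "ref")), "ref")
  k1 <- paste(f1$cluster, f1$term)
  k2 <- paste(f2$cluster, f2$term)
  expect_setequal(k1, k2)
  expect_equal(f2$estimate[match(k1, k2)], f1$estimate, tolerance = 1e-6)
})
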