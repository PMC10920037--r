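test_that("assessment catalog reproduces the instrument score bounds and missing waves", {
  cat <- default_assessments()
  expect_length(cat, 14)
  # summed scales: score_max = n_items * item_max
  for (a in cat) {
    expect_equal(a$score_max, a$n_items * a$item_max)
    expect_equal(a$score_min, a$n_items * a$item_min)
  }
  expect_equal(cat$depression_self$score_max, 26)      # self depression 0-26
  expect_equal(cat$emotional_caregiver$score_max, 10)  # caregiver emotional 0-10
  expect_equal(cat$selfharm_self$score_max, 1)         # self-harm 0-1
  # CBCL-derived scales absent at T3; self-harm/suicidal ideation absent at T1
  for (nm in c("ple_caregiver", "obsession_caregiver", "somatic_caregiver",
               "withdrawal_caregiver"))
    expect_false("T3" %in% cat[[nm]]$waves_administered)
  expect_false("T1" %in% cat$selfharm_self$waves_administered)
  expect_false("T1" %in% cat$suicidal_self$waves_administered)
  expect_true(all(c("T1", "T2", "T3", "T4") %in%
                    cat$depression_self$waves_administered))
})

test_that("severity_to_items respects limits and its binomial mean", {
  a5 <- assessment_spec("toy", "self", n_items = 5, item_min = 0, item_max = 2)
  set.seed(1)
  expect_true(all(severity_to_items(rep(-50, 20), a5) == 0))
  expect_true(all(severity_to_items(rep(50, 20), a5) == 2))
  # severity 0 with b = 0: items ~ Binomial(2, 0.5), mean summed score = 5
  set.seed(2)
  scores <- rowSums(severity_to_items(rep(0, 20000), a5, a = 0.8, b = 0))
  expect_equal(mean(scores), 5, tolerance = 0.02)
})

test_that("generated tables respect bounds, structural waves and cardinality", {
  co <- study_cohort()
  spec <- co$spec_echo
  # bounds hold on every observed item
  for (a_name in names(spec$assessments)) {
    a <- spec$assessments[[a_name]]
    v <- co$item_table$value[co$item_table$assessment == a_name]
    v <- v[!is.na(v)]
    expect_gte(min(v), a$item_min)
    expect_lte(max(v), a$item_max)
    # no records outside administered waves
    expect_true(all(co$item_table$wave[co$item_table$assessment == a_name] %in%
                      a$waves_administered))
  }
  # scale_table: one row per participant x administered (assessment, wave)
  n_admin <- sum(vapply(spec$assessments, function(a)
    length(a$waves_administered), numeric(1)))
  expect_equal(nrow(co$scale_table), spec$n_participants * n_admin)
})

test_that("regeneration with a fixed seed is byte-identical", {
  sp <- low_noise_spec(n = 60, seed = 77)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1$item_table, c2$item_table)
  expect_identical(c1$covariate_table, c2$covariate_table)
  expect_identical(c1$true_labels, c2$true_labels)
})

test_that("degenerate noise collapses each class to one score vector", {
  sp <- cohort_spec(n_participants = 40, within_class_sd = 1e-9,
                    random_intercept_sd = 0, item_missing_rate = 0,
                    scale_missing_rate = 0, dropout_rate = 0, seed = 4)
  # degenerate draws need a deterministic item map: push severities to the
  # saturated ends so the binomial draw is deterministic per class
  sp$class_profiles <- lapply(sp$class_profiles,
                              function(m) ifelse(m > 0, 100, -100))
  co <- generate_cohort(sp)
  for (cl in levels(co$true_labels)) {
    ids <- co$covariate_table$participant[co$true_labels == cl]
    if (length(ids) < 2) next
    sub <- co$scale_table[co$scale_table$participant %in% ids, ]
    per_cell <- tapply(sub$score, paste(sub$wave, sub$assessment),
                       function(v) length(unique(v)))
    expect_true(all(per_cell == 1))
  }
})

test_that("intercept calibration hits target shares within Monte-Carlo error", {
  sp <- cohort_spec(n_participants = 2000, seed = 101)
  co <- generate_cohort(sp)
  emp <- as.numeric(table(co$true_labels)) / 2000
  target <- sp$class_shares_target
  se <- sqrt(target * (1 - target) / 2000)
  expect_true(all(abs(emp - target) <= 3 * se + 0.005))
})

test_that("missingness rates are realized and rate-0 leaves only structural gaps", {
  sp <- cohort_spec(n_participants = 1000, item_missing_rate = 0.02,
                    scale_missing_rate = 0.01, dropout_rate = 0, seed = 8)
  co <- generate_cohort(sp)
  frac <- mean(is.na(co$item_table$value))
  # expected blanks: scale blanks plus item blanks among the rest
  expected <- 0.01 + 0.99 * 0.02
  se <- sqrt(expected * (1 - expected) / nrow(co$item_table))
  expect_lt(abs(frac - expected), 3 * se + 0.002)

  sp0 <- cohort_spec(n_participants = 50, item_missing_rate = 0,
                     scale_missing_rate = 0, dropout_rate = 0, seed = 8)
  co0 <- generate_cohort(sp0)
  expect_false(anyNA(co0$item_table$value))

  co1 <- apply_missingness(co0, item_missing_rate = 1)
  expect_true(all(is.na(co1$item_table$value)))
  expect_true(all(is.na(co1$scale_table$score)))
})

test_that("covariates carry class information iff true_beta is nonzero", {
  sp <- cohort_spec(n_participants = 1500, seed = 31)
  set.seed(31)
  cov <- draw_covariates(sp)
  lab <- draw_classes(sp, cov)
  # chi-square on a strongly weighted binary covariate: association present
  expect_lt(chisq.test(table(cov$bully_victim, lab))$p.value, 0.01)
  # null model: zero slopes
  sp0 <- sp
  sp0$true_beta[-1, ] <- 0
  lab0 <- draw_classes(sp0, cov)
  expect_gt(chisq.test(table(cov$bully_victim, lab0))$p.value, 0.01)
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(cohort_spec(class_shares_target = c(0.5, 0.2, 0.1, 0.1, 0.2)),
               "class_shares_target")
  bad_prof <- default_class_profiles()
  rownames(bad_prof$severe)[1] <- "not_an_assessment"
  expect_error(cohort_spec(class_profiles = bad_prof), "unknown assessment")
  expect_error(cohort_spec(within_class_sd = 0), "within_class_sd")
})

test_that("cohort round-trips through CSV + YAML sidecars", {
  dir <- withr::local_tempdir()
  sp <- low_noise_spec(n = 30, seed = 9)
  co <- generate_cohort(sp)
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("item_table.csv", "scale_table.csv", "covariate_table.csv",
      "truth.json", "cohort_spec.yaml")))))
  sp2 <- spec_from_list(file.path(dir, "cohort_spec.yaml"))
  co2 <- generate_cohort(sp2)
  expect_equal(co2$scale_table$score, co$scale_table$score)
  expect_equal(as.character(co2$true_labels), as.character(co$true_labels))
})
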