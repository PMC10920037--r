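#' Default latent class-profile catalog
#'
#' Mean latent severity (z-units) per class, assessment and wave for the
#' five-class default cohort. The qualitative shapes follow the cluster
#' phenomenology the model is meant to recover:
#' * `unaffected`: -0.3 flat on every assessment;
#' * `internalizing`: +0.8 on internalizing scales, with a +0.3/wave
#'   worsening slope on somatic symptoms, withdrawal and suicidal
#'   ideation;
#' * `discrepant`: +0.8 on self-report scales only (caregiver scales
#'   near 0), with the largest elevation (+1.2) on self-harm and
#'   suicidal ideation;
#' * `externalizing`: +1.0 on hyperactivity/inattention and conduct
#'   problems only;
#' * `severe`: +1.5 on all caregiver scales and +1.0 on self-report.
#'
#' @param assessments assessment catalog, as [default_assessments()].
#' @param waves wave labels.
#' @return named list mapping class name to a D x T matrix of latent
#'   severities (assessments x waves).
#' @export
default_class_profiles <- function(assessments = default_assessments(),
                                   waves = c("T1", "T2", "T3", "T4")) {
  d_names <- names(assessments)
  t_n <- length(waves)
  blank <- function(fill = 0) {
    matrix(fill, nrow = length(d_names), ncol = t_n,
           dimnames = list(d_names, waves))
  }
  internalizing <- c("depression_self", "emotional_caregiver",
                     "sociality_caregiver", "somatic_caregiver",
                     "withdrawal_caregiver", "suicidal_self")
  worsening <- c("somatic_caregiver", "withdrawal_caregiver", "suicidal_self")
  self_scales <- d_names[vapply(assessments, `[[`, character(1), "informant") == "self"]
  caregiver_scales <- setdiff(d_names, self_scales)

  p_unaff <- blank(-0.3)

  p_int <- blank()
  p_int[internalizing, ] <- 0.8
  for (s in worsening) p_int[s, ] <- 0.8 + 0.3 * (seq_len(t_n) - 1)

  p_disc <- blank()
  p_disc[self_scales, ] <- 0.8
  p_disc[c("selfharm_self", "suicidal_self"), ] <- 1.2

  p_ext <- blank()
  p_ext[c("hyperactivity_caregiver", "conduct_caregiver"), ] <- 1.0

  p_sev <- blank()
  p_sev[caregiver_scales, ] <- 1.5
  p_sev[self_scales, ] <- 1.0

  list(unaffected = p_unaff, internalizing = p_int, discrepant = p_disc,
       externalizing = p_ext, severe = p_sev)
}

#' Default baseline covariate catalog
#'
#' Ten representative baseline characteristics mirroring the families of
#' predictors studied for trajectory-class membership: child sex,
#' autistic traits, bullying victimization and perpetration, avoidance of
#' help-seeking for depression, caregiver psychological distress and
#' psychiatric diagnosis, maternal smoking in pregnancy, gestation weeks
#' and dissatisfaction with family. Continuous covariates enter the true
#' class-membership model on a standardized scale (gestation weeks are
#' sign-flipped so that shorter gestation raises risk), so `true_beta`
#' slopes are log-odds per SD for continuous covariates and per category
#' for binary ones.
#'
#' @return data.frame with columns name, type, p1, p2 (Bernoulli
#'   probability, or mean and sd), and flip (sign-flip of the
#'   standardized value in the linear predictor).
#' @export
default_covariates <- function() {
  data.frame(
    name = c("sex_female", "autistic_traits", "bully_victim", "bully_perp",
             "helpseek_avoid", "caregiver_distress", "caregiver_diagnosis",
             "maternal_smoking", "gestation_weeks", "family_dissatisfaction"),
    type = c("binary", "continuous", "binary", "binary", "binary",
             "continuous", "binary", "binary", "continuous", "continuous"),
    p1 = c(0.47, 0, 0.2, 0.1, 0.25, 0, 0.08, 0.1, 39, 0),
    p2 = c(NA, 1, NA, NA, NA, 1, NA, NA, 1.5, 1),
    flip = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default true log-odds of class membership
#'
#' Slope matrix of the true multinomial-logit model generating class
#' labels from baseline covariates, reference class `unaffected`.
#' Directions follow the known epidemiology the generator emulates:
#' female sex raises internalizing/discrepant and lowers externalizing
#' membership; autistic traits and bullying victimization raise all four
#' affected classes; help-seeking avoidance and caregiver diagnosis mark
#' the discrepant class; maternal smoking, caregiver distress, family
#' dissatisfaction and shorter gestation mark the severe class, with a
#' negative bullying-perpetration effect there. Intercepts (first row)
#' are placeholders; they are calibrated to the target class shares when
#' a [cohort_spec()] is built.
#'
#' @param covariates covariate catalog data.frame.
#' @param class_names class names; first is the reference.
#' @return (1 + n_covariates) x (K - 1) matrix, log-odds units.
#' @export
default_true_beta <- function(covariates = default_covariates(),
                              class_names = c("unaffected", "internalizing",
                                              "discrepant", "externalizing",
                                              "severe")) {
  k1 <- class_names[-1]
  beta <- matrix(0, nrow = nrow(covariates) + 1, ncol = length(k1),
                 dimnames = list(c("(Intercept)", covariates$name), k1))
  set_b <- function(cov, cls, val) beta[cov, cls] <<- val
  set_b("sex_female", "internalizing", 0.70)
  set_b("sex_female", "discrepant", 0.40)
  set_b("sex_female", "externalizing", -0.40)
  set_b("autistic_traits", c("internalizing", "discrepant", "externalizing", "severe"),
        c(0.65, 0.35, 0.45, 0.80))
  set_b("bully_victim", c("internalizing", "discrepant", "externalizing", "severe"),
        c(0.65, 0.60, 0.75, 1.25))
  set_b("bully_perp", "severe", -0.90)
  set_b("helpseek_avoid", "discrepant", 0.60)
  set_b("caregiver_distress", c("discrepant", "severe"), c(0.20, 0.60))
  set_b("caregiver_diagnosis", c("discrepant", "severe"), c(0.70, 0.40))
  set_b("maternal_smoking", "severe", 1.00)
  set_b("gestation_weeks", "severe", 0.20)
  set_b("family_dissatisfaction", c("internalizing", "severe"), c(0.20, 0.45))
  beta
}

#' Specify a synthetic cohort
#'
#' Bundles everything the generator needs: sample size, assessment
#' catalog, latent class profiles, target class shares, noise levels,
#' baseline covariates with their true class-membership log-odds, and
#' missingness rates. Class labels are drawn from a true
#' multinomial-logit model (covariates -> class -> trajectories), which
#' makes the downstream predictor regression correctly specified and its
#' coefficient recovery a clean validation. Intercepts are calibrated at
#' construction so expected class shares match `class_shares_target`
#' within 0.005.
#'
#' @param n_participants cohort size.
#' @param assessments assessment catalog ([default_assessments()]).
#' @param class_names class names; first is the reference class.
#' @param class_shares_target simplex vector of target shares; the
#'   default (0.605, 0.162, 0.099, 0.096, 0.039) follows the observed
#'   five-cluster composition the generator emulates.
#' @param class_profiles named list of D x T latent-severity matrices.
#' @param within_class_sd SD of the occasion-level Gaussian noise on
#'   latent severity (z-units, > 0).
#' @param random_intercept_sd SD of the participant-level random
#'   intercept shared across assessments and waves (>= 0).
#' @param covariate_catalog covariate catalog data.frame.
#' @param true_beta slope matrix, intercept row first; intercepts are
#'   re-calibrated here.
#' @param item_missing_rate,scale_missing_rate,dropout_rate probabilities
#'   in \[0, 1\].
#' @param waves wave labels (default T1-T4, ages 10/12/14/16).
#' @param seed integer seed for generation.
#' @param calibrate logical; set `FALSE` to keep `true_beta` intercepts
#'   as given.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 500,
                        assessments = default_assessments(),
                        class_names = c("unaffected", "internalizing",
                                        "discrepant", "externalizing", "severe"),
                        class_shares_target = c(0.605, 0.162, 0.099, 0.096, 0.039),
                        class_profiles = default_class_profiles(assessments),
                        within_class_sd = 0.4,
                        random_intercept_sd = 0.25,
                        covariate_catalog = default_covariates(),
                        true_beta = default_true_beta(covariate_catalog, class_names),
                        item_missing_rate = 0.02,
                        scale_missing_rate = 0.02,
                        dropout_rate = 0,
                        waves = c("T1", "T2", "T3", "T4"),
                        seed = 1L,
                        calibrate = TRUE) {
  if (n_participants < 1) stop_field("n_participants", "must be positive")
  # printed shares can carry rounding slack (e.g. 60.5+16.2+9.9+9.6+3.9
  # = 100.1%); tolerate it and renormalize exactly
  if (abs(sum(class_shares_target) - 1) > 0.005)
    stop_field("class_shares_target", "must sum to 1")
  class_shares_target <- class_shares_target / sum(class_shares_target)
  if (any(class_shares_target <= 0))
    stop_field("class_shares_target", "must be strictly positive")
  if (length(class_shares_target) != length(class_names))
    stop_field("class_shares_target", "length must match class_names")
  if (within_class_sd <= 0) stop_field("within_class_sd", "must be > 0")
  if (random_intercept_sd < 0) stop_field("random_intercept_sd", "must be >= 0")
  for (r in c(item_missing_rate, scale_missing_rate, dropout_rate))
    if (r < 0 || r > 1) stop_field("missingness rate", "must lie in [0, 1]")
  if (!setequal(names(class_profiles), class_names))
    stop_field("class_profiles", "classes must match class_names")
  for (cl in class_names) {
    prof <- class_profiles[[cl]]
    unknown <- setdiff(rownames(prof), names(assessments))
    if (length(unknown))
      stop_field("class_profiles",
                 paste("unknown assessment:", paste(unknown, collapse = ", ")))
    if (ncol(prof) != length(waves))
      stop_field("class_profiles", "profile wave count must match waves")
  }
  if (!identical(rownames(true_beta),
                 c("(Intercept)", covariate_catalog$name)))
    stop_field("true_beta", "rows must be (Intercept) then covariate names")
  if (ncol(true_beta) != length(class_names) - 1)
    stop_field("true_beta", "needs one column per non-reference class")

  spec <- structure(list(
    n_participants = as.integer(n_participants),
    assessments = assessments,
    class_names = class_names,
    class_shares_target = class_shares_target,
    class_profiles = class_profiles,
    within_class_sd = within_class_sd,
    random_intercept_sd = random_intercept_sd,
    covariate_catalog = covariate_catalog,
    true_beta = true_beta,
    item_missing_rate = item_missing_rate,
    scale_missing_rate = scale_missing_rate,
    dropout_rate = dropout_rate,
    waves = waves,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  if (calibrate) spec$true_beta <- calibrate_intercepts(spec)
  spec
}

#' Calibrate multinomial-logit intercepts to target class shares
#'
#' Adjusts the intercept row of `true_beta` so that the expected class
#' shares under the covariate distribution match `class_shares_target`
#' to within `tol`, by a damped log-ratio fixed-point iteration on a
#' fixed Monte-Carlo covariate sample.
#'
#' @param spec a [cohort_spec()] (calibration state ignored).
#' @param tol maximum absolute share error (default 0.005).
#' @param n_mc Monte-Carlo sample size for the expectation.
#' @return `true_beta` with a calibrated intercept row.
#' @export
calibrate_intercepts <- function(spec, tol = 0.005, n_mc = 20000) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(104729L)
  X <- draw_covariates(spec, n_mc)
  Z <- model_scale_covariates(X, spec$covariate_catalog)
  beta <- spec$true_beta
  target <- spec$class_shares_target
  for (iter in 1:300) {
    shares <- colMeans(class_probabilities(Z, beta))
    if (max(abs(shares - target)) < tol) break
    beta[1, ] <- beta[1, ] +
      0.9 * (log(target[-1] / shares[-1]) - log(target[1] / shares[1]))
  }
  beta
}

# covariates on the scale entering the linear predictor:
# binary as 0/1, continuous standardized by catalog mean/sd, optionally
# sign-flipped (gestation weeks: shorter gestation -> higher risk)
model_scale_covariates <- function(X, catalog) {
  Z <- as.matrix(X[, catalog$name, drop = FALSE])
  for (j in seq_len(nrow(catalog))) {
    if (catalog$type[j] == "continuous") {
      z <- (Z[, j] - catalog$p1[j]) / catalog$p2[j]
      Z[, j] <- if (catalog$flip[j]) -z else z
    }
  }
  Z
}

# softmax class probabilities under the true model; Z model-scaled
class_probabilities <- function(Z, beta) {
  eta <- cbind(0, sweep(Z %*% beta[-1, , drop = FALSE], 2, beta[1, ], "+"))
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Draw baseline covariates from their marginals
#'
#' @param spec a [cohort_spec()].
#' @param n number of participants.
#' @return data.frame with `participant` id column plus one column per
#'   covariate in the catalog.
#' @export
draw_covariates <- function(spec, n = spec$n_participants) {
  catalog <- spec$covariate_catalog
  out <- data.frame(participant = seq_len(n))
  for (j in seq_len(nrow(catalog))) {
    out[[catalog$name[j]]] <- switch(catalog$type[j],
      binary = stats::rbinom(n, 1, catalog$p1[j]),
      continuous = stats::rnorm(n, catalog$p1[j], catalog$p2[j]),
      stop_field("covariate type", catalog$type[j]))
  }
  out
}

#' Draw class labels from the true membership model
#'
#' Samples each participant's trajectory class from the multinomial
#' logit defined by `spec$true_beta` evaluated at their covariates
#' (continuous covariates on the standardized, possibly sign-flipped
#' scale). Used inside [generate_cohort()] and directly for
#' coefficient-recovery studies that do not need trajectories.
#'
#' @param spec a [cohort_spec()].
#' @param covariate_table covariates as from [draw_covariates()].
#' @return factor of class labels with levels `spec$class_names`.
#' @export
draw_classes <- function(spec, covariate_table) {
  Z <- model_scale_covariates(covariate_table, spec$covariate_catalog)
  probs <- class_probabilities(Z, spec$true_beta)
  ks <- apply(probs, 1, function(p) sample.int(length(p), 1, prob = p))
  factor(spec$class_names[ks], levels = spec$class_names)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> n=%d, %d classes (%s), %d assessments, %d waves, seed=%d\n",
              x$n_participants, length(x$class_names),
              paste(x$class_names, collapse = "/"),
              length(x$assessments), length(x$waves), x$seed))
  invisible(x)
}
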