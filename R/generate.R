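#' Convert latent severities to item responses
#'
#' Items are conditionally independent given the latent severity: each
#' item is `Binomial(item_max - item_min, plogis(a * severity + b)) +
#' item_min`. With the defaults the item success probability is 0.30 at
#' severity 0 (`b = qlogis(0.3)`) and rises with severity at slope
#' `a = 0.8`, giving the right-skewed score distributions typical of
#' community psychopathology scales. Binary queries (self-harm) reduce
#' to a single Bernoulli item.
#'
#' @param severity numeric vector of latent severities (z-units,
#'   unbounded).
#' @param assessment an [assessment_spec()].
#' @param a,b logistic slope and intercept of the item response model.
#' @return integer matrix, `length(severity)` rows x `n_items` columns.
#' @export
severity_to_items <- function(severity, assessment, a = 0.8, b = stats::qlogis(0.3)) {
  n <- length(severity)
  size <- assessment$item_max - assessment$item_min
  p <- stats::plogis(a * severity + b)
  m <- matrix(stats::rbinom(n * assessment$n_items, size, rep(p, assessment$n_items)),
              nrow = n, ncol = assessment$n_items)
  m + assessment$item_min
}

#' Generate a synthetic cohort with known trajectory classes
#'
#' The generative direction is covariates -> class -> trajectories:
#' baseline covariates are sampled from their marginals, the class label
#' is drawn from the true multinomial-logit model in
#' `spec$true_beta` (intercepts pre-calibrated to the target shares),
#' latent severity per (assessment, wave) is the class profile plus a
#' participant random intercept plus occasion noise, items are drawn
#' from the graded item-response model, scale scores are item sums, and
#' missingness (structural waves, whole-scale blanks, item blanks,
#' dropout) is applied last. Regeneration with the same spec is
#' byte-identical.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `generated_cohort`: list with `item_table`
#'   (participant, wave, informant, assessment, item, value),
#'   `scale_table` (participant, wave, assessment, score),
#'   `covariate_table`, `true_labels` (factor) and `spec_echo`. Rows
#'   absent from the tables mean "not administered at that wave"; `NA`
#'   values mean "administered but missing".
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  waves <- spec$waves

  covariate_table <- draw_covariates(spec, n)
  true_labels <- draw_classes(spec, covariate_table)
  ks <- as.integer(true_labels)

  u <- stats::rnorm(n, 0, spec$random_intercept_sd)

  item_rows <- list()
  for (a_name in names(spec$assessments)) {
    a <- spec$assessments[[a_name]]
    for (w in intersect(waves, a$waves_administered)) {
      wi <- match(w, waves)
      prof <- vapply(spec$class_profiles[spec$class_names],
                     function(m) m[a_name, wi], numeric(1))
      sev <- prof[ks] + u + stats::rnorm(n, 0, spec$within_class_sd)
      items <- severity_to_items(sev, a)
      item_rows[[length(item_rows) + 1]] <- data.frame(
        participant = rep(seq_len(n), a$n_items),
        wave = w,
        informant = a$informant,
        assessment = a_name,
        item = rep(seq_len(a$n_items), each = n),
        value = as.vector(items),
        stringsAsFactors = FALSE
      )
    }
  }
  item_table <- do.call(rbind, item_rows)

  cohort <- structure(list(
    item_table = item_table,
    scale_table = NULL,
    covariate_table = covariate_table,
    true_labels = true_labels,
    spec_echo = spec
  ), class = "generated_cohort")

  cohort <- apply_missingness(cohort,
                              item_missing_rate = spec$item_missing_rate,
                              scale_missing_rate = spec$scale_missing_rate,
                              dropout_rate = spec$dropout_rate)
  cohort$scale_table <- score_cohort(cohort$item_table, spec$assessments)
  cohort
}

#' Apply item-, scale- and participant-level missingness
#'
#' Structurally absent (assessment, wave) cells never have rows in the
#' first place; on top of that, whole-scale blanks are drawn at
#' `scale_missing_rate` per (participant, assessment, wave), item blanks
#' at `item_missing_rate` among remaining items, and dropout removes all
#' records of a participant after a uniformly chosen wave. Item- and
#' scale-level missingness are distinguished because downstream
#' imputation only applies when at least one response was given.
#'
#' @param cohort a `generated_cohort` (scale_table may be NULL; it is
#'   rebuilt by scoring after imputation).
#' @param item_missing_rate,scale_missing_rate,dropout_rate probabilities.
#' @return the cohort with `NA` blanks in `item_table` and dropped
#'   post-dropout rows; `scale_table` is re-scored if present.
#' @export
apply_missingness <- function(cohort, item_missing_rate = 0,
                              scale_missing_rate = 0, dropout_rate = 0) {
  for (r in c(item_missing_rate, scale_missing_rate, dropout_rate))
    if (r < 0 || r > 1) stop_field("missingness rate", "must lie in [0, 1]")
  it <- cohort$item_table
  waves <- cohort$spec_echo$waves

  if (dropout_rate > 0) {
    n <- cohort$spec_echo$n_participants
    drops <- stats::runif(n) < dropout_rate
    last_wave <- ifelse(drops, sample.int(length(waves) - 1, n, replace = TRUE),
                        length(waves))
    keep <- match(it$wave, waves) <= last_wave[it$participant]
    it <- it[keep, , drop = FALSE]
  }

  if (scale_missing_rate > 0) {
    cell <- paste(it$participant, it$wave, it$assessment)
    cells <- unique(cell)
    blank_cells <- cells[stats::runif(length(cells)) < scale_missing_rate]
    it$value[cell %in% blank_cells] <- NA_integer_
  }

  if (item_missing_rate > 0) {
    obs <- !is.na(it$value)
    hit <- obs & stats::runif(nrow(it)) < item_missing_rate
    it$value[hit] <- NA_integer_
  }

  cohort$item_table <- it
  if (!is.null(cohort$scale_table))
    cohort$scale_table <- score_cohort(it, cohort$spec_echo$assessments)
  cohort
}

#' Write a generated cohort to plain-text files
#'
#' Emits `item_table.csv`, `scale_table.csv`, `covariate_table.csv` and a
#' `truth.json` sidecar holding true labels and the true log-odds
#' matrix, plus `cohort_spec.yaml` so the cohort can be regenerated.
#'
#' @param cohort a `generated_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$item_table, file.path(dir, "item_table.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$scale_table, file.path(dir, "scale_table.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariate_table, file.path(dir, "covariate_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(true_labels = as.character(cohort$true_labels),
         true_beta = as.data.frame(cohort$spec_echo$true_beta)),
    file.path(dir, "truth.json"), digits = NA)
  yaml::write_yaml(spec_to_list(cohort$spec_echo),
                   file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}

# cohort_spec <-> plain list, for YAML round-tripping
spec_to_list <- function(spec) {
  list(
    n_participants = spec$n_participants,
    class_names = spec$class_names,
    class_shares_target = spec$class_shares_target,
    within_class_sd = spec$within_class_sd,
    random_intercept_sd = spec$random_intercept_sd,
    item_missing_rate = spec$item_missing_rate,
    scale_missing_rate = spec$scale_missing_rate,
    dropout_rate = spec$dropout_rate,
    waves = spec$waves,
    seed = spec$seed,
    assessments = lapply(spec$assessments, function(a)
      a[c("name", "informant", "n_items", "item_min", "item_max",
          "waves_administered", "binary")]),
    class_profiles = lapply(spec$class_profiles, function(m)
      list(assessments = rownames(m), values = as.vector(m))),
    covariate_catalog = as.list(spec$covariate_catalog),
    true_beta = list(rownames = rownames(spec$true_beta),
                     colnames = colnames(spec$true_beta),
                     values = as.vector(spec$true_beta))
  )
}

#' Rebuild a cohort spec from its YAML/list form
#'
#' @param x list as produced by the YAML serialization in
#'   [write_cohort()], or a path to such a YAML file.
#' @return a `cohort_spec` (intercepts taken as stored, not re-calibrated).
#' @export
spec_from_list <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  assessments <- lapply(x$assessments, function(a)
    assessment_spec(a$name, a$informant, a$n_items, a$item_min, a$item_max,
                    unlist(a$waves_administered), a$binary))
  names(assessments) <- vapply(assessments, `[[`, character(1), "name")
  profiles <- lapply(x$class_profiles, function(p)
    matrix(unlist(p$values), nrow = length(p$assessments),
           dimnames = list(unlist(p$assessments), unlist(x$waves))))
  beta <- matrix(unlist(x$true_beta$values),
                 nrow = length(x$true_beta$rownames),
                 dimnames = list(unlist(x$true_beta$rownames),
                                 unlist(x$true_beta$colnames)))
  catalog <- as.data.frame(x$covariate_catalog, stringsAsFactors = FALSE)
  cohort_spec(
    n_participants = x$n_participants,
    assessments = assessments,
    class_names = unlist(x$class_names),
    class_shares_target = unlist(x$class_shares_target),
    class_profiles = profiles,
    within_class_sd = x$within_class_sd,
    random_intercept_sd = x$random_intercept_sd,
    covariate_catalog = catalog,
    true_beta = beta,
    item_missing_rate = x$item_missing_rate,
    scale_missing_rate = x$scale_missing_rate,
    dropout_rate = x$dropout_rate,
    waves = unlist(x$waves),
    seed = x$seed,
    calibrate = FALSE
  )
}
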