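#' Cluster counts and percentage shares
#'
#' @param labels cluster labels (any atomic or factor).
#' @return data.frame (cluster, count, share_pct) in descending count
#'   order; shares are 100 * count / n rounded half-up to one decimal.
#' @export
cluster_shares <- function(labels) {
  if (!length(labels)) stop_field("labels", "is empty")
  counts <- sort(table(labels), decreasing = TRUE)
  data.frame(
    cluster = names(counts),
    count = as.integer(counts),
    share_pct = round_half_up(100 * as.integer(counts) / length(labels), 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-cluster mean trajectories with standard errors
#'
#' Masked means per (cluster, assessment, wave): only observed cells
#' contribute, SE = SD / sqrt(n_observed). Cells with no observation
#' (e.g. structurally missing waves) are absent from the output, not
#' zero.
#'
#' @param tensor a `trajectory_tensor`.
#' @param labels cluster labels aligned with the tensor's participants.
#' @return data.frame (cluster, assessment, wave, n_obs, mean, se).
#' @export
mean_trajectories <- function(tensor, labels) {
  n <- dim(tensor$values)[1]
  if (length(labels) != n)
    stop_field("labels", "length must match tensor participants")
  rows <- list()
  for (cl in sort(unique(labels))) {
    sel <- which(labels == cl)
    for (d in seq_along(tensor$assessment_names)) {
      for (t in seq_along(tensor$wave_labels)) {
        v <- tensor$values[sel, t, d]
        m <- tensor$mask[sel, t, d]
        v <- v[m == 1]
        if (!length(v)) next
        rows[[length(rows) + 1]] <- data.frame(
          cluster = cl, assessment = tensor$assessment_names[d],
          wave = tensor$wave_labels[t], n_obs = length(v),
          mean = mean(v),
          se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Name clusters by their nearest archetype profile
#'
#' A purely cosmetic reporting step: each cluster's mean z-score
#' trajectory is compared with the archetype profiles (flat-low,
#' internalizing-high, self-over-caregiver, externalizing-high,
#' all-high by default) by mean squared difference in z units — both
#' live on roughly the same scale, and unlike correlation this handles
#' the flat low archetype — and greedily assigned the closest archetype
#' name; labels stay arbitrary integers underneath.
#'
#' @param tensor a `trajectory_tensor`.
#' @param labels cluster labels.
#' @param profiles named list of D x T archetype matrices (default
#'   [default_class_profiles()], restricted to the tensor's
#'   assessments).
#' @return named character vector: cluster label -> archetype name.
#' @export
name_clusters <- function(tensor, labels, profiles = default_class_profiles()) {
  mt <- mean_trajectories(tensor, labels)
  clusters <- sort(unique(labels))
  corr <- matrix(NA_real_, length(clusters), length(profiles),
                 dimnames = list(as.character(clusters), names(profiles)))
  for (ci in seq_along(clusters)) {
    sub <- mt[mt$cluster == clusters[ci], ]
    for (pn in names(profiles)) {
      p <- profiles[[pn]]
      keep <- sub$assessment %in% rownames(p) & sub$wave %in% colnames(p)
      pv <- p[cbind(match(sub$assessment[keep], rownames(p)),
                    match(sub$wave[keep], colnames(p)))]
      corr[ci, pn] <- -mean((sub$mean[keep] - pv)^2)
    }
  }
  corr[is.na(corr)] <- -Inf
  out <- stats::setNames(rep(NA_character_, length(clusters)),
                         as.character(clusters))
  for (step in seq_along(clusters)) {
    best <- which(corr == max(corr), arr.ind = TRUE)[1, ]
    out[rownames(corr)[best[1]]] <- colnames(corr)[best[2]]
    corr[best[1], ] <- -Inf
    if (length(clusters) <= length(profiles)) corr[, best[2]] <- -Inf
  }
  out
}

#' Configure an end-to-end pipeline run
#'
#' @param cohort a [cohort_spec()] describing the simulated cohort.
#' @param vader a [vader_config()] for the final clustering.
#' @param k_max largest K for the prediction-strength curve (set to 0 to
#'   skip selection and use `vader$K`).
#' @param ps_repeats repeated halvings per K.
#' @param ps_threshold prediction-strength threshold for [choose_k()].
#' @param epoch_scale inner-loop epoch multiplier for model selection.
#' @param reference_cluster archetype name used as regression reference.
#' @param m_imputations,mice_iterations multiple-imputation settings.
#' @param all_baseline_participants sensitivity flag: keep every
#'   baseline participant instead of restricting to those observed at
#'   all waves.
#' @param skip_item_imputation sensitivity flag: leave item blanks in
#'   place (scale scores stay missing where any item is blank).
#' @param raw_binary_selfharm sensitivity flag: feed the binary
#'   self-harm indicator raw (0/1) instead of z-standardized.
#' @param seed master seed; all stages derive sub-seeds from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            vader = vader_config(K = 5),
                            k_max = 0, ps_repeats = 5, ps_threshold = 0.8,
                            epoch_scale = 0.5,
                            reference_cluster = "unaffected",
                            m_imputations = 20, mice_iterations = 5,
                            all_baseline_participants = FALSE,
                            skip_item_imputation = FALSE,
                            raw_binary_selfharm = FALSE,
                            seed = 1L) {
  structure(list(cohort = cohort, vader = vader, k_max = k_max,
                 ps_repeats = ps_repeats, ps_threshold = ps_threshold,
                 epoch_scale = epoch_scale,
                 reference_cluster = reference_cluster,
                 m_imputations = m_imputations,
                 mice_iterations = mice_iterations,
                 all_baseline_participants = all_baseline_participants,
                 skip_item_imputation = skip_item_imputation,
                 raw_binary_selfharm = raw_binary_selfharm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(con, stage, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full simulate-to-predictors pipeline
#'
#' Stages in order: simulate the cohort; impute partially missing items
#' (MissForest); score scales; restrict to the analysis population
#' (participants observed at all waves unless
#' `all_baseline_participants`); pool-standardize into the trajectory
#' tensor; optionally select K by prediction strength; cluster with the
#' recurrent variational deep embedding model; name and summarize
#' clusters; run the baseline-predictor analysis. Artifacts (CSV/JSON)
#' and a JSON-lines stage log are written to `out_dir` when given; a
#' stage failure halts with the stage name while earlier artifacts
#' persist.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @return list with `cohort`, `imputation_report`, `tensor`,
#'   `ps_curve` (or NULL), `selected_k`, `model`, `assignment`,
#'   `cluster_names`, `shares`, `trajectories`, `predictors`,
#'   `recovery_ari`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    con <- file(file.path(out_dir, "pipeline_log.jsonl"), open = "a")
    on.exit(close(con))
  }
  note <- function(stage, event, ...) {
    if (!is.null(con)) log_stage(con, stage, event, ...)
  }
  stage <- function(name, expr) {
    note(name, "start")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    note(name, "done", seconds = round(proc.time()[["elapsed"]] - t0, 2))
    out
  }

  cohort <- stage("simulate", generate_cohort(config$cohort))
  if (!is.null(out_dir)) write_cohort(cohort, file.path(out_dir, "cohort"))
  spec <- cohort$spec_echo

  imp <- NULL
  if (!config$skip_item_imputation) {
    imp <- stage("impute-items",
                 impute_cohort_items(cohort$item_table, spec$assessments,
                                     seed = derive_seed(config$seed, 11)))
    cohort$item_table <- imp$item_table
  }
  scale_table <- stage("score", score_cohort(cohort$item_table, spec$assessments))

  keep_ids <- unique(scale_table$participant)
  if (!config$all_baseline_participants) {
    obs <- scale_table[!is.na(scale_table$score), ]
    per_wave <- tapply(obs$participant, obs$wave, unique)
    keep_ids <- Reduce(intersect, per_wave)
  }
  scale_table <- scale_table[scale_table$participant %in% keep_ids, ]

  raw <- if (config$raw_binary_selfharm) "selfharm_self" else character(0)
  tensor <- stage("standardize",
                  standardize(scale_table, waves = spec$waves,
                              raw_assessments = raw))

  ps_curve <- NULL
  k_use <- config$vader$K
  if (config$k_max > 0) {
    ps_curve <- stage("select-k",
      prediction_strength_curve(tensor, config$k_max,
                                repeats = config$ps_repeats,
                                config = config$vader,
                                epoch_scale = config$epoch_scale,
                                seed = derive_seed(config$seed, 21)))
    k_use <- choose_k(ps_curve, config$ps_threshold)
    if (!is.null(out_dir))
      utils::write.csv(as.data.frame(ps_curve),
                       file.path(out_dir, "prediction_strength.csv"),
                       row.names = FALSE)
  }

  cfg <- config$vader
  cfg$K <- as.integer(k_use)
  cfg$seed <- derive_seed(config$seed, 31)
  model <- stage("cluster", fit_vader(tensor, cfg))
  assignment <- assign_clusters(model, tensor)

  cl_names <- name_clusters(tensor, assignment$labels,
                            profiles = spec$class_profiles)
  named_labels <- unname(cl_names[as.character(assignment$labels)])
  shares <- cluster_shares(named_labels)
  trajectories <- mean_trajectories(tensor, named_labels)

  truth <- cohort$true_labels[match(keep_ids, cohort$covariate_table$participant)]
  recovery_ari <- adjusted_rand_index(assignment$labels, as.integer(truth))

  reference <- config$reference_cluster
  if (!reference %in% named_labels) {
    reference <- shares$cluster[1]  # largest cluster as fallback reference
    warning(sprintf("reference cluster '%s' not among named clusters; using largest cluster '%s'",
                    config$reference_cluster, reference), call. = FALSE)
  }
  predictors <- NULL
  if (length(unique(named_labels)) >= 2) {
    predictors <- stage("predictors",
      analyze_predictors(
        cohort$covariate_table[match(keep_ids, cohort$covariate_table$participant), ],
        named_labels,
        reference_cluster = reference,
        m = config$m_imputations, iterations = config$mice_iterations,
        seed = derive_seed(config$seed, 41)))
  } else {
    note("predictors", "skipped", reason = "fewer than 2 clusters")
  }

  if (!is.null(out_dir)) {
    utils::write.csv(shares, file.path(out_dir, "cluster_shares.csv"),
                     row.names = FALSE)
    utils::write.csv(trajectories, file.path(out_dir, "mean_trajectories.csv"),
                     row.names = FALSE)
    if (!is.null(predictors))
      utils::write.csv(predictors$pooled, file.path(out_dir, "odds_ratios.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(selected_k = k_use, recovery_ari = recovery_ari,
           r2_nagelkerke = if (is.null(predictors)) NULL else predictors$r2_nagelkerke,
           vif = if (is.null(predictors)) NULL else predictors$vif,
           seed = config$seed),
      file.path(out_dir, "model_fit.json"), auto_unbox = TRUE, digits = NA)
  }
  note("report", "done")

  list(cohort = cohort, imputation_report = if (is.null(imp)) NULL else imp$report,
       tensor = tensor, ps_curve = ps_curve, selected_k = k_use,
       model = model, assignment = assignment, cluster_names = cl_names,
       shares = shares, trajectories = trajectories,
       predictors = predictors, recovery_ari = recovery_ari,
       config = config)
}
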