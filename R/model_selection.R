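#' Subset a trajectory tensor by participant rows
#'
#' @param tensor a `trajectory_tensor`.
#' @param rows integer or logical row index.
#' @return the subsetted `trajectory_tensor`.
#' @export
tensor_subset <- function(tensor, rows) {
  out <- tensor
  out$values <- tensor$values[rows, , , drop = FALSE]
  out$mask <- tensor$mask[rows, , , drop = FALSE]
  out$participant_ids <- tensor$participant_ids[rows]
  out
}

#' Prediction strength of a labeling pair
#'
#' For each test cluster j (defined by `own` labels, clusters with at
#' least 2 members), the fraction of ordered within-cluster pairs
#' (i != i') that the `cross` labeling co-assigns; the prediction
#' strength is the minimum over test clusters.
#'
#' @param own cluster labels defining the test clusters.
#' @param cross labels from the model trained on the other half.
#' @return prediction strength in \[0, 1\] (`NA` if every test cluster
#'   is a singleton).
#' @export
ps_from_labels <- function(own, cross) {
  stopifnot(length(own) == length(cross))
  vals <- c()
  for (j in unique(own)) {
    members <- cross[own == j]
    nj <- length(members)
    if (nj < 2) next
    co <- sum(tabulate(factor(members)) * (tabulate(factor(members)) - 1))
    vals <- c(vals, co / (nj * (nj - 1)))
  }
  if (!length(vals)) return(NA_real_)
  min(vals)
}

scaled_config <- function(config, K, epoch_scale, seed) {
  vader_config(K = K, L = config$L, hidden_size = config$hidden_size,
               epochs = max(1L, as.integer(round(config$epochs * epoch_scale))),
               pretrain_epochs = max(1L, as.integer(round(config$pretrain_epochs * epoch_scale))),
               batch_size = config$batch_size,
               learning_rate = config$learning_rate,
               variance_floor = config$variance_floor,
               grad_clip = config$grad_clip,
               weight_decay = config$weight_decay %||% 0, seed = seed)
}

#' Prediction strength of K clusters under repeated 2-fold cross-validation
#'
#' Per repeat, participants are randomly halved; a model is trained on
#' each half; for each test half, its own model defines the test
#' clusters and the model trained on the other half is asked to
#' co-assign their within-cluster pairs ([ps_from_labels()]). The two
#' directions are averaged per repeat. K = 1 co-assigns every pair, so
#' its strength is 1 by definition and no training is run. Inner
#' training epochs are scaled down by `epoch_scale` (default 1/2) to
#' keep the selection loop affordable; final clustering is always run
#' at full epochs.
#'
#' @param data a `trajectory_tensor` with at least 4 participants.
#' @param K candidate number of clusters.
#' @param repeats number of repeated halvings (default 20).
#' @param config a [vader_config()] template (its K is overridden).
#' @param epoch_scale multiplier on epochs for inner trainings.
#' @param seed master seed; each repeat derives its own sub-seed.
#' @return list with `K`, `mean_ps`, `sd_ps` and `values` (per repeat).
#' @export
prediction_strength <- function(data, K, repeats = 20, config,
                                epoch_scale = 0.5, seed = 1L) {
  n <- dim(data$values)[1]
  if (n < 4) stop_field("data", "needs at least 4 participants")
  if (K < 1) stop_field("K", "must be >= 1")
  if (K == 1)
    return(list(K = 1L, mean_ps = 1, sd_ps = 0, values = rep(1, repeats)))
  if (floor(n / 2) < K)
    stop_field("K", "a half-sample has fewer participants than clusters")
  vals <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 100 + r))
    perm <- sample.int(n)
    half_a <- perm[seq_len(floor(n / 2))]
    half_b <- perm[(floor(n / 2) + 1):n]
    da <- tensor_subset(data, half_a)
    db <- tensor_subset(data, half_b)
    ma <- fit_vader(da, scaled_config(config, K, epoch_scale,
                                      derive_seed(seed, 1000 + 2 * r)))
    mb <- fit_vader(db, scaled_config(config, K, epoch_scale,
                                      derive_seed(seed, 1000 + 2 * r + 1)))
    ps_b <- ps_from_labels(assign_clusters(mb, db)$labels,
                           assign_clusters(ma, db)$labels)
    ps_a <- ps_from_labels(assign_clusters(ma, da)$labels,
                           assign_clusters(mb, da)$labels)
    vals[r] <- mean(c(ps_a, ps_b), na.rm = TRUE)
  }
  list(K = as.integer(K), mean_ps = mean(vals), sd_ps = stats::sd(vals),
       values = vals)
}

#' Prediction-strength curve over a range of K
#'
#' @param data a `trajectory_tensor`.
#' @param k_max largest K to evaluate (curve covers 1..k_max).
#' @param repeats,config,epoch_scale,seed see [prediction_strength()].
#' @return an object of class `ps_curve`: data.frame (K, mean_ps,
#'   sd_ps) with per-repeat values in `attr(, "values")`.
#' @export
prediction_strength_curve <- function(data, k_max, repeats = 20, config,
                                      epoch_scale = 0.5, seed = 1L) {
  entries <- lapply(seq_len(k_max), function(k)
    prediction_strength(data, k, repeats = repeats, config = config,
                        epoch_scale = epoch_scale, seed = derive_seed(seed, k)))
  curve <- data.frame(K = vapply(entries, `[[`, integer(1), "K"),
                      mean_ps = vapply(entries, `[[`, numeric(1), "mean_ps"),
                      sd_ps = vapply(entries, `[[`, numeric(1), "sd_ps"))
  attr(curve, "values") <- lapply(entries, `[[`, "values")
  class(curve) <- c("ps_curve", "data.frame")
  curve
}

#' Choose the number of clusters from a prediction-strength curve
#'
#' Selects the largest K whose mean prediction strength reaches the
#' threshold (default 0.8, the conventional cutoff); K = 1 if none
#' does. The full curve should always be inspected alongside, since
#' reproducibility alone does not settle interpretability.
#'
#' @param curve a `ps_curve` (or data.frame with columns K, mean_ps).
#' @param threshold minimum mean prediction strength (default 0.8).
#' @return the selected K (integer).
#' @export
choose_k <- function(curve, threshold = 0.8) {
  if (!nrow(curve)) stop_field("curve", "is empty")
  ok <- curve$K[curve$mean_ps >= threshold]
  if (!length(ok)) return(1L)
  as.integer(max(ok))
}

#' Hyperparameter grid search by cross-validated reconstruction loss
#'
#' Each candidate configuration is trained with K = 1 and the loss set
#' to reconstruction only, on each training fold of a repeated k-fold
#' split, and scored by the validation reconstruction loss averaged
#' over folds x repeats. Configurations that, refit at `target_K` on
#' the full data, produce fewer than `target_K` non-empty clusters are
#' excluded; among the survivors the minimal-loss configuration is
#' selected.
#'
#' @param data a `trajectory_tensor`.
#' @param grid list of [vader_config()] candidates.
#' @param folds number of folds (default 10).
#' @param repeats number of repeats of the k-fold split (default 20).
#' @param target_K the pre-specified number of clusters used for the
#'   exclusion refit.
#' @param epoch_scale epoch multiplier for inner trainings.
#' @param seed master seed.
#' @return an object of class `grid_search_result`: list with `table`
#'   (per-configuration mean/SD validation loss, exclusion flag and
#'   reason) and `selected` (index into `grid`).
#' @export
grid_search <- function(data, grid, folds = 10, repeats = 20, target_K,
                        epoch_scale = 0.25, seed = 1L) {
  if (!length(grid)) stop_field("grid", "is empty")
  if (folds < 2) stop_field("folds", "must be >= 2")
  n <- dim(data$values)[1]
  rows <- lapply(seq_along(grid), function(gi) {
    cfg <- grid[[gi]]
    losses <- c()
    for (r in seq_len(repeats)) {
      set.seed(derive_seed(seed, 10000 + r))  # folds shared across configs
      fold_id <- sample(rep_len(seq_len(folds), n))
      for (f in seq_len(folds)) {
        tr <- tensor_subset(data, fold_id != f)
        va <- tensor_subset(data, fold_id == f)
        cfg1 <- scaled_config(cfg, 1L, epoch_scale,
                              derive_seed(seed, 100000 + r * 100 + f))
        cfg1$pretrain_epochs <- cfg1$epochs  # recon-only training budget
        m <- pretrain(tr, cfg1)
        nv <- dim(va$values)[1]
        val <- loss_terms(m, va, eps = matrix(0, nv, cfg1$L))
        losses <- c(losses, val[["reconstruction_loss"]])
      }
    }
    refit <- fit_vader(data, scaled_config(cfg, target_K, epoch_scale,
                                           derive_seed(seed, 7)))
    n_nonempty <- length(unique(assign_clusters(refit, data)$labels))
    data.frame(config = gi, mean_loss = mean(losses), sd_loss = stats::sd(losses),
               nonempty_at_target_K = n_nonempty,
               excluded = n_nonempty < target_K,
               reason = if (n_nonempty < target_K)
                 sprintf("collapsed to %d < %d clusters at target K",
                         n_nonempty, target_K) else "",
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  ok <- which(!table$excluded)
  if (!length(ok)) {
    stop(paste0("all configurations excluded:\n",
                paste(sprintf("  config %d: %s", table$config, table$reason),
                      collapse = "\n")), call. = FALSE)
  }
  selected <- ok[which.min(table$mean_loss[ok])]
  structure(list(table = table, selected = selected,
                 selected_config = grid[[selected]]),
            class = "grid_search_result")
}
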