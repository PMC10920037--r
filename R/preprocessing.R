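#' Score one scale from its items
#'
#' A scale score is the plain sum of its items, kept fractional when
#' items were imputed (scores are never rounded). If any item is still
#' blank the score is missing.
#'
#' @param item_values numeric vector of length `spec$n_items`; blanks as
#'   `NA`. Observed values must lie within the item bounds.
#' @param spec an [assessment_spec()].
#' @return the summed score, or `NA` if any item is blank.
#' @export
score_scale <- function(item_values, spec) {
  if (length(item_values) != spec$n_items)
    stop_field("item_values", sprintf("expected %d items", spec$n_items))
  obs <- item_values[!is.na(item_values)]
  if (any(obs < spec$item_min | obs > spec$item_max))
    stop_field("item_values", sprintf("observed item outside [%d, %d] for %s",
                                      spec$item_min, spec$item_max, spec$name))
  if (anyNA(item_values)) return(NA_real_)
  sum(item_values)
}

#' Score all scales in a long item table
#'
#' @param item_table long item records (participant, wave, assessment,
#'   item, value).
#' @param assessments assessment catalog for bounds checking.
#' @return scale_table data.frame (participant, wave, assessment, score),
#'   score `NA` where any item is blank.
#' @export
score_cohort <- function(item_table, assessments) {
  for (a_name in unique(item_table$assessment)) {
    a <- assessments[[a_name]]
    v <- item_table$value[item_table$assessment == a_name]
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < a$item_min || max(v) > a$item_max))
      stop_field("item_table", sprintf("item outside bounds for %s", a_name))
  }
  key <- paste(item_table$participant, item_table$wave, item_table$assessment,
               sep = "\r")
  sums <- tapply(item_table$value, key,
                 function(v) if (anyNA(v)) NA_real_ else sum(v))
  parts <- strsplit(names(sums), "\r", fixed = TRUE)
  out <- data.frame(
    participant = as.integer(vapply(parts, `[[`, character(1), 1)),
    wave = vapply(parts, `[[`, character(1), 2),
    assessment = vapply(parts, `[[`, character(1), 3),
    score = as.numeric(sums),
    stringsAsFactors = FALSE
  )
  out[order(out$participant, out$wave, out$assessment), , drop = FALSE]
}

#' Iterative random-forest imputation of an item block
#'
#' Implements the missForest scheme on one records x items matrix:
#' blanks are initialized at column means, columns are visited in order
#' of increasing missingness, and each iteration refits a random forest
#' (`n_trees` trees) per incomplete column on the currently completed
#' data and re-predicts that column's blanks. Iteration stops the first
#' time the normalized squared change over previously-blank cells,
#' `sum((new - old)^2) / sum(new^2)`, increases — the iterate before the
#' increase is returned — or at `max_iter`. Rows with no observed item
#' are excluded (no responses, no imputation) and returned blank;
#' observed cells are never altered; imputed values stay fractional.
#'
#' @param item_block numeric matrix, records x items, blanks as `NA`.
#' @param n_trees trees per forest (default 100).
#' @param max_iter maximum missForest iterations (default 10).
#' @param seed integer seed for forest growing.
#' @param bounds optional `c(min, max)`; predictions are clipped into
#'   this range (item bounds) when given.
#' @return the completed matrix with attribute `iterations_used`.
#' @export
missforest_impute <- function(item_block, n_trees = 100, max_iter = 10,
                              seed = 1L, bounds = NULL) {
  X <- as.matrix(item_block)
  storage.mode(X) <- "double"
  if (all(is.na(X)))
    stop("no responses were provided: cannot impute a fully blank block",
         call. = FALSE)
  miss <- is.na(X)
  if (!any(miss)) {
    attr(X, "iterations_used") <- 0L
    return(X)
  }
  all_blank_row <- rowSums(!miss) == 0
  usable <- which(!all_blank_row)

  col_miss <- colSums(miss[usable, , drop = FALSE])
  incomplete <- order(col_miss)[col_miss[order(col_miss)] > 0]
  incomplete <- incomplete[colSums(!miss[usable, incomplete, drop = FALSE]) > 0]

  # mean initialization over observed cells
  Xc <- X
  for (j in seq_len(ncol(X))) {
    mu <- mean(X[!miss[, j], j])
    if (is.nan(mu)) next  # fully blank column: left NA
    Xc[usable, j][miss[usable, j]] <- mu
  }

  if (ncol(X) < 2 || length(incomplete) == 0) {
    out <- Xc
    out[all_blank_row, ] <- NA_real_
    attr(out, "iterations_used") <- 0L
    return(out)
  }

  set.seed(seed)
  prev <- Xc
  prev_delta <- Inf
  iterations_used <- 0L
  for (iter in seq_len(max_iter)) {
    Xn <- prev
    for (j in incomplete) {
      obs_j <- usable[!miss[usable, j]]
      mis_j <- usable[miss[usable, j]]
      if (!length(mis_j)) next
      fit <- ranger::ranger(
        y = Xn[obs_j, j],
        x = as.data.frame(Xn[obs_j, -j, drop = FALSE]),
        num.trees = n_trees, num.threads = 1,
        seed = derive_seed(seed, iter * 1000 + j)
      )
      pred <- stats::predict(fit,
        data = as.data.frame(Xn[mis_j, -j, drop = FALSE]),
        num.threads = 1)$predictions
      if (!is.null(bounds)) pred <- pmin(pmax(pred, bounds[1]), bounds[2])
      Xn[mis_j, j] <- pred
    }
    cells <- miss & !is.na(Xn)
    delta <- sum((Xn[cells] - prev[cells])^2) / sum(Xn[cells]^2)
    if (!is.finite(delta)) delta <- 0
    if (delta >= prev_delta) break  # criterion rose: keep previous iterate
    prev <- Xn
    prev_delta <- delta
    iterations_used <- iter
  }
  out <- prev
  out[all_blank_row, ] <- NA_real_
  out[!miss] <- X[!miss]  # observed cells are inviolate
  attr(out, "iterations_used") <- iterations_used
  out
}

#' Impute partially missing items across a cohort
#'
#' Applies [missforest_impute()] separately to each (assessment, wave)
#' block, predicting each item from the other items of the same
#' instrument at the same wave. Scales with no responses at all for a
#' participant are left blank, and single-item assessments cannot be
#' item-imputed, so some missingness remains by design.
#'
#' @param item_table long item records with blanks.
#' @param assessments assessment catalog.
#' @param n_trees,max_iter,seed forwarded to [missforest_impute()].
#' @return list with `item_table` (completed, fractional values) and
#'   `report`, an `imputation_report` with fields
#'   `fraction_missing_before`, `fraction_missing_after`,
#'   `iterations_used` (total) and `per_assessment` counts.
#' @export
impute_cohort_items <- function(item_table, assessments, n_trees = 100,
                                max_iter = 10, seed = 1L) {
  it <- item_table
  it$value <- as.numeric(it$value)
  before <- mean(is.na(it$value))
  iter_total <- 0L
  per_assessment <- list()
  block_id <- 0L
  for (a_name in unique(it$assessment)) {
    a <- assessments[[a_name]]
    for (w in unique(it$wave[it$assessment == a_name])) {
      block_id <- block_id + 1L
      sel <- it$assessment == a_name & it$wave == w
      blk <- it[sel, , drop = FALSE]
      n_miss <- sum(is.na(blk$value))
      per_assessment[[paste(a_name, w)]] <- n_miss
      if (n_miss == 0 || a$n_items < 2) next
      wide <- matrix(NA_real_, nrow = length(unique(blk$participant)),
                     ncol = a$n_items)
      pid <- sort(unique(blk$participant))
      wide[cbind(match(blk$participant, pid), blk$item)] <- blk$value
      done <- missforest_impute(wide, n_trees = n_trees, max_iter = max_iter,
                                seed = derive_seed(seed, block_id),
                                bounds = c(a$item_min, a$item_max))
      iter_total <- iter_total + attr(done, "iterations_used")
      it$value[sel] <- done[cbind(match(blk$participant, pid), blk$item)]
    }
  }
  after <- mean(is.na(it$value))
  report <- structure(list(
    fraction_missing_before = before,
    fraction_missing_after = after,
    iterations_used = iter_total,
    per_assessment = unlist(per_assessment)
  ), class = "imputation_report")
  list(item_table = it, report = report)
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf("<imputation_report> missing %.1f%% -> %.1f%% (%d forest iterations)\n",
              100 * x$fraction_missing_before, 100 * x$fraction_missing_after,
              x$iterations_used))
  invisible(x)
}

#' Pool-standardize scale scores into a masked trajectory tensor
#'
#' For each assessment, z = (score - pooled mean) / pooled SD, pooling
#' observations across all waves and participants (sample SD, n-1
#' denominator). Higher z means more severe problems. The result is a
#' participant x wave x assessment array with an observed-entry mask;
#' structural absences and residual missingness stay masked. A binary
#' assessment can be passed through raw (0/1, unstandardized) via
#' `raw_assessments`, the sensitivity variant for self-harm.
#'
#' @param scale_table data.frame (participant, wave, assessment, score).
#' @param waves wave labels in temporal order.
#' @param raw_assessments character vector of assessments to leave on
#'   their raw scale.
#' @return an object of class `trajectory_tensor`: list with `values`
#'   (n x T x D array, `NA` where masked), `mask` (0/1 array),
#'   `participant_ids`, `wave_labels`, `assessment_names`.
#' @export
standardize <- function(scale_table, waves = c("T1", "T2", "T3", "T4"),
                        raw_assessments = character(0)) {
  pid <- sort(unique(scale_table$participant))
  a_names <- unique(scale_table$assessment)
  n <- length(pid); tt <- length(waves); d <- length(a_names)
  values <- array(NA_real_, dim = c(n, tt, d),
                  dimnames = list(NULL, waves, a_names))
  idx <- cbind(match(scale_table$participant, pid),
               match(scale_table$wave, waves),
               match(scale_table$assessment, a_names))
  values[idx] <- scale_table$score
  for (j in seq_len(d)) {
    x <- values[, , j]
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < 2)
      stop(sprintf("assessment '%s' has fewer than 2 distinct observed values",
                   a_names[j]), call. = FALSE)
    if (!(a_names[j] %in% raw_assessments)) {
      s <- stats::sd(obs)
      if (s == 0)
        stop(sprintf("assessment '%s' has zero variance", a_names[j]),
             call. = FALSE)
      values[, , j] <- (x - mean(obs)) / s
    }
  }
  structure(list(
    values = values,
    mask = array(as.numeric(!is.na(values)), dim = dim(values),
                 dimnames = dimnames(values)),
    participant_ids = pid,
    wave_labels = waves,
    assessment_names = a_names
  ), class = "trajectory_tensor")
}

#' @export
print.trajectory_tensor <- function(x, ...) {
  cat(sprintf("<trajectory_tensor> %d participants x %d waves x %d assessments, %.1f%% observed\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              100 * mean(x$mask)))
  invisible(x)
}

#' Follow-up rates from per-wave participation counts
#'
#' @param per_wave_counts named integer vector of participating pairs per
#'   wave; the first entry is the baseline.
#' @return data.frame (wave, n, followup_pct), percentage = 100 * n /
#'   n_baseline rounded half-up to one decimal.
#' @export
attrition_report <- function(per_wave_counts) {
  if (length(per_wave_counts) < 1 || per_wave_counts[1] <= 0)
    stop_field("per_wave_counts", "baseline count must be positive")
  data.frame(
    wave = names(per_wave_counts),
    n = as.integer(per_wave_counts),
    followup_pct = round_half_up(100 * per_wave_counts / per_wave_counts[1], 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
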