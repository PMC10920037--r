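#' Round half-up to a number of decimals
#'
#' Base R's `round()` rounds half-to-even; printed cohort bookkeeping
#' (follow-up rates, cluster shares) uses conventional half-up rounding,
#' so a 60.45 becomes 60.5, not 60.4.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline takes its own seed derived from
#' one master seed plus a stream index, so stages can be re-run in
#' isolation and the whole pipeline is reproducible end to end. Results
#' stay inside the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param stream integer stream index (>= 0).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stream = 0) {
  as.integer((as.numeric(master) * 48271 + as.numeric(stream) * 7919 + 12345) %%
               2147483647L)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the pair-counting contingency table. Used to score
#' recovery of known trajectory classes on synthetic cohorts.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return ARI in \[-1, 1\]; 1 means identical partitions up to renaming.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n_pairs <- choose2(length(a))
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    # degenerate: no chance variation (all singletons / one cluster);
    # 1 if the partitions coincide up to relabeling, else 0
    same <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
    return(as.numeric(same))
  }
  (sum_ij - expected) / (max_index - expected)
}

# stop() with the offending field named, for config validation errors
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
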