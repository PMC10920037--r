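# Diagonal-covariance Gaussian mixture fitted by EM with k-means++
# seeding, used to initialize the latent-space mixture prior from the
# pretrained encoder means. Variances are floored so degenerate latent
# configurations (e.g. identical points) cannot produce singular
# components.

kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (K > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (k in 2:K) {
      if (sum(d2) <= 0) {
        pick <- sample.int(n, 1)  # all points coincide with a center
      } else {
        pick <- sample.int(n, 1, prob = d2)
      }
      centers[k, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
    }
  }
  centers
}

gmm_log_density <- function(X, mu, sigma2) {
  # X: n x L; mu, sigma2: K x L. Returns n x K log component densities.
  K <- nrow(mu)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    d2 <- sweep(X, 2, mu[k, ])^2
    out[, k] <- -0.5 * (ncol(X) * log(2 * pi) + sum(log(sigma2[k, ])) +
                          rowSums(sweep(d2, 2, sigma2[k, ], "/")))
  }
  out
}

gmm_responsibilities <- function(X, pi_k, mu, sigma2) {
  lg <- sweep(gmm_log_density(X, mu, sigma2), 2, log(pi_k), "+")
  m <- apply(lg, 1, max)
  g <- exp(lg - m)
  list(gamma = g / rowSums(g), loglik = sum(m + log(rowSums(g))))
}

gmm_fit_once <- function(X, K, floor, max_iter = 100, tol = 1e-8) {
  n <- nrow(X); L <- ncol(X)
  mu <- kmeanspp_centers(X, K)
  d2 <- vapply(seq_len(K), function(k) rowSums(sweep(X, 2, mu[k, ])^2),
               numeric(n))
  lab <- max.col(-matrix(d2, n, K), ties.method = "first")
  pi_k <- pmax(tabulate(lab, K), 0.5) / n
  pi_k <- pi_k / sum(pi_k)
  sigma2 <- matrix(0, K, L)
  gvar <- pmax(apply(X, 2, stats::var), floor)
  if (any(is.na(gvar))) gvar <- rep(floor, L)
  for (k in seq_len(K)) {
    xk <- X[lab == k, , drop = FALSE]
    v <- if (nrow(xk) > 1) apply(xk, 2, stats::var) else gvar
    sigma2[k, ] <- pmax(v, floor)
  }
  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    resp <- gmm_responsibilities(X, pi_k, mu, sigma2)
    gamma <- resp$gamma
    nk <- colSums(gamma)
    pi_k <- pmax(nk, 1e-10) / sum(pmax(nk, 1e-10))
    for (k in seq_len(K)) {
      if (nk[k] < 1e-8) next  # empty component: keep parameters
      mu[k, ] <- colSums(gamma[, k] * X) / nk[k]
      sigma2[k, ] <- pmax(colSums(gamma[, k] * sweep(X, 2, mu[k, ])^2) / nk[k],
                          floor)
    }
    if (abs(resp$loglik - loglik) < tol * (abs(loglik) + 1)) {
      loglik <- resp$loglik
      break
    }
    loglik <- resp$loglik
  }
  list(pi = pi_k, mu = mu, sigma2 = sigma2, loglik = loglik)
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' k-means++ seeding, best of `n_restarts` restarts by log-likelihood,
#' variances floored at `floor`. Used to initialize the latent mixture
#' prior; exported because it is also a convenient reference clusterer
#' on encoded data.
#'
#' @param X n x L numeric matrix.
#' @param K number of components (1 <= K <= n).
#' @param n_restarts EM restarts (default 10).
#' @param floor variance floor (> 0).
#' @param seed integer seed.
#' @return list with `pi` (length K), `mu` (K x L), `sigma2` (K x L),
#'   `loglik`.
#' @export
gmm_fit <- function(X, K, n_restarts = 10, floor = 1e-4, seed = 1L) {
  X <- as.matrix(X)
  if (K < 1) stop_field("K", "must be >= 1")
  if (K > nrow(X)) stop_field("K", "exceeds number of observations")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- gmm_fit_once(X, K, floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}
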