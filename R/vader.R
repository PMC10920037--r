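#' Configure the recurrent variational deep embedding model
#'
#' The model is a single-layer unidirectional LSTM autoencoder whose
#' L-dimensional latent space carries a K-component diagonal Gaussian
#' mixture prior, trained with a masked Gaussian reconstruction loss
#' (observed cells only) plus the mixture-prior latent loss. Missing
#' inputs are replaced by learned imputation values (one scalar per
#' wave x assessment cell, initialized at observed means) so incomplete
#' trajectories are handled inside the model.
#'
#' @param K number of mixture components (clusters), >= 1.
#' @param L latent dimension (default 8).
#' @param hidden_size LSTM state width (default 32).
#' @param epochs joint-training epochs (default 100).
#' @param pretrain_epochs reconstruction-only pretraining epochs
#'   (default 50).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param variance_floor lower bound for all mixture variances (> 0).
#' @param grad_clip global gradient-norm clip (default 5).
#' @param weight_decay decoupled (AdamW-style) weight decay on network
#'   weights (default 0.01); imputation values and mixture parameters
#'   never decay. Regularizes the encoder so half-sample refits during
#'   model selection stay reproducible.
#' @param seed integer seed controlling initialization, shuffling and
#'   reparameterization noise.
#' @return an object of class `vader_config`.
#' @export
vader_config <- function(K, L = 8, hidden_size = 32, epochs = 100,
                         pretrain_epochs = 50, batch_size = 16,
                         learning_rate = 1e-3, variance_floor = 1e-4,
                         grad_clip = 5, weight_decay = 0.01, seed = 1L) {
  if (K < 1) stop_field("K", "must be >= 1")
  if (L < 1) stop_field("L", "must be >= 1")
  if (epochs < 0) stop_field("epochs", "must be >= 0")
  if (pretrain_epochs < 0) stop_field("pretrain_epochs", "must be >= 0")
  if (variance_floor <= 0) stop_field("variance_floor", "must be > 0")
  structure(list(K = as.integer(K), L = as.integer(L),
                 hidden_size = as.integer(hidden_size),
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 variance_floor = variance_floor,
                 grad_clip = grad_clip, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "vader_config")
}

#' Initialize a VaDER model for a data tensor
#'
#' Weights get seeded Glorot initialization; imputation values `B` start
#' at the per-(wave, assessment) observed means (implicit mean
#' imputation); mixture parameters start at a single broad configuration
#' and are only meaningful after [init_mixture()].
#'
#' @param config a [vader_config()].
#' @param data a `trajectory_tensor`.
#' @return an object of class `vader_model`.
#' @export
vader_init <- function(config, data) {
  stopifnot(inherits(config, "vader_config"),
            inherits(data, "trajectory_tensor"))
  dm <- dim(data$values)
  TT <- dm[2]; D <- dm[3]
  H <- config$hidden_size; L <- config$L; K <- config$K
  set.seed(derive_seed(config$seed, 0))
  enc <- lstm_init(D, H)
  dec <- lstm_init(L, H)
  B <- matrix(0, TT, D)
  for (t in seq_len(TT)) for (d in seq_len(D)) {
    v <- data$values[, t, d]
    m <- data$mask[, t, d]
    if (sum(m) > 0) B[t, d] <- mean(v[m == 1])
  }
  par <- list(
    enc.Wx = enc$Wx, enc.Wh = enc$Wh, enc.b = enc$b,
    mu.W = glorot_init(H, L), mu.b = rep(0, L),
    lv.W = glorot_init(H, L), lv.b = rep(-1, L),
    lift.W = glorot_init(L, H), lift.b = rep(0, H),
    dec.Wx = dec$Wx, dec.Wh = dec$Wh, dec.b = dec$b,
    out.W = glorot_init(H, D), out.b = rep(0, D),
    B = B,
    rho = rep(0, K),
    mu_c = matrix(stats::rnorm(K * L, 0, 0.1), K, L),
    phi_c = matrix(0, K, L)
  )
  structure(list(par = par, config = config,
                 axes = list(waves = data$wave_labels,
                             assessments = data$assessment_names),
                 log = NULL, pretrained = FALSE, mixture_ready = FALSE),
            class = "vader_model")
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

mixture_sigma2 <- function(par, floor) floor + exp(par$phi_c)

# Full forward + backward pass on one batch.
# x, mask: n x T x D (x already zero-filled where masked); eps: n x L.
# mode "recon" skips the latent loss (and mixture gradients).
vader_pass <- function(par, x, mask, eps, config, mode = "full",
                       want_grads = TRUE) {
  n <- dim(x)[1]; TT <- dim(x)[2]; D <- dim(x)[3]
  L <- config$L; K <- config$K
  if (sum(mask) == 0) stop("batch has no observed cells", call. = FALSE)

  # implicit mean imputation: learned B fills unobserved positions
  xt <- x
  for (t in seq_len(TT))
    xt[, t, ] <- matrix(x[, t, ], n, D) * matrix(mask[, t, ], n, D) +
      (1 - matrix(mask[, t, ], n, D)) * matrix(par$B[t, ], n, D, byrow = TRUE)

  enc <- lstm_forward(xt, par$enc.Wx, par$enc.Wh, par$enc.b)
  hT <- enc$h_last
  mu_t <- hT %*% par$mu.W + matrix(par$mu.b, n, L, byrow = TRUE)
  lv_raw <- hT %*% par$lv.W + matrix(par$lv.b, n, L, byrow = TRUE)
  lv <- pmin(pmax(lv_raw, -6), 6)
  z <- mu_t + exp(0.5 * lv) * eps

  h0 <- z %*% par$lift.W + matrix(par$lift.b, n, config$hidden_size, byrow = TRUE)
  Xdec <- array(0, dim = c(n, TT, L))
  for (t in seq_len(TT)) Xdec[, t, ] <- z
  dec <- lstm_forward(Xdec, par$dec.Wx, par$dec.Wh, par$dec.b, h0 = h0)
  xhat <- array(0, dim = c(n, TT, D))
  for (t in seq_len(TT))
    xhat[, t, ] <- matrix(dec$H[, t, ], n, config$hidden_size) %*% par$out.W +
      matrix(par$out.b, n, D, byrow = TRUE)

  m_sum <- sum(mask)
  resid <- (x - xhat) * mask
  loss_recon <- sum(resid^2) / m_sum

  loss_latent <- 0
  gamma <- NULL
  sigma2 <- mixture_sigma2(par, config$variance_floor)
  pi_k <- softmax_vec(par$rho)
  KLm <- NULL
  if (mode == "full") {
    lg <- sweep(gmm_log_density(z, par$mu_c, sigma2), 2, log(pi_k), "+")
    mx <- apply(lg, 1, max)
    g <- exp(lg - mx)
    gamma <- g / rowSums(g)
    KLm <- matrix(0, n, K)
    ev <- exp(lv)
    for (k in seq_len(K)) {
      KLm[, k] <- 0.5 * (sum(log(sigma2[k, ])) - rowSums(lv) +
                           rowSums(sweep(ev, 2, sigma2[k, ], "/")) +
                           rowSums(sweep(sweep(mu_t, 2, par$mu_c[k, ])^2,
                                         2, sigma2[k, ], "/")) - L)
    }
    gsafe <- pmax(gamma, 1e-12)
    loss_latent <- mean(rowSums(gamma * KLm) +
                          rowSums(gamma * sweep(log(gsafe), 2, log(pi_k), "-")))
  }

  loss_elbo <- sum(resid^2) / n + loss_latent
  if (!want_grads)
    return(list(loss_recon = loss_recon, loss_latent = loss_latent,
                loss_elbo = loss_elbo, gamma = gamma, mu = mu_t, lv = lv,
                z = z))

  ## ----- backward -----
  # The optimized objective is the negative ELBO under a unit-variance
  # Gaussian observation model: squared error summed over observed
  # cells (not averaged), plus the latent term, both averaged over the
  # batch. The reported reconstruction loss stays the masked mean.
  H <- config$hidden_size
  dxhat <- -2 * resid / n  # d(ELBO recon term) / d xhat
  dH_dec <- array(0, dim = c(n, TT, H))
  d_outW <- matrix(0, H, D); d_outb <- rep(0, D)
  for (t in seq_len(TT)) {
    dxt <- matrix(dxhat[, t, ], n, D)
    ht <- matrix(dec$H[, t, ], n, H)
    d_outW <- d_outW + crossprod(ht, dxt)
    d_outb <- d_outb + colSums(dxt)
    dH_dec[, t, ] <- dxt %*% t(par$out.W)
  }
  bdec <- lstm_backward(dec, par$dec.Wx, par$dec.Wh, dH_dec)
  dz <- matrix(0, n, L)
  for (t in seq_len(TT)) dz <- dz + matrix(bdec$dX[, t, ], n, L)
  dz <- dz + bdec$dh0 %*% t(par$lift.W)
  d_liftW <- crossprod(z, bdec$dh0)
  d_liftb <- colSums(bdec$dh0)

  dmu <- dz
  dlv <- dz * 0.5 * exp(0.5 * lv) * eps

  d_rho <- rep(0, K)
  d_muc <- matrix(0, K, L)
  d_phic <- matrix(0, K, L)
  if (mode == "full") {
    ev <- exp(lv)
    gsafe <- pmax(gamma, 1e-12)
    # direct terms, responsibilities held fixed
    S <- gamma %*% (1 / sigma2)               # n x L: sum_c gamma_ic / s2_cl
    Mw <- gamma %*% (par$mu_c / sigma2)       # n x L: sum_c gamma_ic mu_cl/s2_cl
    dmu <- dmu + (mu_t * S - Mw) / n
    dlv <- dlv + 0.5 * (ev * S - 1) / n
    d_s2 <- matrix(0, K, L)
    for (k in seq_len(K)) {
      gk <- gamma[, k]
      diff <- sweep(mu_t, 2, par$mu_c[k, ])
      d_muc[k, ] <- -colSums(gk * sweep(diff, 2, sigma2[k, ], "/")) / n
      d_s2[k, ] <- 0.5 * colSums(gk * sweep(-sweep(ev, 2, sigma2[k, ], "/") -
                                              sweep(diff^2, 2, sigma2[k, ], "/") + 1,
                                            2, sigma2[k, ], "/")) / n
    }
    d_rho <- colSums(sweep(-gamma, 2, pi_k, "+")) / n

    # indirect terms through the responsibilities gamma = softmax(lg),
    # lg_c = log pi_c + log N(z; mu_c, s2_c):
    # dL/dlg_c = gamma_c (A_c - sum_k gamma_k A_k),
    # A_c = KL_c + log gamma_c - log pi_c + 1
    A <- KLm + sweep(log(gsafe), 2, log(pi_k), "-") + 1
    dlg <- gamma * (A - rowSums(gamma * A)) / n   # n x K
    dz_lat <- matrix(0, n, L)
    for (k in seq_len(K)) {
      zdiff_s <- sweep(sweep(z, 2, par$mu_c[k, ]), 2, sigma2[k, ], "/")
      dz_lat <- dz_lat - dlg[, k] * zdiff_s
      d_muc[k, ] <- d_muc[k, ] + colSums(dlg[, k] * zdiff_s)
      d_s2[k, ] <- d_s2[k, ] +
        0.5 * colSums(dlg[, k] * (zdiff_s^2 - matrix(1 / sigma2[k, ], n, L,
                                                     byrow = TRUE)))
    }
    d_rho <- d_rho + colSums(dlg) - colSums(rowSums(dlg) %*% t(pi_k))
    d_phic <- d_s2 * exp(par$phi_c)
    dmu <- dmu + dz_lat
    dlv <- dlv + dz_lat * 0.5 * exp(0.5 * lv) * eps
  }

  dlv_raw <- dlv * (lv_raw > -6 & lv_raw < 6)
  d_muW <- crossprod(hT, dmu); d_mub <- colSums(dmu)
  d_lvW <- crossprod(hT, dlv_raw); d_lvb <- colSums(dlv_raw)
  dhT <- dmu %*% t(par$mu.W) + dlv_raw %*% t(par$lv.W)
  dH_enc <- array(0, dim = c(n, TT, H))
  dH_enc[, TT, ] <- dhT
  benc <- lstm_backward(enc, par$enc.Wx, par$enc.Wh, dH_enc)
  dB <- matrix(0, TT, D)
  for (t in seq_len(TT))
    dB[t, ] <- colSums(matrix(benc$dX[, t, ], n, D) *
                         (1 - matrix(mask[, t, ], n, D)))

  grads <- list(
    enc.Wx = benc$dWx, enc.Wh = benc$dWh, enc.b = benc$db,
    mu.W = d_muW, mu.b = d_mub, lv.W = d_lvW, lv.b = d_lvb,
    lift.W = d_liftW, lift.b = d_liftb,
    dec.Wx = bdec$dWx, dec.Wh = bdec$dWh, dec.b = bdec$db,
    out.W = d_outW, out.b = d_outb,
    B = dB, rho = d_rho, mu_c = d_muc, phi_c = d_phic
  )
  list(loss_recon = loss_recon, loss_latent = loss_latent,
       loss_elbo = loss_elbo, grads = grads, gamma = gamma)
}

tensor_x <- function(data) {
  x <- data$values
  x[is.na(x)] <- 0
  x
}

#' Reconstruction and latent loss on a data slice
#'
#' Evaluates both terms of the training objective: the masked mean
#' squared reconstruction error over observed cells (missing inputs
#' replaced by the learned imputation values), and the mixture-prior
#' latent loss `sum_c gamma_c KL(q(z|x) || N(mu_c, sigma2_c)) +
#' sum_c gamma_c log(gamma_c / pi_c)` with responsibilities computed at
#' the reparameterized sample `z = mu + sigma * eps`.
#'
#' @param model a `vader_model`.
#' @param data a `trajectory_tensor` (or compatible slice).
#' @param eps optional n x L noise matrix; defaults to a standard-normal
#'   draw. Pass zeros to evaluate at the posterior mean.
#' @return named numeric vector `c(reconstruction_loss, latent_loss)`.
#' @export
loss_terms <- function(model, data, eps = NULL) {
  x <- tensor_x(data)
  n <- dim(x)[1]
  if (sum(data$mask) == 0) stop("all cells are masked", call. = FALSE)
  if (is.null(eps)) eps <- matrix(stats::rnorm(n * model$config$L), n)
  out <- vader_pass(model$par, x, data$mask, eps, model$config,
                    mode = "full", want_grads = FALSE)
  c(reconstruction_loss = out$loss_recon, latent_loss = out$loss_latent)
}

train_loop <- function(model, data, epochs, mode, seed_stream) {
  cfg <- model$config
  x <- tensor_x(data)
  mask <- data$mask
  n <- dim(x)[1]
  trainable <- names(model$par)
  if (mode == "recon")
    trainable <- setdiff(trainable, c("rho", "mu_c", "phi_c"))
  state <- adam_init(model$par[trainable])
  log_rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(cfg$seed, seed_stream + ep))
    idx <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    rec_sum <- lat_sum <- w_sum <- 0
    for (s in starts) {
      b <- idx[s:min(s + cfg$batch_size - 1, n)]
      nb <- length(b)
      eps <- if (mode == "recon") matrix(0, nb, cfg$L) else
        matrix(stats::rnorm(nb * cfg$L), nb)
      out <- vader_pass(model$par,
                        x[b, , , drop = FALSE], mask[b, , , drop = FALSE],
                        eps, cfg, mode = mode)
      if (!is.finite(out$loss_recon + out$loss_latent))
        stop(sprintf("non-finite loss at epoch %d", ep), call. = FALSE)
      upd <- adam_step(model$par[trainable], out$grads[trainable], state,
                       lr = cfg$learning_rate, clip = cfg$grad_clip,
                       weight_decay = cfg$weight_decay %||% 0,
                       decay_skip = c("B", "rho", "mu_c", "phi_c"))
      model$par[trainable] <- upd$params
      state <- upd$state
      rec_sum <- rec_sum + nb * out$loss_recon
      lat_sum <- lat_sum + nb * out$loss_latent
      w_sum <- w_sum + nb
    }
    log_rows[[ep]] <- data.frame(phase = mode, epoch = ep,
                                 reconstruction_loss = rec_sum / w_sum,
                                 latent_loss = lat_sum / w_sum)
  }
  model$log <- rbind(model$log, do.call(rbind, log_rows))
  model
}

#' Pretrain the autoencoder on reconstruction loss only
#'
#' Trains the LSTM autoencoder and the implicit imputation values with
#' the loss set to reconstruction loss alone; mixture parameters are
#' untouched. With `pretrain_epochs = 0` the seeded initialization is
#' returned as is.
#'
#' @param data a `trajectory_tensor`.
#' @param config a [vader_config()].
#' @return a `vader_model` with `pretrained = TRUE`.
#' @export
pretrain <- function(data, config) {
  model <- vader_init(config, data)
  model <- train_loop(model, data, config$pretrain_epochs, "recon",
                      seed_stream = 10000)
  model$pretrained <- TRUE
  model
}

#' Initialize the mixture prior from the pretrained latent space
#'
#' Encodes all participants to their latent means and fits a K-component
#' diagonal-covariance Gaussian mixture by EM (k-means++ seeding, best
#' of `n_restarts` restarts by likelihood); the fitted weights, means
#' and floored variances are copied into the model as the latent prior.
#'
#' @param model a pretrained `vader_model`.
#' @param data the `trajectory_tensor` it was trained on.
#' @param K number of components (defaults to the configured K).
#' @param n_restarts EM restarts (default 30); the restart landscape is
#'   rugged enough on half-samples that 10 restarts occasionally miss
#'   the dominant optimum.
#' @return the model with mixture parameters set.
#' @export
init_mixture <- function(model, data, K = model$config$K, n_restarts = 30) {
  n <- dim(data$values)[1]
  if (K > n) stop_field("K", "exceeds number of participants")
  enc <- vader_encode(model, data)
  fit <- gmm_fit(enc$mu, K, n_restarts = n_restarts,
                 floor = model$config$variance_floor,
                 seed = derive_seed(model$config$seed, 1))
  model$par$rho <- log(pmax(fit$pi, 1e-10))
  model$par$mu_c <- fit$mu
  model$par$phi_c <- log(pmax(fit$sigma2 - model$config$variance_floor, 1e-10))
  model$mixture_ready <- TRUE
  model
}

#' Jointly train network, imputation and mixture parameters
#'
#' Minimizes reconstruction loss + latent loss by stochastic gradient
#' (Adam) for `config$epochs` epochs. Mixture weights stay on the
#' simplex through a softmax parameterization and variances stay above
#' the floor through an exponential parameterization. The per-epoch
#' training log (both loss terms) is appended to `model$log`.
#'
#' @param model a `vader_model` with the mixture initialized.
#' @param data the `trajectory_tensor`.
#' @param config optional config override (defaults to the model's).
#' @return the trained `vader_model` (training log in `$log`).
#' @export
train_full <- function(model, data, config = model$config) {
  model$config <- config
  model <- train_loop(model, data, config$epochs, "full", seed_stream = 20000)
  model
}

#' Encode participants to latent means and log-variances
#'
#' @param model a `vader_model`.
#' @param data a `trajectory_tensor`.
#' @return list with `mu` and `lv` (n x L matrices).
#' @export
vader_encode <- function(model, data) {
  x <- tensor_x(data)
  n <- dim(x)[1]
  out <- vader_pass(model$par, x, data$mask,
                    matrix(0, n, model$config$L), model$config,
                    mode = "full", want_grads = FALSE)
  list(mu = out$mu, lv = out$lv)
}

#' Assign participants to clusters
#'
#' Responsibilities are evaluated at the latent mean (no sampling), so
#' assignment is deterministic given model and data:
#' `gamma_c = pi_c N(mu; mu_c, sigma2_c) / sum_k pi_k N(mu; mu_k,
#' sigma2_k)`, with the hard label the argmax (ties to the lowest
#' index).
#'
#' @param model a trained `vader_model`.
#' @param data a `trajectory_tensor` with the model's wave and
#'   assessment axes.
#' @return an object of class `cluster_assignment`: list with `labels`
#'   (integer vector) and `responsibilities` (n x K matrix, rows sum
#'   to 1).
#' @export
assign_clusters <- function(model, data) {
  if (dim(data$values)[2] != length(model$axes$waves) ||
      dim(data$values)[3] != length(model$axes$assessments))
    stop("tensor axes do not match the model", call. = FALSE)
  enc <- vader_encode(model, data)
  sigma2 <- mixture_sigma2(model$par, model$config$variance_floor)
  pi_k <- softmax_vec(model$par$rho)
  resp <- gmm_responsibilities(enc$mu, pi_k, model$par$mu_c, sigma2)
  labels <- apply(resp$gamma, 1, which.max)
  structure(list(labels = labels, responsibilities = resp$gamma),
            class = "cluster_assignment")
}

#' Pretrain, initialize the mixture and train a VaDER model
#'
#' Convenience wrapper running the three training stages in order.
#'
#' @param data a `trajectory_tensor`.
#' @param config a [vader_config()].
#' @return a trained `vader_model`.
#' @export
fit_vader <- function(data, config) {
  model <- pretrain(data, config)
  model <- init_mixture(model, data)
  train_full(model, data)
}

#' @export
print.vader_model <- function(x, ...) {
  cat(sprintf("<vader_model> K=%d, L=%d, hidden=%d; pretrained=%s, mixture=%s, %d logged epochs\n",
              x$config$K, x$config$L, x$config$hidden_size,
              x$pretrained, x$mixture_ready,
              if (is.null(x$log)) 0L else nrow(x$log)))
  invisible(x)
}

#' Save or load a fitted VaDER model
#'
#' The archive holds every numeric array of the model (weights,
#' imputation values, mixture parameters) plus its config, axis labels
#' and training log, serialized with R's native compressed format.
#'
#' @param model a `vader_model`.
#' @param path file path (conventionally `.rds`).
#' @return `save_vader` returns `path` invisibly; `load_vader` returns
#'   the restored `vader_model`.
#' @export
save_vader <- function(model, path) {
  stopifnot(inherits(model, "vader_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_vader
#' @export
load_vader <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "vader_model"))
    stop("file does not contain a vader_model", call. = FALSE)
  model
}
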