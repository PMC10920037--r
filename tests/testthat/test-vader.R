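test_that("config invariants are enforced", {
  expect_error(vader_config(K = 0), "K")
  expect_error(vader_config(K = 2, L = 0), "L")
  expect_error(vader_config(K = 2, variance_floor = 0), "variance_floor")
  expect_error(vader_config(K = 2, epochs = -1), "epochs")
})

test_that("latent loss matches the closed-form diagonal-Gaussian KL", {
  # single component, so latent loss = KL(q || p) with gamma = 1
  tn <- toy_tensor(n = 4, tt = 2, d = 3)
  cfg <- vader_config(K = 1, L = 2, hidden_size = 6, seed = 2)
  m <- vader_init(cfg, tn)
  mu_p <- c(0.3, -0.7); s2_p <- c(0.5, 1.5)
  m$par$mu_c <- matrix(mu_p, 1)
  m$par$phi_c <- matrix(log(s2_p - cfg$variance_floor), 1)
  enc <- vader_encode(m, tn)
  lt <- loss_terms(m, tn, eps = matrix(0, 4, 2))
  kl_hand <- mean(vapply(1:4, function(i)
    kl_diag_oracle(enc$mu[i, ], exp(enc$lv[i, ]), mu_p, s2_p), numeric(1)))
  expect_equal(unname(lt["latent_loss"]), kl_hand, tolerance = 1e-8)

  # q identical to the single prior component: latent loss exactly 0.
  # Force a constant encoder so mu = mu_c and lv = log s2_c.
  m$par$mu.W[] <- 0; m$par$mu.b <- mu_p
  m$par$lv.W[] <- 0; m$par$lv.b <- log(s2_p)
  lt0 <- loss_terms(m, tn, eps = matrix(0, 4, 2))
  expect_equal(unname(lt0["latent_loss"]), 0, tolerance = 1e-10)
})

test_that("responsibilities equal the direct Bayes posterior on hand-set points", {
  cfg <- vader_config(K = 3, L = 2, hidden_size = 4, seed = 3,
                      variance_floor = 1e-6)
  tn <- toy_tensor(n = 10, tt = 2, d = 2, seed = 9)
  m <- vader_init(cfg, tn)
  set.seed(10)
  m$par$mu_c <- matrix(rnorm(6), 3, 2)
  m$par$phi_c <- matrix(rnorm(6, 0, 0.5), 3, 2)
  m$par$rho <- c(0.2, -0.4, 1.1)
  a <- assign_clusters(m, tn)
  # brute-force Bayes with dnorm products at the latent means
  enc <- vader_encode(m, tn)
  s2 <- 1e-6 + exp(m$par$phi_c)
  pi_k <- exp(m$par$rho) / sum(exp(m$par$rho))
  for (i in 1:10) {
    dens <- vapply(1:3, function(k)
      pi_k[k] * prod(dnorm(enc$mu[i, ], m$par$mu_c[k, ], sqrt(s2[k, ]))),
      numeric(1))
    expect_equal(a$responsibilities[i, ], dens / sum(dens), tolerance = 1e-9)
  }
  expect_equal(rowSums(a$responsibilities), rep(1, 10), tolerance = 1e-6)
  expect_equal(a$labels, apply(a$responsibilities, 1, which.max))
})

test_that("a point on a far-separated component gets that label with certainty", {
  cfg <- vader_config(K = 2, L = 2, hidden_size = 4, seed = 4)
  tn <- toy_tensor(n = 3, tt = 2, d = 2, seed = 11)
  m <- vader_init(cfg, tn)
  enc <- vader_encode(m, tn)
  m$par$mu_c <- rbind(enc$mu[1, ], enc$mu[1, ] + 50)
  m$par$phi_c <- matrix(0, 2, 2)
  m$par$rho <- c(0, 0)
  a <- assign_clusters(m, tn)
  expect_equal(a$labels[1], 1L)
  expect_gte(a$responsibilities[1, 1], 0.99)
})

test_that("masked cells never contribute to the reconstruction loss", {
  tn <- toy_tensor(n = 5, tt = 3, d = 3, seed = 12, miss = 0.3)
  cfg <- vader_config(K = 2, L = 2, hidden_size = 5, seed = 5)
  m <- vader_init(cfg, tn)
  eps <- matrix(0, 5, 2)
  base <- loss_terms(m, tn, eps = eps)
  tn2 <- tn
  tn2$values[tn2$mask == 0] <- 99  # perturb unobserved cells only
  pert <- loss_terms(m, tn2, eps = eps)
  expect_identical(base, pert)
})

test_that("perfect reconstruction yields zero reconstruction loss", {
  tn <- toy_tensor(n = 3, tt = 2, d = 2, seed = 13)
  cfg <- vader_config(K = 1, L = 2, hidden_size = 4, seed = 6)
  m <- vader_init(cfg, tn)
  # constant-zero input is reproducible by a zeroed decoder head
  tn$values[] <- 0
  m$par$out.W[] <- 0; m$par$out.b[] <- 0
  lt <- loss_terms(m, tn, eps = matrix(0, 3, 2))
  expect_equal(unname(lt["reconstruction_loss"]), 0)
})

test_that("pretraining reduces reconstruction loss and pretrain_epochs = 0 is inert", {
  tn <- study_tensor()
  small <- tensor_subset(tn, 1:120)
  cfg0 <- vader_config(K = 5, hidden_size = 16, pretrain_epochs = 0, seed = 7)
  m0 <- pretrain(small, cfg0)
  m_init <- vader_init(cfg0, small)
  expect_identical(m0$par, m_init$par)

  cfg <- vader_config(K = 5, hidden_size = 16, pretrain_epochs = 30, seed = 7)
  m <- pretrain(small, cfg)
  expect_lt(tail(m$log$reconstruction_loss, 1), m$log$reconstruction_loss[1])

  # constant-zero data is learned to near-zero loss
  zero <- small
  zero$values[] <- 0
  zero$mask[] <- 1
  mz <- pretrain(zero, vader_config(K = 1, hidden_size = 8, L = 2,
                                    pretrain_epochs = 100, seed = 8))
  expect_lte(tail(mz$log$reconstruction_loss, 1), 0.01)
})

test_that("mixture initialization recovers separated latent blobs and floors variance", {
  tn <- toy_tensor(n = 40, tt = 2, d = 3, seed = 14)
  cfg <- vader_config(K = 2, L = 2, hidden_size = 6, seed = 9)
  m <- vader_init(cfg, tn)
  # K = 1: single component at the latent mean
  m1 <- init_mixture(m, tn, K = 1)
  enc <- vader_encode(m, tn)
  expect_equal(softmax_like <- exp(m1$par$rho) / sum(exp(m1$par$rho)), 1)
  expect_equal(as.numeric(m1$par$mu_c), colMeans(enc$mu), tolerance = 1e-6)

  # two well-separated blobs in a synthetic latent space
  set.seed(15)
  X <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
             matrix(rnorm(100, 4, 0.1), 50, 2))
  fit <- gmm_fit(X, 2, seed = 1)
  centers <- fit$mu[order(fit$mu[, 1]), ]
  expect_lt(max(abs(centers - rbind(c(0, 0), c(4, 4)))), 0.1)

  # degenerate identical latents: variances at floor, no crash
  fitd <- gmm_fit(matrix(1, 20, 2), 2, floor = 1e-4, seed = 2)
  expect_true(all(fitd$sigma2 >= 1e-4))
  expect_error(gmm_fit(matrix(rnorm(10), 5, 2), 6), "exceeds")
})

test_that("training is seed-deterministic and epochs = 0 is a no-op", {
  tn <- tensor_subset(study_tensor(), 1:100)
  cfg <- vader_config(K = 3, hidden_size = 8, epochs = 5, pretrain_epochs = 5,
                      seed = 10)
  m1 <- fit_vader(tn, cfg)
  m2 <- fit_vader(tn, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$par, m2$par)

  cfg0 <- vader_config(K = 3, hidden_size = 8, epochs = 0, pretrain_epochs = 3,
                       seed = 10)
  m <- pretrain(tn, cfg0)
  m <- init_mixture(m, tn)
  m3 <- train_full(m, tn)
  expect_identical(m3$par, m$par)
})

test_that("permuting participants permutes labels identically", {
  tn <- tensor_subset(study_tensor(), 1:150)
  cfg <- vader_config(K = 3, hidden_size = 8, epochs = 10, pretrain_epochs = 10,
                      seed = 11)
  m <- fit_vader(tn, cfg)
  a <- assign_clusters(m, tn)
  perm <- sample(150)
  a2 <- assign_clusters(m, tensor_subset(tn, perm))
  expect_identical(a2$labels, a$labels[perm])
})

test_that("a fitted model round-trips through its archive", {
  tn <- toy_tensor(n = 8, tt = 2, d = 2, seed = 16)
  cfg <- vader_config(K = 2, L = 2, hidden_size = 4, epochs = 2,
                      pretrain_epochs = 2, seed = 12)
  m <- fit_vader(tn, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_vader(m, path)
  m2 <- load_vader(path)
  expect_identical(m2$par, m$par)
  expect_identical(assign_clusters(m2, tn)$labels,
                   assign_clusters(m, tn)$labels)
})
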