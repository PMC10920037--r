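infer_types <- function(df, types = NULL) {
  vars <- setdiff(names(df), "participant")
  out <- stats::setNames(character(length(vars)), vars)
  for (v in vars) {
    x <- df[[v]]
    if (!is.null(types) && v %in% names(types)) {
      out[v] <- types[[v]]
    } else if (is.factor(x) || is.character(x)) {
      out[v] <- if (length(unique(stats::na.omit(x))) > 2) "nominal" else "binary"
    } else if (length(unique(stats::na.omit(x))) <= 2) {
      out[v] <- "binary"
    } else {
      out[v] <- "continuous"
    }
  }
  out
}

#' Screen baseline characteristics for inter-cluster differences
#'
#' Continuous variables are tested with one-way ANOVA (classic F over
#' between/within mean squares), categorical ones with the Pearson
#' chi-square test (no continuity correction). Selection is p < 0.05,
#' deliberately without multiplicity adjustment: the screen exists to
#' feed the regression, and minimizing type II error is the priority.
#' Tests use available cases; a variable with a single observed level
#' is excluded with a reason.
#'
#' @param covariate_table data.frame of baseline variables (an optional
#'   `participant` column is ignored).
#' @param labels cluster labels (factor or vector), one per row.
#' @param types optional named vector overriding type inference
#'   ("continuous", "binary", "nominal").
#' @return data.frame (variable, test, statistic, df1, df2, p_value,
#'   selected, note).
#' @export
screen_predictors <- function(covariate_table, labels, types = NULL) {
  g <- factor(labels)
  if (nlevels(g) < 2) stop_field("labels", "need at least 2 clusters")
  tp <- infer_types(covariate_table, types)
  rows <- lapply(names(tp), function(v) {
    x <- covariate_table[[v]]
    ok <- !is.na(x) & !is.na(g)
    out <- data.frame(variable = v, test = NA_character_,
                      statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                      p_value = NA_real_, selected = FALSE, note = "",
                      stringsAsFactors = FALSE)
    if (length(unique(x[ok])) < 2) {
      out$note <- "single observed level"
      return(out)
    }
    if (tp[v] == "continuous") {
      tt <- stats::oneway.test(x[ok] ~ g[ok], var.equal = TRUE)
      out$test <- "one-way ANOVA F"
      out$statistic <- unname(tt$statistic)
      out$df1 <- unname(tt$parameter[1]); out$df2 <- unname(tt$parameter[2])
      out$p_value <- tt$p.value
    } else {
      tab <- table(x[ok], droplevels(g[ok]))
      tt <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out$test <- "Pearson chi-square"
      out$statistic <- unname(tt$statistic)
      out$df1 <- unname(tt$parameter)
      out$p_value <- tt$p.value
    }
    out$selected <- is.finite(out$p_value) && out$p_value < 0.05
    out
  })
  do.call(rbind, rows)
}

# Bayesian-draw linear regression + predictive mean matching (5 donors)
pmm_impute_one <- function(y, X, mis, donors = 5) {
  obs <- which(!mis)
  Xo <- X[obs, , drop = FALSE]
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[mis, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, y[obs])
  dfres <- max(length(obs) - ncol(Xo), 1)
  s2 <- sum(fit$residuals^2) / dfres
  s2_star <- s2 * dfres / stats::rchisq(1, dfres)
  XtXi <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
  beta_star <- fit$coefficients +
    drop(chol(s2_star * XtXi + diag(1e-12, ncol(Xo))) %*% stats::rnorm(ncol(Xo)))
  yhat_obs <- drop(Xo %*% fit$coefficients)
  yhat_mis <- drop(Xm %*% beta_star)
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    y[obs][sample(pool, 1)]
  }, numeric(1))
}

logistic_impute_one <- function(y, X, mis) {
  obs <- which(!mis)
  df <- as.data.frame(X[, -1, drop = FALSE])
  yy <- factor(y[obs])
  fit <- suppressWarnings(stats::glm(yy ~ ., data = df[obs, , drop = FALSE],
                                     family = stats::binomial()))
  if (!fit$converged) stop("logistic model did not converge")
  vc <- suppressWarnings(stats::vcov(fit))
  co <- stats::coef(fit)
  ok <- !is.na(co)
  draw <- co
  draw[ok] <- co[ok] + drop(chol(vc[ok, ok] + diag(1e-10, sum(ok))) %*%
                              stats::rnorm(sum(ok)))
  draw[!ok] <- 0
  eta <- drop(cbind(1, as.matrix(df[mis, , drop = FALSE])) %*% draw)
  lvls <- levels(yy)
  picked <- lvls[1 + stats::rbinom(length(eta), 1, stats::plogis(eta))]
  if (is.numeric(y)) as.numeric(picked) else picked
}

nominal_impute_one <- function(y, X, mis) {
  obs <- which(!mis)
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$.y <- factor(y)
  fit <- nnet::multinom(.y ~ ., data = df[obs, , drop = FALSE],
                        trace = FALSE, maxit = 300)
  pr <- stats::predict(fit, newdata = df[mis, , drop = FALSE], type = "probs")
  pr <- matrix(pr, nrow = sum(mis))
  lvls <- levels(df$.y)
  if (ncol(pr) == 1) pr <- cbind(1 - pr, pr)
  picked <- apply(pr, 1, function(p) sample(lvls, 1, prob = p))
  if (is.numeric(y)) as.numeric(picked) else picked
}

#' Multiple imputation of baseline covariates by chained equations
#'
#' Per-variable conditional models cycled over the incomplete
#' covariates in order of increasing missingness: predictive mean
#' matching with 5 donors (and Bayesian parameter draws) for continuous
#' variables, Bayesian logistic draws for binary, multinomial for
#' nominal. The cluster label (outcome) is included as a predictor in
#' every conditional model, as congenial imputation requires. Produces
#' m completed tables from distinct sub-seed streams; observed cells
#' are identical across all m tables. A conditional model that fails is
#' flagged with a warning and its variable skipped for that iteration.
#'
#' @param covariate_table data.frame with missing values (`participant`
#'   column passed through untouched).
#' @param labels complete cluster labels, one per row.
#' @param m number of imputed datasets (default 100).
#' @param iterations chained-equation sweeps per dataset (default 10).
#' @param seed master seed.
#' @param types optional named type overrides.
#' @return an object of class `imputed_stack`: list with `imputations`
#'   (list of m data.frames), `m`, `iterations`, `types`, `seed`.
#' @export
mice_impute <- function(covariate_table, labels, m = 100, iterations = 10,
                        seed = 1L, types = NULL) {
  tp <- infer_types(covariate_table, types)
  vars <- names(tp)
  for (v in vars)
    if (all(is.na(covariate_table[[v]])))
      stop_field(v, "has no observed values")
  n_mis <- vapply(vars, function(v) sum(is.na(covariate_table[[v]])), numeric(1))
  visit <- vars[order(n_mis)]
  visit <- visit[n_mis[order(n_mis)] > 0]
  g <- factor(labels)

  imputations <- vector("list", m)
  for (j in seq_len(m)) {
    set.seed(derive_seed(seed, 5000 + j))
    comp <- covariate_table
    for (v in visit) {
      mis <- is.na(comp[[v]])
      comp[[v]][mis] <- sample(comp[[v]][!mis], sum(mis), replace = TRUE)
    }
    if (length(visit)) {
      for (it in seq_len(iterations)) {
        for (v in visit) {
          mis <- is.na(covariate_table[[v]])
          others <- setdiff(vars, v)
          X <- stats::model.matrix(
            ~ ., data = cbind(comp[others], .cluster = g))
          res <- tryCatch(
            switch(tp[v],
              continuous = pmm_impute_one(comp[[v]], X, mis),
              binary = logistic_impute_one(comp[[v]], X, mis),
              nominal = nominal_impute_one(comp[[v]], X, mis)),
            error = function(e) {
              warning(sprintf("conditional model for '%s' failed (%s); skipped this iteration",
                              v, conditionMessage(e)), call. = FALSE)
              NULL
            })
          if (!is.null(res)) comp[[v]][mis] <- res
        }
      }
    }
    imputations[[j]] <- comp
  }
  structure(list(imputations = imputations, m = m, iterations = iterations,
                 types = tp, seed = seed), class = "imputed_stack")
}

#' Fit a baseline-category multinomial logit of cluster membership
#'
#' Maximum likelihood for the baseline-category logit model via
#' [nnet::multinom()], with all non-reference clusters fitted jointly.
#' Continuous predictors are standardized before fitting (so odds
#' ratios are per SD), Wald standard errors come from the observed
#' information, and |coefficient| > 15 triggers a separation warning.
#'
#' @param covariate_table complete data.frame of predictors.
#' @param labels cluster labels.
#' @param reference_cluster label of the reference cluster.
#' @param types optional named type overrides.
#' @param standardize_continuous standardize continuous predictors
#'   (default TRUE).
#' @return data.frame (cluster, term, estimate, se) with attributes
#'   `loglik`, `loglik_null`, `n`.
#' @export
fit_multinomial <- function(covariate_table, labels, reference_cluster,
                            types = NULL, standardize_continuous = TRUE) {
  g <- factor(labels)
  if (!reference_cluster %in% levels(g))
    stop_field("reference_cluster", "not present in labels")
  if (any(table(g) == 0)) stop_field("labels", "empty cluster present")
  g <- stats::relevel(g, ref = as.character(reference_cluster))
  tp <- infer_types(covariate_table, types)
  df <- covariate_table[names(tp)]
  if (anyNA(df)) stop_field("covariate_table", "contains missing values")
  for (v in names(tp))
    if (tp[v] == "continuous" && standardize_continuous)
      df[[v]] <- as.numeric(scale(df[[v]]))
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  df$.y <- g
  fit <- nnet::multinom(.y ~ ., data = df, Hess = TRUE, trace = FALSE,
                        maxit = 1000, reltol = 1e-12)
  sm <- summary(fit)
  co <- sm$coefficients
  se <- sm$standard.errors
  if (is.null(dim(co))) {  # K = 2: vectors
    co <- matrix(co, nrow = 1, dimnames = list(levels(g)[2], names(stats::coef(fit))))
    se <- matrix(se, nrow = 1, dimnames = dimnames(co))
  }
  if (any(abs(co) > 15))
    warning("possible separation: |coefficient| > 15", call. = FALSE)
  out <- data.frame(
    cluster = rep(rownames(co), ncol(co)),
    term = rep(colnames(co), each = nrow(co)),
    estimate = as.vector(co),
    se = as.vector(se),
    stringsAsFactors = FALSE
  )
  ll1 <- as.numeric(stats::logLik(fit))
  null_fit <- nnet::multinom(.y ~ 1, data = df, trace = FALSE)
  attr(out, "loglik") <- ll1
  attr(out, "loglik_null") <- as.numeric(stats::logLik(null_fit))
  attr(out, "n") <- nrow(df)
  out
}

#' Pool multiply-imputed regression estimates by Rubin's rules
#'
#' Per (cluster, term): pooled estimate Qbar = mean of the m estimates,
#' within-variance W = mean squared SE, between-variance B = sample
#' variance of estimates, total variance T = W + (1 + 1/m) B, degrees
#' of freedom (m - 1) \[1 + W / ((1 + 1/m) B)\]^2 (infinite when B = 0),
#' 95% CI Qbar +/- t(df, 0.975) sqrt(T), two-sided p from the t
#' reference. Estimates and CIs are exponentiated to odds ratios.
#'
#' @param fits list of m coefficient tables from [fit_multinomial()].
#' @return data.frame of class `pooled_regression_table`: (cluster,
#'   term, estimate, W, B, T, df, or, ci_lo, ci_hi, p_value).
#' @export
pool_rubin <- function(fits) {
  m <- length(fits)
  if (m < 1) stop_field("fits", "is empty")
  key0 <- paste(fits[[1]]$cluster, fits[[1]]$term)
  for (f in fits)
    if (!identical(paste(f$cluster, f$term), key0))
      stop_field("fits", "coefficient names differ across imputations")
  if (m == 1)
    warning("only one imputation: returning unpooled estimates", call. = FALSE)
  est <- sapply(fits, `[[`, "estimate")
  ses <- sapply(fits, `[[`, "se")
  est <- matrix(est, ncol = m)
  ses <- matrix(ses, ncol = m)
  qbar <- rowMeans(est)
  W <- rowMeans(ses^2)
  B <- if (m > 1) apply(est, 1, stats::var) else rep(0, nrow(est))
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  tq <- stats::qt(0.975, df)
  lo <- qbar - tq * sqrt(Tv)
  hi <- qbar + tq * sqrt(Tv)
  p <- 2 * stats::pt(-abs(qbar) / sqrt(Tv), df)
  out <- data.frame(
    cluster = fits[[1]]$cluster, term = fits[[1]]$term,
    estimate = qbar, W = W, B = B, T = Tv, df = df,
    or = exp(qbar), ci_lo = exp(lo), ci_hi = exp(hi), p_value = p,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pooled_regression_table", "data.frame")
  out
}

#' Nagelkerke's R-squared from model and null log-likelihoods
#'
#' Cox-Snell `R2_CS = 1 - exp(2 (l0 - l1) / n)` rescaled by its maximum
#' `1 - exp(2 l0 / n)` to lie in \[0, 1\].
#'
#' @param loglik fitted-model log-likelihood (>= `loglik_null`).
#' @param loglik_null intercept-only log-likelihood.
#' @param n number of observations (> 0).
#' @return Nagelkerke R-squared in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik, loglik_null, n) {
  if (n <= 0) stop_field("n", "must be positive")
  if (loglik < loglik_null - 1e-8)
    stop_field("loglik", "must be >= loglik_null")
  r2_cs <- 1 - exp(2 * (loglik_null - loglik) / n)
  r2_cs / (1 - exp(2 * loglik_null / n))
}

#' Variance inflation factors of a predictor set
#'
#' For single-column predictors, `VIF_j = 1 / (1 - R2_j)` from
#' regressing predictor j on the others. Multi-column categorical terms
#' use the generalized VIF, reported as `GVIF^(1/df)` (the square of
#' `GVIF^(1/(2 df))`) so values are comparable across terms. Perfect
#' collinearity yields an infinite VIF.
#'
#' @param covariate_table data.frame of predictors (no outcome; an
#'   optional `participant` column is ignored).
#' @return data.frame (term, df, gvif, vif).
#' @export
compute_vif <- function(covariate_table) {
  df <- covariate_table[setdiff(names(covariate_table), "participant")]
  if (ncol(df) < 2) stop_field("covariate_table", "needs >= 2 predictors")
  X <- stats::model.matrix(~ ., data = df)
  asn <- attr(X, "assign")
  X <- X[, asn != 0, drop = FALSE]
  asn <- asn[asn != 0]
  if (any(apply(X, 2, stats::sd) == 0))
    stop_field("covariate_table", "constant predictor column")
  R <- stats::cor(X)
  detR <- det(R)
  terms <- attr(stats::terms(~ ., data = df), "term.labels")
  rows <- lapply(unique(asn), function(a) {
    idx <- which(asn == a)
    if (detR <= .Machine$double.eps) {
      gvif <- Inf
    } else {
      gvif <- det(R[idx, idx, drop = FALSE]) *
        det(R[-idx, -idx, drop = FALSE]) / detR
    }
    data.frame(term = terms[a], df = length(idx), gvif = gvif,
               vif = gvif^(1 / length(idx)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen, impute, fit and pool: the full predictor analysis
#'
#' Screens candidates on the unimputed table ([screen_predictors()]),
#' multiply imputes the selected variables with the cluster label in
#' every conditional model ([mice_impute()]), fits the baseline-category
#' multinomial logit on each completed table ([fit_multinomial()]) and
#' pools by Rubin's rules ([pool_rubin()]). Nagelkerke R-squared is
#' computed per imputation and averaged; VIF is computed on the first
#' imputed dataset (optionally averaged across all).
#'
#' @param covariate_table baseline covariates (may contain missing
#'   values).
#' @param labels cluster labels.
#' @param reference_cluster reference cluster label.
#' @param m,iterations,seed imputation settings (see [mice_impute()]).
#' @param types optional named type overrides.
#' @param vif_average average VIF across imputations instead of using
#'   the first (default FALSE).
#' @return list with `screening`, `pooled` (a
#'   `pooled_regression_table`), `r2_nagelkerke`, `vif`, `m`.
#' @export
analyze_predictors <- function(covariate_table, labels, reference_cluster,
                               m = 100, iterations = 10, seed = 1L,
                               types = NULL, vif_average = FALSE) {
  screening <- screen_predictors(covariate_table, labels, types)
  keep <- screening$variable[screening$selected]
  if (!length(keep))
    stop("no variable passed the p < 0.05 screen", call. = FALSE)
  tab <- covariate_table[c(intersect(names(covariate_table), "participant"), keep)]
  stack <- mice_impute(tab, labels, m = m, iterations = iterations,
                       seed = seed, types = types)
  fits <- lapply(stack$imputations, function(d)
    fit_multinomial(d[keep], labels, reference_cluster, types = types))
  pooled <- pool_rubin(fits)
  r2 <- mean(vapply(fits, function(f)
    nagelkerke_r2(attr(f, "loglik"), attr(f, "loglik_null"), attr(f, "n")),
    numeric(1)))
  vif <- if (vif_average) {
    vs <- lapply(stack$imputations, function(d) compute_vif(d[keep]))
    out <- vs[[1]]
    out$gvif <- rowMeans(sapply(vs, `[[`, "gvif"))
    out$vif <- rowMeans(sapply(vs, `[[`, "vif"))
    out
  } else {
    compute_vif(stack$imputations[[1]][keep])
  }
  list(screening = screening, pooled = pooled, r2_nagelkerke = r2,
       vif = vif, m = m)
}
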