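#' Multi-kernel Bayesian BLUP (RKHS) via Gibbs sampling
#'
#' Fits y = mu + E_j + sum_t u_t + e with each random term
#' u_t ~ N(0, K_t sigma2_t) for an arbitrary set of observation-level PSD
#' kernels (genomic G, hyperspectral H, vegetation-index V, environmental W
#' and Hadamard G x E interaction GW), flat priors on the intercept and
#' environment effects, and scaled-inverse-chi-square priors on all
#' variances. Each kernel is handled through its eigendecomposition:
#' writing K = U D U', the term is reparameterised as u = U b with
#' independent coefficients b_k ~ N(0, d_k sigma2_t), so one Gibbs sweep
#' updates every coefficient of a term jointly in closed form.
#' Observations with a masked (NA) response stay in the model: they are
#' imputed from the current linear predictor each sweep, and their
#' posterior-mean linear predictor is the reported prediction.
#'
#' Prior scales follow the usual R2-split convention: the prior expects a
#' fraction `R2` of the response variance to be explained, divided equally
#' across kernel terms, with `df0` prior degrees of freedom per variance.
#' A variance named in `fix_var` is held at that value (degenerate prior).
#'
#' @param y numeric response with `NA` for masked entries (e.g. test-set
#'   records in cross-validation).
#' @param env factor/character of environment (year) labels, or `NULL` for
#'   an intercept-only fixed part. An environment with no unmasked records
#'   is predicted with the mean of the training-environment effects (its
#'   environment-specific signal, if any, must come through W/GW terms);
#'   a message reports when this is triggered.
#' @param kernels named list of observation-level [kernel] objects (or bare
#'   matrices) in the row order of `y`.
#' @param n_iter,burn_in,thin Gibbs sweeps, burn-in sweeps discarded from
#'   posterior summaries, and thinning interval for stored variance
#'   samples. Predictions and effect means accumulate over every
#'   post-burn-in sweep regardless of thinning.
#' @param df0 prior degrees of freedom for every variance.
#' @param R2 prior proportion of variance explained by the kernel terms
#'   jointly, in (0, 1).
#' @param fix_var named list pinning variances, e.g.
#'   `list(G = 0.4, e = 0.2)`; use `"e"` for the residual.
#' @param seed integer seed; fixed seed gives a reproducible chain.
#' @param verbose print progress every 2000 sweeps.
#' @return object of class `kernpred_fit`: posterior means/sds of the
#'   intercept, environment effects and variances, per-term effect vectors
#'   `u`, fitted values `yhat` for every observation (masked ones
#'   included), thinned variance samples, and bookkeeping fields.
#' @export
fit_multikernel <- function(y, env = NULL, kernels, n_iter = 12000L,
                            burn_in = 2000L, thin = 5L, df0 = 5,
                            R2 = 0.5, fix_var = NULL, seed = 1L,
                            verbose = FALSE) {
  n <- length(y)
  stopifnot(length(kernels) >= 1L, burn_in < n_iter, R2 > 0, R2 < 1)
  if (is.null(names(kernels)) || any(!nzchar(names(kernels)))) {
    stop("kernels must be a named list")
  }
  set.seed(seed)
  masked <- is.na(y)
  if (sum(!masked) < 3L) stop("need at least 3 unmasked observations")

  # fixed-effect design: intercept + environment (treatment coding)
  if (!is.null(env)) {
    env <- as.character(env)
    stopifnot(length(env) == n)
    train_envs <- sort(unique(env[!masked]))
    X <- matrix(0, n, length(train_envs),
                dimnames = list(NULL, train_envs))
    known <- env %in% train_envs
    X[cbind(which(known), match(env[known], train_envs))] <- 1
    if (any(!known)) {
      message(sum(!known), " observation(s) in unseen environment(s) ",
              "predicted with the mean of training-environment effects")
      X[!known, ] <- 1 / length(train_envs)
    }
  } else {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "mu"))
  }
  p <- ncol(X)
  if (sum(!masked) <= p) stop("fewer unmasked observations than fixed levels")
  XtX <- crossprod(X)
  if (qr(XtX)$rank < p) stop("fixed-effect design is rank deficient")
  XtX_chol <- chol(XtX)

  # eigendecomposition of each kernel term
  terms <- names(kernels)
  eig <- lapply(kernels, function(k) {
    K <- if (inherits(k, "kernel")) k$K else as.matrix(k)
    if (nrow(K) != n) stop("kernel dimension does not match observations")
    es <- eigen((K + t(K)) / 2, symmetric = TRUE)
    keep <- es$values > 1e-10 * max(es$values)
    if (min(es$values) < -1e-8 * max(es$values)) {
      stop("kernel is not PSD (smallest eigenvalue ", min(es$values), ")")
    }
    mean_diag <- mean(diag(K))
    list(U = es$vectors[, keep, drop = FALSE], d = es$values[keep],
         m = sum(keep), mean_diag = mean_diag)
  })

  # initial values and prior scales
  y_obs <- y[!masked]
  vy <- stats::var(y_obs)
  if (vy == 0) vy <- .Machine$double.eps
  yc <- y
  yc[masked] <- mean(y_obs)
  nt <- length(terms)
  S0 <- vapply(terms, function(t) {
    vy * R2 / nt * (df0 + 2) / max(eig[[t]]$mean_diag, 1e-12)
  }, numeric(1))
  S0e <- vy * (1 - R2) * (df0 + 2)
  sigma2 <- vapply(terms, function(t) {
    vy * R2 / nt / max(eig[[t]]$mean_diag, 1e-12)
  }, numeric(1))
  sigma2e <- vy * (1 - R2)
  fixed <- rep(FALSE, nt); names(fixed) <- terms
  fixed_e <- FALSE
  for (nm in names(fix_var)) {
    if (nm == "e") { sigma2e <- fix_var[[nm]]; fixed_e <- TRUE }
    else if (nm %in% terms) { sigma2[nm] <- fix_var[[nm]]; fixed[nm] <- TRUE }
    else stop("fix_var names must be kernel names or 'e'")
  }

  beta <- rep(0, p)
  b <- lapply(terms, function(t) rep(0, eig[[t]]$m)); names(b) <- terms
  u <- lapply(terms, function(t) rep(0, n)); names(u) <- terms
  e <- yc - as.vector(X %*% beta)

  n_keep <- n_iter - burn_in
  acc_eta <- rep(0, n); acc_beta <- rep(0, p)
  acc_u <- lapply(terms, function(t) rep(0, n)); names(acc_u) <- terms
  acc_v <- acc_v2 <- c(sigma2 * 0, e = 0)
  n_samp <- floor(n_keep / thin)
  samples <- matrix(NA_real_, n_samp, nt + 1L,
                    dimnames = list(NULL, c(terms, "e")))
  isamp <- 0L

  for (it in seq_len(n_iter)) {
    # fixed effects (flat prior)
    r <- e + as.vector(X %*% beta)
    bhat <- backsolve(XtX_chol,
                      backsolve(XtX_chol, crossprod(X, r),
                                transpose = TRUE))
    beta <- as.vector(bhat) +
      backsolve(XtX_chol, stats::rnorm(p)) * sqrt(sigma2e)
    xb <- as.vector(X %*% beta)
    e <- r - xb

    # kernel terms: joint update of eigen-coefficients
    for (t in terms) {
      et <- eig[[t]]
      r <- e + u[[t]]
      rv <- crossprod(et$U, r)
      cvar <- 1 / (1 / sigma2e + 1 / (et$d * sigma2[t]))
      b[[t]] <- as.vector(rv) / sigma2e * cvar +
        stats::rnorm(et$m) * sqrt(cvar)
      u[[t]] <- as.vector(et$U %*% b[[t]])
      e <- r - u[[t]]
      if (!fixed[t]) {
        ss <- sum(b[[t]]^2 / et$d)
        sigma2[t] <- (ss + S0[t]) /
          stats::rchisq(1L, df = df0 + et$m)
      }
    }

    # impute masked responses from the current linear predictor
    if (any(masked)) {
      eta_m <- xb[masked] + Reduce(`+`, lapply(u, `[`, masked))
      yc[masked] <- eta_m + stats::rnorm(sum(masked)) * sqrt(sigma2e)
      e[masked] <- yc[masked] - eta_m
    }
    if (!fixed_e) {
      sigma2e <- (sum(e^2) + S0e) / stats::rchisq(1L, df = df0 + n)
    }

    if (it > burn_in) {
      eta <- xb + Reduce(`+`, u)
      acc_eta <- acc_eta + eta
      acc_beta <- acc_beta + beta
      for (t in terms) acc_u[[t]] <- acc_u[[t]] + u[[t]]
      v <- c(sigma2, e = sigma2e)
      acc_v <- acc_v + v; acc_v2 <- acc_v2 + v^2
      if ((it - burn_in) %% thin == 0L && isamp < n_samp) {
        isamp <- isamp + 1L
        samples[isamp, ] <- v
      }
    }
    if (verbose && it %% 2000L == 0L) {
      message("sweep ", it, " / ", n_iter)
    }
  }

  post_v <- acc_v / n_keep
  post_v_sd <- sqrt(pmax(acc_v2 / n_keep - post_v^2, 0))
  beta_hat <- acc_beta / n_keep
  env_eff <- if (!is.null(env)) {
    stats::setNames(beta_hat, colnames(X))
  } else NULL
  structure(list(
    mu = if (is.null(env)) beta_hat[1] else mean(beta_hat),
    env_effects = env_eff,
    var_post = post_v, var_post_sd = post_v_sd,
    u = lapply(acc_u, function(a) a / n_keep),
    yhat = acc_eta / n_keep,
    samples = samples[seq_len(isamp), , drop = FALSE],
    masked = masked, terms = terms,
    n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed),
    class = "kernpred_fit")
}

#' @exportS3Method print kernpred_fit
print.kernpred_fit <- function(x, ...) {
  cat("Multi-kernel RKHS fit:", length(x$yhat), "observations,",
      sum(x$masked), "masked\n")
  cat("terms:", paste(x$terms, collapse = " + "), "\n")
  cat("posterior-mean variances:\n")
  print(round(x$var_post, 5))
  invisible(x)
}

#' Feature table from kernel rows for the ML baselines
#'
#' Each observation's feature vector is the concatenation of its rows of
#' the supplied observation-level kernels (relationship/covariance rows as
#' predictors), aligned by the shared observation order — the analogue of
#' left-joining per-source predictor tables on year and genotype.
#'
#' @param kernels named list of observation-level [kernel]s with identical
#'   label order.
#' @return numeric matrix, one row per observation.
#' @export
ml_features <- function(kernels) {
  stopifnot(length(kernels) >= 1L)
  labs <- NULL
  blocks <- lapply(names(kernels), function(nm) {
    k <- kernels[[nm]]
    K <- if (inherits(k, "kernel")) k$K else as.matrix(k)
    if (is.null(labs)) labs <<- rownames(K)
    else if (!identical(rownames(K), labs)) {
      stop("kernel label order mismatch in ml_features()")
    }
    colnames(K) <- paste0(nm, "_", seq_len(ncol(K)))
    K
  })
  do.call(cbind, blocks)
}

#' Random-forest regression baseline
#'
#' Regression forest with 100 trees and all predictors considered at every
#' split, mirroring the usual default for regression forests on kernel-row
#' features; a fixed seed makes predictions reproducible.
#'
#' @param x_train,x_test numeric feature matrices with identical columns.
#' @param y_train numeric response for the training rows.
#' @param n_trees number of trees (default 100).
#' @param seed random seed (default 42).
#' @return numeric predictions for `x_test` rows.
#' @export
fit_rfr <- function(x_train, y_train, x_test, n_trees = 100L, seed = 42L) {
  stopifnot(n_trees >= 1L, nrow(x_train) == length(y_train))
  if (anyNA(x_train) || anyNA(x_test)) {
    stop("missing feature values after alignment")
  }
  if (!identical(colnames(x_train), colnames(x_test))) {
    stop("train and test feature columns differ")
  }
  df_tr <- data.frame(y = y_train, x_train, check.names = TRUE)
  fit <- ranger::ranger(y ~ ., data = df_tr, num.trees = n_trees,
                        mtry = ncol(x_train), seed = seed,
                        num.threads = 1L)
  df_te <- data.frame(x_test, check.names = TRUE)
  as.numeric(stats::predict(fit, data = df_te,
                            num.threads = 1L)$predictions)
}

# NIPALS PLS1: returns projection objects for up to ncomp components.
# With a single response the NIPALS inner loop converges in one pass, so
# max_iter only caps the (never-reached) defensive iteration count.
.pls_nipals <- function(X, y, ncomp, max_iter = 200L, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  Xd <- X; yd <- y
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp); Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) { ncomp <- a - 1L; break }
    w <- w / nw
    tvec <- as.vector(Xd %*% w)
    tt <- sum(tvec^2)
    if (tt < .Machine$double.eps) { ncomp <- a - 1L; break }
    pvec <- crossprod(Xd, tvec) / tt
    qa <- sum(yd * tvec) / tt
    Xd <- Xd - tcrossprod(tvec, pvec)
    yd <- yd - qa * tvec
    W[, a] <- w; P[, a] <- pvec; Q[a] <- qa; Tm[, a] <- tvec
  }
  list(W = W[, seq_len(ncomp), drop = FALSE],
       P = P[, seq_len(ncomp), drop = FALSE],
       Q = Q[seq_len(ncomp)], ncomp = ncomp)
}

.pls_coef <- function(fit, ncomp) {
  W <- fit$W[, seq_len(ncomp), drop = FALSE]
  P <- fit$P[, seq_len(ncomp), drop = FALSE]
  Q <- fit$Q[seq_len(ncomp)]
  R <- W %*% solve(crossprod(P, W))
  as.vector(R %*% Q)
}

#' Partial least-squares regression baseline
#'
#' NIPALS PLS1 on centred/scaled features and centred response. The number
#' of latent components is chosen by inner k-fold cross-validation on the
#' training set, minimising mean squared error over 1..`max_comp`
#' components (capped at the feature rank).
#'
#' @param x_train,x_test numeric feature matrices with identical columns.
#' @param y_train numeric response for the training rows.
#' @param max_comp largest component count considered (default 20).
#' @param max_iter NIPALS iteration cap per component (default 200).
#' @param inner_k inner cross-validation folds (default 5).
#' @param seed seed for the inner fold split.
#' @return list with `pred` (test predictions), `ncomp` (selected
#'   components) and `cv_mse` (inner-CV curve).
#' @export
fit_plsr <- function(x_train, y_train, x_test, max_comp = 20L,
                     max_iter = 200L, inner_k = 5L, seed = 1L) {
  stopifnot(max_iter >= 1L, nrow(x_train) == length(y_train))
  if (stats::var(y_train) == 0) {
    stop("zero-variance response in PLSR training fold")
  }
  mu_x <- colMeans(x_train)
  sd_x <- apply(x_train, 2L, stats::sd)
  keep <- sd_x > .Machine$double.eps
  xs <- sweep(sweep(x_train[, keep, drop = FALSE], 2L, mu_x[keep], "-"),
              2L, sd_x[keep], "/")
  xt <- sweep(sweep(x_test[, keep, drop = FALSE], 2L, mu_x[keep], "-"),
              2L, sd_x[keep], "/")
  mu_y <- mean(y_train)
  ys <- y_train - mu_y
  rank_cap <- min(qr(xs)$rank, nrow(xs) - 1L)
  ncmax <- max(1L, min(max_comp, rank_cap))

  set.seed(seed)
  n <- nrow(xs)
  k <- min(inner_k, n)
  fold <- sample(rep_len(seq_len(k), n))
  sse <- numeric(ncmax); cnt <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    if (stats::var(ys[tr]) == 0) next
    fitf <- .pls_nipals(xs[tr, , drop = FALSE], ys[tr],
                        min(ncmax, sum(tr) - 1L), max_iter)
    for (a in seq_len(ncmax)) {
      aa <- min(a, fitf$ncomp)
      if (aa < 1L) next
      pf <- xs[!tr, , drop = FALSE] %*% .pls_coef(fitf, aa)
      sse[a] <- sse[a] + sum((ys[!tr] - pf)^2)
    }
    cnt <- cnt + sum(!tr)
  }
  cv_mse <- sse / max(cnt, 1L)
  ncomp <- which.min(cv_mse)
  fit <- .pls_nipals(xs, ys, ncomp, max_iter)
  beta <- .pls_coef(fit, fit$ncomp)
  list(pred = as.vector(xt %*% beta) + mu_y, ncomp = fit$ncomp,
       cv_mse = cv_mse)
}
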