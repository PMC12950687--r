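sim_kernel_data <- function(n, seed, s2g = 1.5, s2e = 0.8, rank = 30) {
  set.seed(seed)
  Z <- matrix(rnorm(n * rank), n)
  K <- tcrossprod(Z) / rank
  u <- as.vector(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) * sqrt(s2g)
  y <- 2 + u + rnorm(n, 0, sqrt(s2e))
  list(K = K, y = y, u = u, s2g = s2g, s2e = s2e)
}

test_that("pinned-variance Gibbs matches the closed-form BLUP", {
  d <- sim_kernel_data(50, seed = 13)
  n <- length(d$y)
  fit <- fit_multikernel(d$y, kernels = list(G = d$K), n_iter = 6000,
                         burn_in = 1000,
                         fix_var = list(G = d$s2g, e = d$s2e), seed = 1)
  lam <- d$s2e / d$s2g
  V <- d$s2g * d$K + d$s2e * diag(n)
  Vi <- solve(V)
  beta <- sum(Vi %*% d$y) / sum(Vi)
  u_star <- as.vector(d$K %*% solve(d$K + lam * diag(n), d$y - beta))
  rel <- sqrt(sum((fit$u$G - u_star)^2) / sum(u_star^2))
  expect_lt(rel, 0.05)
})

test_that("a constant response collapses onto the intercept", {
  K <- tcrossprod(matrix(rnorm(30 * 10), 30)) / 10
  y <- rep(3.5, 30)
  fit <- fit_multikernel(y, kernels = list(G = K), n_iter = 1500,
                         burn_in = 300, seed = 2)
  expect_equal(unname(fit$mu), 3.5, tolerance = 0.05)
  expect_lt(fit$var_post["G"], 1e-6)
  expect_lt(max(abs(fit$yhat - 3.5)), 0.05)
})

test_that("chains are reproducible and honest about masking", {
  d <- sim_kernel_data(40, seed = 21)
  f1 <- fit_multikernel(d$y, kernels = list(G = d$K), n_iter = 800,
                        burn_in = 200, seed = 5)
  f2 <- fit_multikernel(d$y, kernels = list(G = d$K), n_iter = 800,
                        burn_in = 200, seed = 5)
  expect_identical(f1$yhat, f2$yhat)
  expect_identical(f1$var_post, f2$var_post)

  ym <- d$y
  ym[1:8] <- NA
  fm <- fit_multikernel(ym, kernels = list(G = d$K), n_iter = 3000,
                        burn_in = 500, seed = 5)
  expect_true(all(fm$masked[1:8]))
  expect_true(all(is.finite(fm$yhat)))
  # masked predictions carry signal from relatives
  expect_gt(cor(fm$yhat[1:8], d$u[1:8] + 2), 0.3)
})

test_that("an all-but-zero-variance extra term leaves predictions alone", {
  d <- sim_kernel_data(60, seed = 31)
  extra <- tcrossprod(matrix(rnorm(60 * 15), 60)) / 15
  f1 <- fit_multikernel(d$y, kernels = list(G = d$K), n_iter = 3000,
                        burn_in = 500, seed = 3)
  f2 <- fit_multikernel(d$y, kernels = list(G = d$K, Z = extra),
                        n_iter = 3000, burn_in = 500, seed = 3,
                        fix_var = list(Z = 1e-10))
  expect_gt(cor(f1$yhat, f2$yhat), 0.999)
  expect_lt(mean(abs(f1$yhat - f2$yhat)) / stats::sd(d$y), 0.05)
  expect_lt(max(abs(f1$yhat - f2$yhat)) / stats::sd(d$y), 0.15)
})

test_that("environment fixed effects and unseen environments are handled", {
  set.seed(8)
  n <- 60
  K <- tcrossprod(matrix(rnorm(n * 20), n)) / 20
  env <- rep(c("Y1", "Y2", "Y3"), each = 20)
  shift <- c(Y1 = 0, Y2 = 5, Y3 = -3)
  y <- shift[env] + rnorm(n, 0, 0.5)
  fit <- fit_multikernel(y, env = env, kernels = list(G = K),
                         n_iter = 2000, burn_in = 400, seed = 4)
  eff <- fit$env_effects
  expect_equal(unname(eff["Y2"] - eff["Y1"]), 5, tolerance = 0.5)

  ym <- y
  ym[env == "Y3"] <- NA
  expect_message(
    fu <- fit_multikernel(ym, env = env, kernels = list(G = K),
                          n_iter = 1000, burn_in = 200, seed = 4),
    "unseen environment")
  # unseen-year records sit at the mean of training-environment effects
  expect_equal(mean(fu$yhat[env == "Y3"]),
               mean(fu$env_effects), tolerance = 0.5)
})

test_that("sampler guards reject invalid inputs", {
  K <- diag(4)
  expect_error(fit_multikernel(rnorm(4), kernels = list(G = diag(3))),
               "dimension")
  expect_error(fit_multikernel(rnorm(4), kernels = list(diag(4))),
               "named")
  npd <- diag(4); npd[1, 1] <- -2
  expect_error(fit_multikernel(rnorm(4), kernels = list(G = npd)),
               "not PSD")
  expect_error(fit_multikernel(c(1, 2, NA, NA), kernels = list(G = K),
                               n_iter = 10, burn_in = 1),
               "at least 3 unmasked")
})

test_that("random-forest baseline is deterministic and fits in-sample", {
  set.seed(12)
  x <- matrix(rnorm(150 * 8), 150, dimnames = list(NULL, paste0("k", 1:8)))
  y <- as.vector(x %*% rnorm(8)) + rnorm(150, 0, 0.3)
  p1 <- fit_rfr(x, y, x)
  p2 <- fit_rfr(x, y, x)
  expect_identical(p1, p2)
  expect_gt(cor(p1, y), 0.95)
  expect_equal(fit_rfr(x, rep(2, 150), x), rep(2, 150), tolerance = 1e-12)
  expect_error(fit_rfr(x, y, x[, 1:3]), "columns differ")
})

test_that("PLSR reduces to least squares and finds exact signal", {
  set.seed(14)
  x <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "f"))
  y <- 1 + 3 * x[, 1] + rnorm(40, 0, 0.2)
  f <- fit_plsr(x, y, x, max_comp = 1)
  expect_equal(f$pred, unname(fitted(lm(y ~ x))), tolerance = 1e-10)
  expect_equal(f$ncomp, 1L)

  x3 <- cbind(a = y, b = y, c = y)
  f3 <- fit_plsr(x3, y, x3)
  expect_equal(f3$ncomp, 1L)  # inner CV picks one component
  expect_equal(f3$pred, y, tolerance = 1e-8)
  # component count never exceeds feature rank
  expect_lte(fit_plsr(x3, y, x3, max_comp = 10)$ncomp, qr(scale(x3))$rank)
  expect_error(fit_plsr(x, rep(1, 40), x), "zero-variance")
})

test_that("ml_features concatenates aligned kernel rows", {
  pd <- medium_pdata()$pdata
  f <- ml_features(pd$kernels[c("Gexp", "V")])
  expect_equal(nrow(f), nrow(pd$obs))
  expect_equal(ncol(f), 2 * nrow(pd$obs))
  k2 <- pd$kernels$V
  k2$K <- k2$K[rev(seq_len(nrow(k2$K))), rev(seq_len(nrow(k2$K)))]
  expect_error(ml_features(list(G = pd$kernels$Gexp, V = k2$K)),
               "label order")
})
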