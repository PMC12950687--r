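test_that("CV2 folds are balanced, deterministic and level-aware", {
  obs10 <- data.frame(genotype = paste0("g", 1:10))
  f <- make_cv2_folds(obs10, k = 5, seed = 1)
  expect_equal(as.vector(sort(table(f))), rep(2L, 5))

  obs11 <- data.frame(genotype = paste0("g", 1:11))
  f11 <- make_cv2_folds(obs11, k = 5, seed = 1)
  expect_equal(sort(as.vector(table(f11)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L))

  expect_identical(make_cv2_folds(obs11, seed = 9),
                   make_cv2_folds(obs11, seed = 9))

  gen <- data.frame(genotype = rep(paste0("g", 1:12), each = 3))
  fg <- make_cv2_folds(gen, k = 4, level = "genotype", seed = 2)
  split_count <- tapply(fg, gen$genotype, function(x) length(unique(x)))
  expect_true(all(split_count == 1L))

  expect_error(make_cv2_folds(obs10, k = 11), "exceeds")
})

test_that("predictive ability matches exact and attenuated cases", {
  x <- rnorm(50)
  expect_equal(predictive_ability(x, x)$pooled, 1)
  expect_equal(predictive_ability(-x, x)$pooled, -1)
  set.seed(77)
  o <- rnorm(1000)
  p <- o + rnorm(1000)  # 1:1 signal-to-noise => r ~ 1/sqrt(2)
  expect_equal(predictive_ability(p, o)$pooled, 1 / sqrt(2),
               tolerance = 0.05)
  expect_error(predictive_ability(1:2, 2:3), "at least 3")
  expect_warning(r0 <- predictive_ability(rep(1, 5), rnorm(5))$pooled,
                 "zero variance")
  expect_true(is.na(r0))
  # per-environment breakdown agrees when environments are homogeneous
  env <- rep(c("a", "b"), each = 500)
  pa <- predictive_ability(p, o, env)
  expect_equal(unname(pa$by_environment), rep(pa$pooled, 2),
               tolerance = 0.08)
})

test_that("coincidence index counts top-k overlap with stable ties", {
  x <- rnorm(100)
  expect_equal(coincidence_index(x, x, k = 30), 100)
  expect_equal(coincidence_index(x, -x, k = 30), 0)

  # population 40, k = 30, last 20 observations reversed in the predictions
  set.seed(3)
  obs <- sort(rnorm(40), decreasing = TRUE)
  pred <- obs
  pred[21:40] <- rev(pred[21:40])
  # brute-force set intersection oracle
  top_p <- order(-pred, seq_along(pred))[1:30]
  top_o <- order(-obs, seq_along(obs))[1:30]
  expect_equal(coincidence_index(pred, obs, k = 30),
               100 * length(intersect(top_p, top_o)) / 30)

  # invariance under strictly monotone transforms
  expect_equal(coincidence_index(exp(pred), obs^3 + 5 * obs, k = 30),
               coincidence_index(pred, obs, k = 30))
  expect_error(coincidence_index(x, x, k = 101), "exceeds")
})

test_that("CV2 runs end to end for BLUP and ML engines", {
  pd <- medium_pdata()$pdata
  train <- !pd$is_validation
  obs <- trait_obs(pd, "GY")[train, ]
  ker <- lapply(pd$kernels[c("Gexp", "H")], function(k) {
    kernel(k$K[train, train], labels = k$labels[train],
           level = "observation", name = k$name, check_psd = FALSE)
  })
  cv <- run_cv2(obs, ker, list(G = "Gexp", H = "H"), seed = 1,
                n_iter = 600, burn_in = 150)
  expect_s3_class(cv, "cv_result")
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_true(all(table(cv$folds) >= floor(nrow(obs) / 5)))
  expect_false(anyNA(cv$predictions))
  expect_true(all(cv$pa$pa > -1 & cv$pa$pa < 1))

  cvr <- run_cv2(obs, ker, list(G = "Gexp"), engine = "rfr", seed = 1)
  expect_identical(cvr$level, "genotype")
  expect_false(anyNA(cvr$predictions))
})

test_that("CV0 never trains on the held-out year and counts its fits", {
  pd <- medium_pdata()$pdata
  train <- !pd$is_validation
  obs <- trait_obs(pd, "GY")[train, ]
  ker <- lapply(pd$kernels["Gexp"], function(k) {
    kernel(k$K[train, train], labels = k$labels[train],
           level = "observation", name = k$name, check_psd = FALSE)
  })
  cv <- run_cv0(obs, ker, list(G = "Gexp"), seed = 2,
                n_iter = 400, burn_in = 100)
  # 3 held-out years x 5 rotations x 1 model
  expect_equal(nrow(cv$detail), 15L)
  expect_setequal(unique(cv$detail$year), c("Y1", "Y2", "Y3"))
  expect_equal(nrow(cv$pa), 3L)
  expect_true(all(is.finite(cv$pa$pa_mean)))

  obs2 <- obs[obs$environment != "Y3", ]
  expect_error(run_cv0(obs2, ker, list(G = "Gexp")), "at least 3")
})

test_that("CV0 predicts a new year when G x E is absent and h2 is high", {
  vf <- list(SPI = c(0.9, 0, 0.1), HI = c(0.9, 0, 0.1),
             GY = c(0.9, 0, 0.1), TGW = c(0.9, 0, 0.1),
             BIOMASS = c(0.9, 0, 0.1))
  cfg <- simulation_config(n_genotypes = 60, n_markers = 400,
                           n_validation_genotypes = 0,
                           overlap_fractions = 1,
                           variance_fractions = vf, seed = 17)
  m <- simulate_markers(cfg)
  sim <- simulate_trial(cfg, m)
  pd <- suppressWarnings(build_prediction_data(sim, m, traits = "GY"))
  obs <- trait_obs(pd, "GY")
  cv <- run_cv0(obs, pd$kernels["Gexp"], list(G = "Gexp"),
                years = "Y2", seed = 3, n_iter = 1200, burn_in = 300)
  pa <- cv$detail$pa
  # positive with bootstrap confidence over the 5 rotations
  boot <- replicate(2000, mean(sample(pa, replace = TRUE)))
  expect_gt(stats::quantile(boot, 0.025), 0)
})

test_that("external validation masks the trial and averages fold predictions", {
  pd <- medium_pdata()$pdata
  obs <- trait_obs(pd, "GY")
  res <- run_external(obs, pd$is_validation, pd$kernels,
                      list(G = "Gexp", H = "H"), top_k = 10, seed = 4,
                      n_iter = 600, burn_in = 150)
  # 5 folds x 2 models
  expect_equal(nrow(res$per_fold), 10L)
  expect_equal(nrow(res$predictions), sum(pd$is_validation))
  expect_true(all(res$pa$ci >= 0 & res$pa$ci <= 100))
  # validation genotypes share the training marker-effect vectors, so
  # both engines find signal
  expect_gt(res$pa$pa[res$pa$model == "G"], 0)
  expect_gt(res$pa$pa[res$pa$model == "H"], 0)
})

test_that("pooled PA equals per-environment PA on homogeneous environments", {
  set.seed(5)
  o <- rnorm(300)
  p <- o + rnorm(300, 0, 0.6)
  env <- rep(c("Y1", "Y2", "Y3"), 100)
  pa <- predictive_ability(p, o, env)
  expect_equal(unname(pa$by_environment),
               rep(pa$pooled, 3), tolerance = 0.1)
})
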