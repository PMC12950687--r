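test_that("marker simulation is deterministic and honours its controls", {
  cfg <- simulation_config(n_genotypes = 5, n_markers = 10,
                           n_validation_genotypes = 0, seed = 1)
  m1 <- simulate_markers(cfg)
  m2 <- simulate_markers(cfg)
  expect_identical(m1, m2)

  cfg0 <- simulation_config(n_genotypes = 30, n_markers = 50,
                            n_validation_genotypes = 0,
                            missing_rate = 0, high_missing_frac = 0,
                            seed = 2)
  expect_false(anyNA(simulate_markers(cfg0)))

  expect_error(simulation_config(n_genotypes = 0), "positive")
  expect_error(simulate_markers(
    simulation_config(n_markers = 5, seed = 1)), "n_markers")
  expect_error(
    simulation_config(variance_fractions = list(
      SPI = c(0.6, 0.2, 0.3), HI = c(0.35, 0.1, 0.55),
      GY = c(0.25, 0.2, 0.55), TGW = c(0.4, 0.15, 0.45),
      BIOMASS = c(0.2, 0.2, 0.6))),
    "summing to 1")
})

test_that("simulated MAF spectrum straddles the QC threshold", {
  cfg <- simulation_config(n_genotypes = 200, n_markers = 2000,
                           n_validation_genotypes = 0,
                           maf_range = c(0.02, 0.5), seed = 5)
  m <- simulate_markers(cfg)
  # brute-force per-marker MAF on the generated matrix
  maf <- apply(m, 2, function(x) {
    p <- mean(x, na.rm = TRUE) / 2
    min(p, 1 - p)
  })
  expect_gt(sum(maf < 0.05), 20)
  expect_gt(sum(maf >= 0.05), 1500)
})

test_that("trait identities and positivity hold on every plot", {
  s <- small_sim()
  plots <- s$sim$plots
  lat <- s$sim$truth$latent_biomass
  lat <- lat[match(plots$plot, lat$plot), ]

  expect_true(all(plots$SPI > 0 & plots$SPI < 1))
  expect_true(all(plots$HI > 0 & plots$HI < 1))
  expect_true(all(lat$spike_dw > 0 & lat$biomass_a7 > 0 &
                    lat$biomass_mat > 0 & lat$grain_w > 0 & lat$tgw > 0))
  expect_true(all(lat$spike_dw < lat$biomass_a7))
  expect_true(all(lat$grain_w < lat$biomass_mat))
  # GN * (TGW/1000) = GY and FE = GN / spike dry weight, exactly
  expect_equal(plots$GN * lat$tgw / 1000, plots$GY, tolerance = 1e-12)
  expect_equal(plots$FE, plots$GN / lat$spike_dw, tolerance = 1e-12)
  expect_equal(plots$SPI, lat$spike_dw / lat$biomass_a7,
               tolerance = 1e-12)
  expect_equal(plots$HI, lat$grain_w / lat$biomass_mat,
               tolerance = 1e-12)
})

test_that("trial generation is reproducible for a fixed seed", {
  cfg <- simulation_config(n_genotypes = 25, n_markers = 60,
                           n_validation_genotypes = 10, seed = 11)
  m <- simulate_markers(cfg)
  s1 <- simulate_trial(cfg, m)
  s2 <- simulate_trial(cfg, m)
  expect_identical(s1$plots, s2$plots)
  expect_identical(s1$reflectance, s2$reflectance)
  expect_identical(s1$ec, s2$ec)
})

test_that("realised variance fractions match the request", {
  vf <- list(SPI = c(0.5, 0.2, 0.3), HI = c(0.5, 0.2, 0.3),
             GY = c(0.5, 0.2, 0.3), TGW = c(0.5, 0.2, 0.3),
             BIOMASS = c(0.5, 0.2, 0.3))
  cfg <- simulation_config(n_genotypes = 250, n_markers = 800,
                           n_validation_genotypes = 0,
                           overlap_fractions = 1,
                           variance_fractions = vf, seed = 3)
  m <- simulate_markers(cfg)
  sim <- simulate_trial(cfg, m)
  for (tr in c("SPI", "GY")) {
    expect_true(all(abs(sim$truth$realized_fractions[[tr]] -
                          c(0.5, 0.2, 0.3)) < 0.05))
  }
})

test_that("zero G x E gives consistent rankings across environments", {
  vf <- list(SPI = c(0.95, 0, 0.05), HI = c(0.95, 0, 0.05),
             GY = c(0.95, 0, 0.05), TGW = c(0.95, 0, 0.05),
             BIOMASS = c(0.95, 0, 0.05))
  cfg <- simulation_config(n_genotypes = 120, n_markers = 400,
                           n_validation_genotypes = 0,
                           overlap_fractions = 1,
                           variance_fractions = vf,
                           design_sd_frac = 0, seed = 8)
  m <- simulate_markers(cfg)
  sim <- simulate_trial(cfg, m)
  means <- tapply(sim$plots$GY,
                  sim$plots[, c("genotype", "environment")], mean)
  cors <- cor(means, method = "spearman")
  expect_true(all(cors[upper.tri(cors)] > 0.9))
})

test_that("reflectance carries the configured band loadings", {
  s <- small_sim()
  sim <- s$sim
  refl <- sim$reflectance
  w <- refl_wavelengths(refl)
  # genotype means of GY and of each band within one environment
  env <- "Y1"
  sel <- refl$environment == env
  x <- rowsum(as.matrix(refl[sel, -(1:3)]), refl$genotype[sel])
  x <- x / as.vector(table(refl$genotype[sel])[rownames(x)])
  gy <- tapply(sim$plots$GY[sim$plots$environment == env],
               sim$plots$genotype[sim$plots$environment == env], mean)
  r <- cor(x[names(gy), ], gy)
  nir <- which.min(abs(w - 850))
  red <- which.min(abs(w - 670))
  expect_gt(r[nir], 0)
  expect_lt(r[red], 0)
  # strongest positive association within the NIR bump
  expect_lt(abs(w[which.max(r)] - 850), 40)
})

test_that("the data bundle round-trips through disk", {
  cfg <- simulation_config(n_genotypes = 15, n_markers = 40,
                           n_validation_genotypes = 5, seed = 21)
  m <- simulate_markers(cfg)
  sim <- simulate_trial(cfg, m)
  dir <- withr::local_tempdir()
  write_sim_bundle(sim, m, dir)
  expect_true(file.exists(file.path(dir, "plots.csv")))
  m2 <- read_dosage_tsv(file.path(dir, "dosages.tsv"))
  expect_equal(m2, m)
  rf <- utils::read.csv(file.path(dir, "reflectance.csv"),
                        check.names = FALSE)
  expect_identical(names(rf)[4], sprintf("%.2f", refl_wavelengths(sim$reflectance)[1]))
  # ground truth is a separate bundle
  expect_true(file.exists(file.path(dir, "ground_truth",
                                    "true_genetic_values.csv")))
})
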