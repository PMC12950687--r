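# shared fixtures, generated once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small all-overlap trial without a validation set: fast stage-1 checks
small_sim <- function() {
  cached("small_sim", {
    cfg <- simulation_config(n_genotypes = 60, n_markers = 300,
                             n_validation_genotypes = 0,
                             overlap_fractions = 1, seed = 42)
    m <- simulate_markers(cfg)
    list(config = cfg, markers = m,
         sim = simulate_trial(cfg, m))
  })
}

# medium trial with a validation set and assembled prediction data
medium_pdata <- function() {
  cached("medium_pdata", {
    cfg <- simulation_config(n_genotypes = 80, n_markers = 600,
                             n_validation_genotypes = 40,
                             overlap_fractions = 1, seed = 7)
    m <- simulate_markers(cfg)
    sim <- simulate_trial(cfg, m)
    pd <- suppressWarnings(
      build_prediction_data(sim, m, traits = c("GY", "HI"),
                            include_validation = TRUE))
    list(config = cfg, markers = m, sim = sim, pdata = pd)
  })
}

# toy dosage matrix with hand-crafted QC failures
toy_markers <- function() {
  set.seed(1)
  n <- 20L
  m <- matrix(2 * rbinom(n * 6, 1, 0.4), n, 6,
              dimnames = list(sprintf("g%02d", 1:n), paste0("m", 1:6)))
  m[1:17, 1] <- NA; m[18:20, 1] <- c(0, 2, 2)   # missing 0.85 -> removed
  m[1:16, 2] <- NA; m[17:20, 2] <- c(0, 2, 2, 0) # missing 0.80 -> kept
  m[1:2, 3] <- NA; m[3:20, 3] <- rep(c(0, 2), 9) # missing 0.10 -> kept
  m[, 4] <- 0                                    # monomorphic -> MAF rule
  m[, 5] <- c(rep(1, 3), rep(0, 9), rep(2, 8))   # 15% het, MAF 0.475
  m
}
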