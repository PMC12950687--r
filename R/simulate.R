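#' Configuration for the synthetic multi-environment trial generator
#'
#' The generator emulates a multi-year wheat trial series: several training
#' environments (years) with partially overlapping genotype sets laid out in
#' an alpha-lattice with replicated incomplete blocks, plus one external
#' validation trial of new genotypes drawn from the same marker-effect
#' distribution. Five base traits are simulated directly (SPI, HI, GY, TGW
#' and above-ground biomass at anthesis + 7 days) and the remaining traits
#' follow from their algebraic identities: spike dry weight = SPI x biomass,
#' GN = GY / (TGW/1000), FE = GN / spike dry weight, harvest biomass =
#' GY / HI. Canopy reflectance carries the genetic and genotype-by-
#' environment signal of one trait (GY by default) through smooth red-edge /
#' NIR band loadings, while HI carries no spectral signal.
#'
#' @param n_genotypes training genotype pool size.
#' @param n_markers number of SNP markers.
#' @param n_environments number of training environments (years).
#' @param n_validation_genotypes genotypes in the external validation trial.
#' @param overlap_fractions per-environment fraction of the pool tested in
#'   that environment; sets are nested so environments share their smaller
#'   sets (recycled to `n_environments`).
#' @param replicates replicates per genotype per environment.
#' @param variance_fractions named list, one `c(genotype, gxe, residual)`
#'   triple (summing to 1) per base trait `SPI`, `HI`, `GY`, `TGW`,
#'   `BIOMASS`.
#' @param trait_means,trait_cvs named numeric: base-trait means on the
#'   natural scale and total (g + gxe + residual) coefficients of variation.
#' @param env_sd_frac environment main-effect sd as a fraction of each
#'   trait's total sd.
#' @param gxe_reaction_weight fraction of the G x E variance carried by the
#'   genotype-specific linear reaction to the 1-D environmental index from
#'   the EC table; the remainder is exchangeable marker-driven
#'   per-environment deviation, so the configured G x E fraction matches
#'   the combined-analysis ANOVA estimand.
#' @param design_sd_frac block/row/column effect sd as a fraction of total
#'   sd (each).
#' @param block_size plots per incomplete block.
#' @param spectral_loading_spec data frame with columns `center`, `width`
#'   (nm), `sign` and `weight`: Gaussian band loadings carrying the spectral
#'   signal.
#' @param spectral_signal_trait base trait whose genetic and G x E signal
#'   the spectra load on.
#' @param spectral_g_weight,spectral_gxe_weight weights of the standardised
#'   genetic and G x E signals in the loadings.
#' @param spectral_noise_sd,spectral_ar1 band-noise sd and AR(1) correlation
#'   between adjacent bands.
#' @param n_bands,wavelength_range hyperspectral band count and range (nm).
#' @param ec_weeks number of weekly environmental-covariate records.
#' @param maf_range uniform minor-allele-frequency spectrum for simulated
#'   markers.
#' @param missing_rate,het_rate typical per-marker missing and heterozygous
#'   call rates.
#' @param high_missing_frac,high_het_frac fractions of markers with
#'   elevated missingness (> 0.8) or heterozygosity (0.1-0.3), so the QC
#'   filters have work to do.
#' @param dta_mean,dta_g_sd,dta_env_sd,dta_e_sd days-to-anthesis mean,
#'   marker-driven genetic sd, environment sd and plot residual sd.
#' @param senescence_decay named multipliers applied to the five
#'   multispectral band means at the second timepoint.
#' @param seed integer seed; all generator randomness flows from it.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(
    n_genotypes = 300L, n_markers = 2000L, n_environments = 3L,
    n_validation_genotypes = 120L,
    overlap_fractions = c(0.5, 0.95, 0.95),
    replicates = 2L,
    variance_fractions = list(
      SPI = c(0.20, 0.15, 0.65), HI = c(0.35, 0.10, 0.55),
      GY = c(0.25, 0.20, 0.55), TGW = c(0.40, 0.15, 0.45),
      BIOMASS = c(0.20, 0.20, 0.60)),
    trait_means = c(SPI = 0.345, HI = 0.355, GY = 440, TGW = 28,
                    BIOMASS = 730),
    trait_cvs = c(SPI = 0.10, HI = 0.10, GY = 0.15, TGW = 0.08,
                  BIOMASS = 0.12),
    env_sd_frac = 0.75, design_sd_frac = 0.05, block_size = 20L,
    gxe_reaction_weight = 0.25,
    spectral_loading_spec = data.frame(
      center = c(670, 720, 850), width = c(30, 20, 40),
      sign = c(-1, 1, 1), weight = c(0.015, 0.020, 0.030)),
    spectral_signal_trait = "GY",
    spectral_g_weight = 1, spectral_gxe_weight = 1,
    spectral_noise_sd = 0.008, spectral_ar1 = 0.9,
    n_bands = 273L, wavelength_range = c(398.47, 1000.58),
    ec_weeks = 20L,
    maf_range = c(0.02, 0.5), missing_rate = 0.02, het_rate = 0.01,
    high_missing_frac = 0.03, high_het_frac = 0.03,
    dta_mean = 110, dta_g_sd = 2.5, dta_env_sd = 2, dta_e_sd = 1,
    senescence_decay = c(Blue = 1.0, Green = 0.95, Red = 1.3,
                         RedEdge = 0.9, NIR = 0.8),
    seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_genotypes, n_markers, n_environments, replicates)
  if (any(counts <= 0)) stop("configuration error: counts must be positive")
  if (n_validation_genotypes < 0) {
    stop("configuration error: n_validation_genotypes must be >= 0")
  }
  cfg$overlap_fractions <- rep_len(overlap_fractions, n_environments)
  if (any(cfg$overlap_fractions < 0 | cfg$overlap_fractions > 1)) {
    stop("configuration error: overlap fractions must lie in [0, 1]")
  }
  for (tr in names(variance_fractions)) {
    v <- variance_fractions[[tr]]
    if (length(v) != 3L || any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop("configuration error: variance fractions for ", tr,
           " must be 3 nonnegative values summing to 1")
    }
  }
  needed <- c("SPI", "HI", "GY", "TGW", "BIOMASS")
  if (!all(needed %in% names(variance_fractions)) ||
      !all(needed %in% names(trait_means)) ||
      !all(needed %in% names(trait_cvs))) {
    stop("configuration error: variance_fractions, trait_means and ",
         "trait_cvs must cover ", paste(needed, collapse = ", "))
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Simulate a SNP dosage matrix
#'
#' Markers are drawn for the training pool plus the validation genotypes
#' (row ids `G...` and `V...`). Per-marker allele frequencies come from a
#' uniform spectrum spanning both sides of the usual MAF filter threshold;
#' lines are close to fully inbred (dosage 0/2) with a small heterozygous
#' call rate, and configurable fractions of markers carry elevated
#' missingness or heterozygosity so the QC rules are exercised.
#'
#' @param config a [simulation_config()].
#' @return dosage matrix with `NA` for missing calls.
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_markers < 10L) {
    stop("configuration error: n_markers must be >= 10")
  }
  set.seed(config$seed)
  n <- config$n_genotypes + config$n_validation_genotypes
  p <- stats::runif(config$n_markers, config$maf_range[1],
                    config$maf_range[2])
  m <- matrix(2 * stats::rbinom(n * config$n_markers, 1L,
                                rep(p, each = n)),
              nrow = n, ncol = config$n_markers)
  # heterozygous calls: per-marker rate, a few markers strongly elevated
  het_rate <- rep(config$het_rate, config$n_markers)
  hi_het <- stats::runif(config$n_markers) < config$high_het_frac
  het_rate[hi_het] <- stats::runif(sum(hi_het), 0.12, 0.30)
  if (any(het_rate > 0)) {
    het_mask <- matrix(stats::runif(n * config$n_markers) <
                         rep(het_rate, each = n), n)
    m[het_mask] <- 1L
  }
  miss_rate <- rep(config$missing_rate, config$n_markers)
  hi_miss <- stats::runif(config$n_markers) < config$high_missing_frac
  miss_rate[hi_miss] <- stats::runif(sum(hi_miss), 0.82, 0.95)
  if (any(miss_rate > 0)) {
    miss_mask <- matrix(stats::runif(n * config$n_markers) <
                          rep(miss_rate, each = n), n)
    m[miss_mask] <- NA
  }
  rownames(m) <- c(sprintf("G%04d", seq_len(config$n_genotypes)),
                   if (config$n_validation_genotypes > 0)
                     sprintf("V%04d",
                             seq_len(config$n_validation_genotypes)))
  colnames(m) <- sprintf("M%05d", seq_len(config$n_markers))
  storage.mode(m) <- "double"
  m
}

# smooth green-vegetation baseline reflectance
refl_baseline <- function(lambda) {
  0.04 + 0.06 * exp(-((lambda - 555) / 25)^2) +
    0.40 * stats::plogis((lambda - 715) / 18)
}

# weekly environmental covariates for one environment (11 ECs)
sim_ec_env <- function(weeks, env_shift) {
  t <- seq_len(weeks) / weeks
  tmean <- 12 + 10 * t + 3 * sin(2 * pi * t) + env_shift[1] +
    stats::rnorm(weeks, 0, 0.8)
  tmin <- tmean - 6 + stats::rnorm(weeks, 0, 0.5)
  tmax <- tmean + 7 + stats::rnorm(weeks, 0, 0.5)
  trange <- tmax - tmin
  rh <- 75 - 10 * t + env_shift[2] + stats::rnorm(weeks, 0, 2)
  rain <- pmax(0, stats::rnorm(weeks, 18 - 10 * t + env_shift[3], 8))
  rain[c(3L, 15L)[c(3L, 15L) <= weeks]] <- 0  # region-wide dry weeks
  srad <- 12 + 8 * t + env_shift[4] + stats::rnorm(weeks, 0, 0.7)
  wind <- pmax(0.2, 2.5 + env_shift[5] + stats::rnorm(weeks, 0, 0.4))
  et0 <- pmax(0.2, 2 + 3 * t + env_shift[6] + stats::rnorm(weeks, 0, 0.3))
  gdd <- pmax(0, tmean - 4) * 7
  vpd <- pmax(0.05, 0.12 * tmean * (1 - rh / 100) +
                stats::rnorm(weeks, 0, 0.05))
  ecs <- cbind(tmin = tmin, tmax = tmax, tmean = tmean, trange = trange,
               rhum = rh, rain = rain, srad = srad, wind = wind,
               et0 = et0, gdd = gdd, vpd = vpd)
  as.vector(ecs)  # stacked: EC-major, week within EC
}

ec_col_names <- function(weeks) {
  ecs <- c("tmin", "tmax", "tmean", "trange", "rhum", "rain", "srad",
           "wind", "et0", "gdd", "vpd")
  as.vector(vapply(ecs, function(e) sprintf("%s_w%02d", e, seq_len(weeks)),
                   character(weeks)))
}

# alpha-lattice layout for one environment: replicates, incomplete blocks,
# rows and columns nested in block
layout_env <- function(env, genotypes, replicates, block_size) {
  out <- list()
  for (r in seq_len(replicates)) {
    g <- sample(genotypes)
    n <- length(g)
    pos <- seq_len(n)
    blk <- ceiling(pos / block_size)
    half <- ceiling(block_size / 2)
    row_in_blk <- ceiling((pos - (blk - 1) * block_size) / half)
    col_in_blk <- pos - (blk - 1) * block_size - (row_in_blk - 1) * half
    out[[r]] <- data.frame(
      environment = env, genotype = g, replicate = r,
      block = sprintf("%s_R%d_B%02d", env, r, blk),
      row = sprintf("%s_R%d_B%02d_r%d", env, r, blk, row_in_blk),
      col = sprintf("%s_R%d_B%02d_c%d", env, r, blk, col_in_blk),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$plot <- sprintf("%s_P%04d", env, seq_len(nrow(res)))
  res
}

#' Simulate a multi-environment trial with ground truth
#'
#' Generates plot-level phenotypes, hyperspectral reflectance,
#' multispectral band means and vegetation indices, an environment x weekly
#' environmental-covariate matrix, and an external validation trial, all
#' with known genetic, G x E and environmental effects. Genetic values are
#' marker-driven (g = M alpha, rescaled so realised variance fractions meet
#' the configured ones); G x E arises as genotype-specific linear reactions
#' to a one-dimensional environmental index computed from the EC matrix;
#' validation genotypes share the training marker-effect vectors.
#'
#' @param config a [simulation_config()].
#' @param markers dosage matrix from [simulate_markers()] (may contain
#'   missing calls; genetic values use mean-imputed dosages).
#' @return object of class `sim_trial`: list with elements `plots`,
#'   `reflectance`, `msi`, `vi`, `ec`, `validation` (same tables for the
#'   validation trial), `truth` and `config`.
#' @export
simulate_trial <- function(config, markers) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_g <- config$n_genotypes
  n_v <- config$n_validation_genotypes
  envs <- sprintf("Y%d", seq_len(config$n_environments))
  all_envs <- c(envs, if (n_v > 0) "VAL")
  geno_train <- rownames(markers)[seq_len(n_g)]
  geno_val <- if (n_v > 0) rownames(markers)[n_g + seq_len(n_v)]

  # ---- environmental covariates and environmental index ----
  ec <- t(vapply(seq_along(all_envs), function(j) {
    sim_ec_env(config$ec_weeks, stats::rnorm(6, 0, c(2, 4, 6, 1.5, 0.6, 0.5)))
  }, numeric(11L * config$ec_weeks)))
  dimnames(ec) <- list(all_envs, ec_col_names(config$ec_weeks))
  ec_sd <- apply(ec, 2L, pop_sd)
  informative <- ec_sd > .Machine$double.eps
  if (length(all_envs) >= 2L && any(informative)) {
    ec_z <- scale(ec[, informative, drop = FALSE])
    env_index <- rowMeans(ec_z)
    env_index <- (env_index - mean(env_index)) /
      max(pop_sd(env_index), .Machine$double.eps)
  } else {
    # a single environment carries no environmental gradient
    env_index <- rep(0, length(all_envs))
  }

  # ---- genetic and G x E effects from markers ----
  md <- impute_mean(markers)
  mc <- sweep(md, 2L, colMeans(md[seq_len(n_g), , drop = FALSE]), "-")
  traits <- c("SPI", "HI", "GY", "TGW", "BIOMASS")
  g_mat <- matrix(0, nrow(markers), length(traits),
                  dimnames = list(rownames(markers), traits))
  ge_arr <- array(0, c(nrow(markers), length(all_envs), length(traits)),
                  dimnames = list(rownames(markers), all_envs, traits))
  env_eff <- matrix(0, length(all_envs), length(traits),
                    dimnames = list(all_envs, traits))
  sd_tot <- config$trait_means[traits] * config$trait_cvs[traits]
  sd_e <- numeric(length(traits)); names(sd_e) <- traits
  for (tr in traits) {
    fr <- config$variance_fractions[[tr]]
    a <- stats::rnorm(ncol(mc))
    g_raw <- as.vector(mc %*% a)
    g_train <- g_raw[seq_len(n_g)]
    sg <- pop_sd(g_train)
    g_mat[, tr] <- (g_raw - mean(g_train)) / max(sg, 1e-12) *
      sqrt(fr[1]) * sd_tot[tr]
    # G x E: blend of a linear reaction to the environmental index and
    # exchangeable marker-driven per-environment deviations
    wrn <- config$gxe_reaction_weight
    b_raw <- as.vector(mc %*% stats::rnorm(ncol(mc)))
    b_raw <- (b_raw - mean(b_raw[seq_len(n_g)])) /
      max(pop_sd(b_raw[seq_len(n_g)]), 1e-12)
    ge_rn <- outer(b_raw, env_index)
    dev <- mc %*% matrix(stats::rnorm(ncol(mc) * length(all_envs)),
                         ncol(mc))
    dev <- sweep(dev, 2L, colMeans(dev[seq_len(n_g), , drop = FALSE]), "-")
    dev_sd <- apply(dev[seq_len(n_g), , drop = FALSE], 2L, pop_sd)
    dev <- sweep(dev, 2L, pmax(dev_sd, 1e-12), "/")
    ge_raw <- sqrt(wrn) * ge_rn + sqrt(1 - wrn) * dev
    s_ge <- pop_sd(as.vector(ge_raw[seq_len(n_g),
                                    seq_along(envs), drop = FALSE]))
    scale_ge <- if (fr[2] > 0 && s_ge > 1e-12) {
      sqrt(fr[2]) * sd_tot[tr] / s_ge
    } else 0
    ge_arr[, , tr] <- ge_raw * scale_ge
    env_eff[, tr] <- stats::rnorm(length(all_envs), 0,
                                  config$env_sd_frac * sd_tot[tr])
    sd_e[tr] <- sqrt(fr[3]) * sd_tot[tr]
  }
  g_dta_raw <- as.vector(mc %*% stats::rnorm(ncol(mc)))
  g_dta <- (g_dta_raw - mean(g_dta_raw[seq_len(n_g)])) /
    max(pop_sd(g_dta_raw[seq_len(n_g)]), 1e-12) * config$dta_g_sd
  dta_env <- stats::rnorm(length(all_envs), 0, config$dta_env_sd)
  names(dta_env) <- all_envs

  # ---- plot layouts ----
  env_sets <- lapply(seq_along(envs), function(j) {
    geno_train[seq_len(max(2L, round(config$overlap_fractions[j] * n_g)))]
  })
  layouts <- mapply(layout_env, envs, env_sets,
                    MoreArgs = list(replicates = config$replicates,
                                    block_size = config$block_size),
                    SIMPLIFY = FALSE)
  plots <- do.call(rbind, layouts)
  if (n_v > 0) {
    val_plots <- layout_env("VAL", geno_val, config$replicates,
                            config$block_size)
    plots <- rbind(plots, val_plots)
  }
  rownames(plots) <- NULL

  # design nuisance effects, one draw per label, scaled per trait later
  design_z <- list()
  for (f in c("block", "row", "col")) {
    lv <- unique(plots[[f]])
    z <- stats::rnorm(length(lv)); names(z) <- lv
    design_z[[f]] <- z[plots[[f]]]
  }

  # ---- plot-level base traits and identities ----
  i_g <- match(plots$genotype, rownames(markers))
  i_e <- match(plots$environment, all_envs)
  n_plots <- nrow(plots)
  base <- matrix(0, n_plots, length(traits), dimnames = list(NULL, traits))
  resid_draws <- matrix(0, n_plots, length(traits),
                        dimnames = list(NULL, traits))
  for (tr in traits) {
    resid_draws[, tr] <- stats::rnorm(n_plots, 0, sd_e[tr])
    design <- (design_z$block + design_z$row + design_z$col) *
      config$design_sd_frac * sd_tot[tr]
    base[, tr] <- config$trait_means[tr] + env_eff[i_e, tr] +
      g_mat[i_g, tr] + ge_arr[cbind(i_g, i_e, match(tr, traits))] +
      design + resid_draws[, tr]
  }
  base[, "SPI"] <- pmin(pmax(base[, "SPI"], 0.02), 0.98)
  base[, "HI"] <- pmin(pmax(base[, "HI"], 0.02), 0.98)
  for (tr in c("GY", "TGW", "BIOMASS")) {
    base[, tr] <- pmax(base[, tr], 0.02 * config$trait_means[tr])
  }
  spike_dw <- base[, "SPI"] * base[, "BIOMASS"]
  biomass_mat <- base[, "GY"] / base[, "HI"]
  gn <- base[, "GY"] / (base[, "TGW"] / 1000)
  fe <- gn / spike_dw
  plots$DTA <- round(config$dta_mean + g_dta[i_g] + dta_env[i_e] +
                       stats::rnorm(n_plots, 0, config$dta_e_sd), 1)
  plots$SPI <- base[, "SPI"]
  plots$HI <- base[, "HI"]
  plots$FE <- fe
  plots$GN <- gn
  plots$GY <- base[, "GY"]

  # ---- hyperspectral reflectance ----
  lambda <- seq(config$wavelength_range[1], config$wavelength_range[2],
                length.out = config$n_bands)
  sig_tr <- config$spectral_signal_trait
  zg <- g_mat[, sig_tr] / max(pop_sd(g_mat[seq_len(n_g), sig_tr]), 1e-12)
  ge_sig <- matrix(ge_arr[, , sig_tr], nrow = nrow(markers),
                   dimnames = dimnames(ge_arr)[1:2])
  s_ge_sig <- pop_sd(as.vector(ge_sig[seq_len(n_g), seq_along(envs)]))
  zge <- if (s_ge_sig > 1e-12) ge_sig / s_ge_sig else ge_sig * 0
  signal <- config$spectral_g_weight * zg[i_g] +
    config$spectral_gxe_weight * zge[cbind(i_g, i_e)]
  loading <- rep(0, config$n_bands)
  for (b in seq_len(nrow(config$spectral_loading_spec))) {
    sp <- config$spectral_loading_spec[b, ]
    loading <- loading +
      sp$sign * sp$weight * exp(-0.5 * ((lambda - sp$center) / sp$width)^2)
  }
  env_shift <- stats::rnorm(length(all_envs), 0, 0.01)
  refl <- matrix(rep(refl_baseline(lambda), each = n_plots), n_plots) +
    outer(signal, loading) + env_shift[i_e]
  # AR(1) noise across adjacent bands (smooth sensor noise)
  rho <- config$spectral_ar1; sdn <- config$spectral_noise_sd
  noise <- matrix(0, n_plots, config$n_bands)
  noise[, 1L] <- stats::rnorm(n_plots, 0, sdn)
  for (k in 2L:config$n_bands) {
    noise[, k] <- rho * noise[, k - 1L] +
      sqrt(1 - rho^2) * stats::rnorm(n_plots, 0, sdn)
  }
  refl <- pmax(refl + noise, 1e-4)
  colnames(refl) <- sprintf("%.2f", lambda)
  reflectance <- cbind(plots[, c("genotype", "environment", "plot")],
                       as.data.frame(refl))

  # ---- multispectral band means (two timepoints) and VIs ----
  msi1 <- msi_from_hyperspectral(reflectance)
  bands5 <- c("Blue", "Green", "Red", "RedEdge", "NIR")
  msi2 <- msi1
  for (b in bands5) {
    msi2[[b]] <- pmax(msi1[[b]] * config$senescence_decay[[b]] +
                        stats::rnorm(n_plots, 0, 0.003), 1e-4)
  }
  names(msi1)[match(bands5, names(msi1))] <- paste0(bands5, "_t1")
  names(msi2)[match(bands5, names(msi2))] <- paste0(bands5, "_t2")
  msi <- cbind(msi1, msi2[, paste0(bands5, "_t2")])
  vi1 <- compute_vis(msi$Blue_t1, msi$Red_t1, msi$NIR_t1)
  vi2 <- compute_vis(msi$Blue_t2, msi$Red_t2, msi$NIR_t2)
  vi <- cbind(plots[, c("genotype", "environment", "plot")],
              data.frame(NDVI1 = vi1$NDVI, EVI1 = vi1$EVI,
                         NDVI2 = vi2$NDVI, EVI2 = vi2$EVI))

  # ---- ground truth ----
  gv <- g_mat
  tg <- config$trait_means
  gv_lvl <- sweep(g_mat, 2L, tg[colnames(g_mat)], "+")
  gn_g <- gv_lvl[, "GY"] / (gv_lvl[, "TGW"] / 1000)
  fe_g <- gn_g / (gv_lvl[, "SPI"] * gv_lvl[, "BIOMASS"])
  true_gen <- cbind(gv, GN = gn_g - mean(gn_g[seq_len(n_g)]),
                    FE = fe_g - mean(fe_g[seq_len(n_g)]))
  realized <- lapply(traits, function(tr) {
    vg <- pop_sd(g_mat[seq_len(n_g), tr])^2
    vge <- pop_sd(as.vector(ge_arr[seq_len(n_g), seq_along(envs), tr]))^2
    ve <- pop_sd(resid_draws[, tr])^2
    c(genotype = vg, gxe = vge, residual = ve) / (vg + vge + ve)
  })
  names(realized) <- traits
  truth <- list(
    true_genetic_values = true_gen,
    true_gxe_values = ge_arr,
    true_env_effects = env_eff,
    latent_biomass = data.frame(
      plots[, c("environment", "genotype", "plot")],
      spike_dw = spike_dw, biomass_a7 = base[, "BIOMASS"],
      biomass_mat = biomass_mat, grain_w = base[, "GY"],
      tgw = base[, "TGW"]),
    env_index = env_index,
    realized_fractions = realized)

  is_val <- plots$environment == "VAL"
  split_tabs <- function(df) list(train = df[!is_val, , drop = FALSE],
                                  val = df[is_val, , drop = FALSE])
  pt <- split_tabs(plots); rf <- split_tabs(reflectance)
  ms <- split_tabs(msi); vt <- split_tabs(vi)
  validation <- if (n_v > 0) {
    list(plots = pt$val, reflectance = rf$val, msi = ms$val, vi = vt$val)
  }
  structure(list(plots = pt$train, reflectance = rf$train, msi = ms$train,
                 vi = vt$train, ec = ec, validation = validation,
                 truth = truth, config = config),
            class = "sim_trial")
}

#' @exportS3Method print sim_trial
print.sim_trial <- function(x, ...) {
  cat("Synthetic multi-environment trial\n")
  cat(sprintf("  %d training plots in %d environment(s); %d genotypes\n",
              nrow(x$plots), length(unique(x$plots$environment)),
              length(unique(x$plots$genotype))))
  if (!is.null(x$validation)) {
    cat(sprintf("  validation trial: %d plots, %d genotypes\n",
                nrow(x$validation$plots),
                length(unique(x$validation$plots$genotype))))
  }
  invisible(x)
}

#' Write all generated tables of a synthetic trial to disk
#'
#' Dosages as TSV, plot/VI/MSI/reflectance tables as CSV (the reflectance
#' header is the wavelength in nm at two decimals), the EC matrix as CSV,
#' and ground truth as a separate CSV bundle that the analysis stages never
#' read.
#'
#' @param sim a `sim_trial` from [simulate_trial()].
#' @param markers dosage matrix used to build the trial.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_sim_bundle <- function(sim, markers, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth_dir <- file.path(dir, "ground_truth")
  dir.create(truth_dir, showWarnings = FALSE)
  w <- function(df, f) {
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
    file.path(dir, f)
  }
  files <- c(
    write_dosage_tsv(markers, file.path(dir, "dosages.tsv")),
    w(sim$plots, "plots.csv"), w(sim$reflectance, "reflectance.csv"),
    w(sim$msi, "msi.csv"), w(sim$vi, "vi.csv"),
    w(data.frame(environment = rownames(sim$ec), sim$ec,
                 check.names = FALSE), "ec.csv"))
  if (!is.null(sim$validation)) {
    files <- c(files,
               w(sim$validation$plots, "validation_plots.csv"),
               w(sim$validation$reflectance, "validation_reflectance.csv"),
               w(sim$validation$msi, "validation_msi.csv"),
               w(sim$validation$vi, "validation_vi.csv"))
  }
  tg <- sim$truth
  utils::write.csv(data.frame(genotype = rownames(tg$true_genetic_values),
                              tg$true_genetic_values),
                   file.path(truth_dir, "true_genetic_values.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(environment = rownames(tg$true_env_effects),
                              tg$true_env_effects),
                   file.path(truth_dir, "true_env_effects.csv"),
                   row.names = FALSE)
  utils::write.csv(tg$latent_biomass,
                   file.path(truth_dir, "latent_biomass.csv"),
                   row.names = FALSE)
  invisible(files)
}
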