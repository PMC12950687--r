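#' Assemble prediction inputs from trial tables
#'
#' Convenience layer running the standard pre-modelling pipeline: marker QC
#' and imputation, the VanRaden G matrix, L2 normalisation and per-band
#' adjusted means for the hyperspectral kernel H, vegetation-index adjusted
#' means for V, the environmental-covariate kernel W, kernel expansion to
#' observation level and the Hadamard interaction GW, plus per-environment
#' trait BLUEs as the response.
#'
#' @param sim a `sim_trial` from [simulate_trial()] (or a list with the
#'   same table layout).
#' @param markers dosage matrix covering every genotype in the trial.
#' @param traits trait columns to adjust (default the five biomass-
#'   partitioning traits).
#' @param include_validation append the external validation trial's
#'   observations (their BLUEs are carried for evaluation, never for
#'   training).
#' @param use_dta_covariate adjust trait and spectral means for days to
#'   anthesis.
#' @param qc apply [filter_markers()] before building G.
#' @return list: `obs` (data frame `genotype`, `environment`, one response
#'   column per trait), `is_validation`, `kernels` (named list `Gexp`,
#'   `H`, `V`, `Wexp`, `GW` at observation level), `qc_report`, `blues`.
#' @export
build_prediction_data <- function(sim, markers, traits = c("SPI", "HI",
                                    "FE", "GN", "GY"),
                                  include_validation = FALSE,
                                  use_dta_covariate = TRUE, qc = TRUE) {
  plots <- sim$plots
  refl <- sim$reflectance
  vi <- sim$vi
  if (include_validation && !is.null(sim$validation)) {
    plots <- rbind(plots, sim$validation$plots)
    refl <- rbind(refl, sim$validation$reflectance)
    vi <- rbind(vi, sim$validation$vi)
  }

  # response: per-environment BLUEs for each trait
  blues <- do.call(rbind, lapply(traits, function(tr) {
    blues_per_environment(plots, tr, use_dta_covariate = use_dta_covariate)
  }))
  wide <- adjusted_means_wide(blues)
  obs <- wide[order(wide$environment, wide$genotype), , drop = FALSE]
  rownames(obs) <- NULL
  okey <- obs_key(obs$genotype, obs$environment)

  # genomic kernel
  qc_report <- NULL
  m <- markers[unique(plots$genotype), , drop = FALSE]
  if (qc) {
    f <- filter_markers(m)
    m <- f$markers
    qc_report <- f$report
  }
  g <- vanraden_g(impute_mean(m))
  g_exp <- expand_kernel(g, obs)

  # hyperspectral kernel: L2-normalise, adjust per band, combine over envs
  dta <- plots[, c("plot", "DTA")]
  rn <- l2_normalize(refl)
  rn <- merge(rn, dta, by = "plot", sort = FALSE)
  band_cols <- setdiff(names(rn), c("genotype", "environment", "plot",
                                    "DTA"))
  band_adj <- adjust_means_ols(rn, band_cols,
                               use_dta_covariate = use_dta_covariate)
  rownames(band_adj) <- obs_key(band_adj$genotype, band_adj$environment)
  h <- linear_kernel(as.matrix(band_adj[okey, band_cols, drop = FALSE]),
                     labels = okey, level = "observation", name = "H")

  # vegetation-index kernel
  vin <- merge(vi, dta, by = "plot", sort = FALSE)
  vi_cols <- c("NDVI1", "EVI1", "NDVI2", "EVI2")
  vi_adj <- adjust_means_ols(vin, vi_cols,
                             use_dta_covariate = use_dta_covariate)
  rownames(vi_adj) <- obs_key(vi_adj$genotype, vi_adj$environment)
  v <- linear_kernel(as.matrix(vi_adj[okey, vi_cols, drop = FALSE]),
                     labels = okey, level = "observation", name = "V")

  # environmental-covariate kernel and the Hadamard interaction
  w <- linear_kernel(sim$ec, labels = rownames(sim$ec),
                     level = "environment", name = "W")
  w_exp <- expand_kernel(w, obs)
  gw <- interaction_kernel(g_exp, w_exp)

  is_val <- obs$environment == "VAL"
  list(obs = obs, is_validation = is_val,
       kernels = list(Gexp = g_exp, H = h, V = v, Wexp = w_exp, GW = gw),
       qc_report = qc_report, blues = blues)
}

#' Standard model list of the prediction study
#'
#' Single-kernel genomic (G) and hyperspectral (H) models plus the full
#' multi-omic model combining genomic, hyperspectral, vegetation-index,
#' environmental and interaction kernels.
#' @return named list mapping model names to kernel-name vectors.
#' @export
standard_models <- function() {
  list(G = "Gexp", H = "H",
       `G+H+V+W+GW` = c("Gexp", "H", "V", "Wexp", "GW"))
}

#' Response vector for one trait from assembled prediction data
#'
#' @param data result of [build_prediction_data()].
#' @param trait trait name.
#' @return data frame `genotype`, `environment`, `y` aligned with the
#'   kernels in `data`.
#' @export
trait_obs <- function(data, trait) {
  stopifnot(trait %in% names(data$obs))
  data.frame(genotype = data$obs$genotype,
             environment = data$obs$environment,
             y = data$obs[[trait]], stringsAsFactors = FALSE)
}
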