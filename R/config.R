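#' Reproducible end-to-end runs from a configuration file
#'
#' A run configuration is a YAML file (or equivalent list) with blocks:
#' `paths` (`data_dir`, `results_dir`), `simulation` (arguments of
#' [simulation_config()]), `kernels` (kernel names to build, default all),
#' `models` (named model -> kernel-name vectors, default
#' [standard_models()]), `traits`, `cv` (named blocks `cv2`, `cv0`,
#' `external` with their options), `sampler` (`n_iter`, `burn_in`, ...)
#' and `seed`. [cmd_simulate()] writes the synthetic data bundle plus a
#' manifest; [cmd_run()] executes QC, spectral processing, adjustment,
#' kernel building, model fitting and validation, caching the assembled
#' prediction data keyed by a content hash of its inputs.
#'
#' @name cli_config
NULL

#' Read and validate a run configuration
#'
#' @param path YAML file path, or a list already in memory.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  for (field in c("paths", "seed")) {
    if (is.null(cfg[[field]])) {
      stop("run configuration is missing required field '", field, "'")
    }
  }
  for (field in c("data_dir", "results_dir")) {
    if (is.null(cfg$paths[[field]])) {
      stop("run configuration is missing required field 'paths$",
           field, "'")
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$traits)) cfg$traits <- c("SPI", "HI", "FE", "GN", "GY")
  if (is.null(cfg$kernels)) {
    cfg$kernels <- c("Gexp", "H", "V", "Wexp", "GW")
  }
  if (is.null(cfg$models)) cfg$models <- standard_models()
  cfg$models <- lapply(cfg$models, unlist)
  for (m in names(cfg$models)) {
    terms <- cfg$models[[m]]
    missing_k <- setdiff(terms, cfg$kernels)
    if (length(missing_k)) {
      stop("model '", m, "' requests kernel(s) not configured: ",
           paste(missing_k, collapse = ", "))
    }
    if ("GW" %in% terms && !"Wexp" %in% cfg$kernels) {
      stop("model '", m, "' requests GW without the W kernel")
    }
  }
  if (is.null(cfg$sampler)) cfg$sampler <- list()
  structure(cfg, class = "run_config")
}

.manifest_path <- function(dir) file.path(dir, "manifest.json")

.bundle_manifest <- function(dir, seed, extra = list()) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        "manifest.json"))
  hashes <- as.vector(tools::md5sum(file.path(dir, files)))
  c(list(seed = seed,
         package_version = as.character(utils::packageVersion("kernpred")),
         files = stats::setNames(as.list(hashes), files)),
    extra)
}

#' Generate and write the synthetic data bundle
#'
#' @param config a `run_config` (or path to one).
#' @param overwrite allow writing into a non-empty data directory.
#' @return invisibly, the manifest list.
#' @export
cmd_simulate <- function(config, overwrite = FALSE) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  dir <- cfg$paths$data_dir
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    stop("data directory '", dir, "' exists; pass overwrite = TRUE")
  }
  sim_args <- if (is.null(cfg$simulation)) list() else cfg$simulation
  sim_args$seed <- cfg$seed
  scfg <- do.call(simulation_config, sim_args)
  markers <- simulate_markers(scfg)
  sim <- simulate_trial(scfg, markers)
  write_sim_bundle(sim, markers, dir)
  manifest <- .bundle_manifest(dir, cfg$seed)
  jsonlite::write_json(manifest, .manifest_path(dir), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

.read_sim_bundle <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE)
  ec_df <- rd("ec.csv")
  ec <- as.matrix(ec_df[, -1L, drop = FALSE])
  rownames(ec) <- ec_df[[1L]]
  has_val <- file.exists(file.path(dir, "validation_plots.csv"))
  list(markers = read_dosage_tsv(file.path(dir, "dosages.tsv")),
       plots = rd("plots.csv"), reflectance = rd("reflectance.csv"),
       vi = rd("vi.csv"), msi = rd("msi.csv"), ec = ec,
       validation = if (has_val) list(
         plots = rd("validation_plots.csv"),
         reflectance = rd("validation_reflectance.csv"),
         vi = rd("validation_vi.csv"),
         msi = rd("validation_msi.csv")))
}

#' Execute the configured analysis pipeline
#'
#' Reads the data bundle, assembles kernels and BLUEs (cached by a content
#' hash of the bundle manifest and the relevant configuration), runs the
#' configured cross-validation schemes for each trait and model, and
#' writes CVResult CSV/JSON files plus a run manifest into the results
#' directory.
#'
#' @param config a `run_config` (or path to one).
#' @return invisibly, a named list of `cv_result` objects
#'   (`<scheme>.<trait>`).
#' @export
cmd_run <- function(config) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  dir <- cfg$paths$data_dir
  if (!dir.exists(dir) || !file.exists(.manifest_path(dir))) {
    stop("data bundle not found in '", dir, "'; run cmd_simulate() first")
  }
  res_dir <- cfg$paths$results_dir
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  schemes <- if (is.null(cfg$cv)) list(cv2 = list()) else cfg$cv
  if (!is.null(schemes$cv0)) {
    n_env <- length(setdiff(
      unique(utils::read.csv(file.path(dir, "plots.csv"))$environment),
      "VAL"))
    if (n_env < 3L) {
      stop("CV0 requires at least 3 environments; the bundle has ", n_env)
    }
  }

  # stage: assemble prediction data (cached by content hash)
  bundle_manifest <- jsonlite::read_json(.manifest_path(dir))
  stage_key <- .content_key(list(files = bundle_manifest$files,
                                 traits = cfg$traits,
                                 kernels = cfg$kernels,
                                 external = !is.null(schemes$external)))
  cache_file <- file.path(res_dir, "prediction_data.rds")
  key_file <- file.path(res_dir, "prediction_data.key")
  if (file.exists(cache_file) && file.exists(key_file) &&
      identical(readLines(key_file, warn = FALSE), stage_key)) {
    message("stage 'prediction data': cached")
    pdata <- readRDS(cache_file)
  } else {
    sim <- .read_sim_bundle(dir)
    pdata <- build_prediction_data(
      sim, sim$markers, traits = cfg$traits,
      include_validation = !is.null(schemes$external))
    saveRDS(pdata, cache_file)
    writeLines(stage_key, key_file)
    message(sprintf(
      "stage 'prediction data': %d observations, kernels %s",
      nrow(pdata$obs), paste(names(pdata$kernels), collapse = ", ")))
  }
  kernels <- pdata$kernels[intersect(cfg$kernels, names(pdata$kernels))]

  sampler <- cfg$sampler
  results <- list()
  for (tr in cfg$traits) {
    obs_all <- trait_obs(pdata, tr)
    train <- !pdata$is_validation
    obs <- obs_all[train, , drop = FALSE]
    ksub <- lapply(kernels, function(k) {
      kernel(k$K[train, train, drop = FALSE],
             labels = k$labels[train], level = "observation",
             name = k$name, q = k$q, check_psd = FALSE)
    })
    for (sc in names(schemes)) {
      opts <- schemes[[sc]]
      args <- c(list(kernels = if (sc == "external") kernels else ksub,
                     models = cfg$models,
                     seed = cfg$seed),
                sampler,
                opts[setdiff(names(opts), "top_k")])
      res <- switch(
        sc,
        cv2 = do.call(run_cv2, c(list(obs = obs), args)),
        cv0 = do.call(run_cv0, c(list(obs = obs), args)),
        external = do.call(run_external, c(
          list(obs = obs_all, is_validation = pdata$is_validation,
               top_k = if (is.null(opts$top_k)) 30L else opts$top_k),
          args)),
        stop("unknown cv scheme '", sc, "'"))
      tag <- paste(sc, tr, sep = ".")
      results[[tag]] <- res
      write_cv_result(res, file.path(res_dir,
                                     paste0("cvresult_", sc, "_", tr,
                                            ".csv")))
      message(sprintf("stage '%s' / %s: done (%d model(s))", sc, tr,
                      nrow(res$pa)))
    }
  }
  run_manifest <- list(seed = cfg$seed, traits = cfg$traits,
                       models = lapply(cfg$models, as.list),
                       schemes = names(schemes),
                       data_manifest = bundle_manifest$files)
  jsonlite::write_json(run_manifest, file.path(res_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

.content_key <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(json, tmp)
  on.exit(unlink(tmp))
  as.vector(tools::md5sum(tmp))
}
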