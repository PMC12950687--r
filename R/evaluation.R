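#' Cross-validation harness
#'
#' Three validation schemes for the prediction engines: CV2 masks random
#' records (sparse testing), CV0 leaves one year out entirely and predicts
#' it from the other years (with 5 rotations of the training folds), and
#' external validation predicts a separate breeding trial whose responses
#' are never seen in training. Observations are rows of a data frame with
#' columns `genotype`, `environment` and `y` (typically per-environment
#' BLUEs), aligned with observation-level kernels.
#'
#' @name evaluation
NULL

#' k-fold assignments for CV2
#'
#' Near-equal folds (sizes differing by at most one unit). At
#' `"genotype"` level all records of a genotype share a fold.
#'
#' @param obs data frame with a `genotype` column (or a character vector of
#'   genotype ids, one per record).
#' @param k number of folds.
#' @param level `"record"` or `"genotype"`.
#' @param seed integer seed; assignment is deterministic given the seed.
#' @return integer fold id per record.
#' @export
make_cv2_folds <- function(obs, k = 5L, level = c("record", "genotype"),
                           seed = 1L) {
  level <- match.arg(level)
  geno <- if (is.data.frame(obs)) as.character(obs$genotype)
          else as.character(obs)
  n <- length(geno)
  set.seed(seed)
  if (level == "record") {
    if (k > n) stop("k exceeds the number of records")
    fold <- rep_len(seq_len(k), n)[order(stats::runif(n))]
  } else {
    units <- unique(geno)
    if (k > length(units)) stop("k exceeds the number of genotypes")
    uf <- rep_len(seq_len(k), length(units))[order(stats::runif(length(units)))]
    names(uf) <- units
    fold <- unname(uf[geno])
  }
  fold
}

#' Predictive ability
#'
#' Pearson correlation between predictions and observations pooled over all
#' records, with a per-environment breakdown.
#'
#' @param pred,obs numeric vectors of equal length.
#' @param environment optional environment labels for the breakdown.
#' @return list with `pooled` (numeric) and `by_environment` (named
#'   numeric, present when labels are given). Zero variance in either
#'   vector yields `NA` with a warning.
#' @export
predictive_ability <- function(pred, obs, environment = NULL) {
  stopifnot(length(pred) == length(obs))
  ok <- !is.na(pred) & !is.na(obs)
  if (sum(ok) < 3L) stop("need at least 3 paired values")
  r1 <- function(p, o) {
    if (stats::sd(p) == 0 || stats::sd(o) == 0) {
      warning("zero variance; predictive ability undefined")
      return(NA_real_)
    }
    stats::cor(p, o)
  }
  out <- list(pooled = r1(pred[ok], obs[ok]))
  if (!is.null(environment)) {
    ev <- environment[ok]
    out$by_environment <- vapply(
      sort(unique(ev)),
      function(e) {
        sel <- ev == e
        if (sum(sel) < 3L) return(NA_real_)
        suppressWarnings(r1(pred[ok][sel], obs[ok][sel]))
      }, numeric(1))
  }
  out
}

#' Coincidence index for top-k selection
#'
#' Percentage overlap between the top-k units ranked by predictions and by
#' observations. Ties are broken by the stable unit order (position in the
#' input, or `ids` when given).
#'
#' @param pred,obs numeric score vectors over the same units.
#' @param k selection size (default 30).
#' @param ids optional unit identifiers (defaults to positions).
#' @param direction `"higher"` if large scores are better.
#' @return CI in percent, in `[0, 100]`.
#' @export
coincidence_index <- function(pred, obs, k = 30L, ids = NULL,
                              direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(length(pred) == length(obs))
  if (k > length(pred)) stop("k exceeds the number of scored units")
  if (is.null(ids)) ids <- seq_along(pred)
  s <- if (direction == "higher") -1 else 1
  top_pred <- ids[order(s * pred, seq_along(pred))][seq_len(k)]
  top_obs <- ids[order(s * obs, seq_along(obs))][seq_len(k)]
  100 * length(intersect(top_pred, top_obs)) / k
}

# fit one model (named kernel subset) with masked y, return predictions
# for every observation
.fit_predict <- function(engine, y_masked, env, kernels, terms, opts) {
  ker <- kernels[terms]
  if (any(vapply(ker, is.null, logical(1)))) {
    stop("model requires kernel(s) not supplied: ",
         paste(setdiff(terms, names(kernels)), collapse = ", "))
  }
  if (engine == "blup") {
    fit <- fit_multikernel(y_masked, env = env, kernels = ker,
                           n_iter = opts$n_iter, burn_in = opts$burn_in,
                           thin = opts$thin, df0 = opts$df0, R2 = opts$R2,
                           seed = opts$seed)
    return(fit$yhat)
  }
  feats <- ml_features(ker)
  tr <- !is.na(y_masked)
  pred <- rep(NA_real_, length(y_masked))
  if (engine == "rfr") {
    pred[!tr] <- fit_rfr(feats[tr, , drop = FALSE], y_masked[tr],
                         feats[!tr, , drop = FALSE],
                         n_trees = opts$n_trees, seed = opts$ml_seed)
  } else if (engine == "plsr") {
    pred[!tr] <- fit_plsr(feats[tr, , drop = FALSE], y_masked[tr],
                          feats[!tr, , drop = FALSE],
                          max_comp = opts$max_comp,
                          seed = opts$ml_seed)$pred
  } else stop("unknown engine '", engine, "'")
  pred
}

.cv_opts <- function(...) {
  opts <- list(n_iter = 12000L, burn_in = 2000L, thin = 5L, df0 = 5,
               R2 = 0.5, seed = 1L, n_trees = 100L, max_comp = 20L,
               ml_seed = 42L)
  dots <- list(...)
  opts[names(dots)] <- dots
  opts
}

#' CV2: random-record five-fold cross-validation
#'
#' Records are split into `k` folds (record level for the BLUP engine,
#' genotype level for the ML engines, by default); each fold is masked in
#' turn and predicted from the rest, and predictive ability is computed on
#' the pooled out-of-fold predictions across all environments.
#'
#' @param obs data frame with `genotype`, `environment`, `y`.
#' @param kernels named list of observation-level [kernel]s aligned with
#'   `obs`.
#' @param models named list: model name -> character vector of kernel
#'   names, e.g. `list(G = "Gexp", H = "H")`.
#' @param k folds (default 5).
#' @param engine `"blup"`, `"rfr"` or `"plsr"`.
#' @param level fold level; defaults to `"record"` for BLUP and
#'   `"genotype"` for the ML engines.
#' @param seed fold-assignment seed.
#' @param ... sampler / ML options (`n_iter`, `burn_in`, `R2`, `df0`,
#'   `n_trees`, `max_comp`, ...).
#' @return list of class `cv_result`: scheme, fold vector, per-record
#'   prediction table, and a `pa` data frame (model, pooled PA, per-
#'   environment PA).
#' @export
run_cv2 <- function(obs, kernels, models, k = 5L,
                    engine = c("blup", "rfr", "plsr"), level = NULL,
                    seed = 1L, ...) {
  engine <- match.arg(engine)
  if (is.null(level)) level <- if (engine == "blup") "record" else "genotype"
  opts <- .cv_opts(...)
  fold <- make_cv2_folds(obs, k = k, level = level, seed = seed)
  preds <- matrix(NA_real_, nrow(obs), length(models),
                  dimnames = list(NULL, names(models)))
  for (f in seq_len(k)) {
    test <- fold == f
    y_masked <- obs$y
    y_masked[test] <- NA
    stopifnot(!any(test & !is.na(y_masked)))  # leakage guard
    for (m in names(models)) {
      p <- .fit_predict(engine, y_masked, obs$environment, kernels,
                        models[[m]], opts)
      preds[test, m] <- p[test]
    }
  }
  pa <- do.call(rbind, lapply(names(models), function(m) {
    r <- predictive_ability(preds[, m], obs$y, obs$environment)
    data.frame(model = m, pa = r$pooled,
               t(r$by_environment), check.names = FALSE)
  }))
  structure(list(scheme = "CV2", engine = engine, level = level,
                 folds = fold, predictions = preds, obs = obs, pa = pa,
                 seed = seed),
            class = "cv_result")
}

#' CV0: leave-one-year-out prediction of a new environment
#'
#' For each held-out year, the remaining years form the training set, which
#' is split into `k` folds; in each of the `k` rotations the model is
#' trained on the other folds (the held-out year and the left-out fold are
#' both masked) and the entire held-out year is predicted. Predictive
#' ability per rotation is summarised as mean and sd per year.
#'
#' @inheritParams run_cv2
#' @param years which years to hold out (default: all environments in
#'   `obs`); each must leave at least two training years.
#' @return list of class `cv_result` with per-rotation and summarised PA.
#' @export
run_cv0 <- function(obs, kernels, models, years = NULL, k = 5L,
                    engine = c("blup", "rfr", "plsr"), seed = 1L, ...) {
  engine <- match.arg(engine)
  opts <- .cv_opts(...)
  all_years <- sort(unique(obs$environment))
  if (is.null(years)) years <- all_years
  if (any(!years %in% all_years)) {
    stop("held-out year(s) absent: ",
         paste(setdiff(years, all_years), collapse = ", "))
  }
  if (length(all_years) < 3L) {
    stop("CV0 needs at least 3 environments (2 training years per test year)")
  }
  rows <- list(); pred_list <- list()
  for (yr in years) {
    test <- obs$environment == yr
    train_idx <- which(!test)
    fold <- make_cv2_folds(obs[train_idx, , drop = FALSE], k = k,
                           level = "record", seed = seed)
    for (f in seq_len(k)) {
      y_masked <- obs$y
      y_masked[test] <- NA
      y_masked[train_idx[fold == f]] <- NA
      stopifnot(all(is.na(y_masked[test])))  # no leakage of the test year
      for (m in names(models)) {
        p <- .fit_predict(engine, y_masked, obs$environment, kernels,
                          models[[m]], opts)
        r <- predictive_ability(p[test], obs$y[test])
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, rotation = f, model = m, pa = r$pooled)
        pred_list[[paste(yr, f, m, sep = ".")]] <- p[test]
      }
    }
  }
  detail <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(
    detail, detail[, c("year", "model")], drop = TRUE), function(d) {
      data.frame(year = d$year[1], model = d$model[1],
                 pa_mean = mean(d$pa), pa_sd = stats::sd(d$pa))
    }))
  rownames(summary) <- NULL
  structure(list(scheme = "CV0", engine = engine, detail = detail,
                 pa = summary, predictions = pred_list, seed = seed),
            class = "cv_result")
}

#' External validation on a separate breeding trial
#'
#' Training records are split into `k` folds; each set of `k - 1` folds
#' trains the model (validation responses and the left-out fold masked) and
#' predicts the whole validation set. The `k` prediction vectors are
#' averaged before computing predictive ability and the coincidence index;
#' per-fold PA is reported as well.
#'
#' @inheritParams run_cv2
#' @param obs combined data frame of training and validation records.
#' @param is_validation logical vector marking validation rows of `obs`.
#' @param top_k selection size for the coincidence index (default 30; set
#'   `NULL` to skip).
#' @return list of class `cv_result` with averaged-prediction PA, per-fold
#'   PA and CI per model.
#' @export
run_external <- function(obs, is_validation, kernels, models, k = 5L,
                         top_k = 30L, engine = c("blup", "rfr", "plsr"),
                         seed = 1L, ...) {
  engine <- match.arg(engine)
  opts <- .cv_opts(...)
  stopifnot(length(is_validation) == nrow(obs))
  train_idx <- which(!is_validation)
  val_idx <- which(is_validation)
  if (!length(val_idx)) stop("no validation rows flagged")
  fold <- make_cv2_folds(obs[train_idx, , drop = FALSE], k = k,
                         level = "record", seed = seed)
  acc <- matrix(0, length(val_idx), length(models),
                dimnames = list(NULL, names(models)))
  per_fold <- list()
  for (f in seq_len(k)) {
    y_masked <- obs$y
    y_masked[val_idx] <- NA
    y_masked[train_idx[fold == f]] <- NA
    stopifnot(all(is.na(y_masked[val_idx])))  # leakage guard
    for (m in names(models)) {
      p <- .fit_predict(engine, y_masked, obs$environment, kernels,
                        models[[m]], opts)
      acc[, m] <- acc[, m] + p[val_idx]
      r <- predictive_ability(p[val_idx], obs$y[val_idx])
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        fold = f, model = m, pa = r$pooled)
    }
  }
  avg_pred <- acc / k
  pa_rows <- lapply(names(models), function(m) {
    r <- predictive_ability(avg_pred[, m], obs$y[val_idx])
    ci <- if (!is.null(top_k)) {
      coincidence_index(avg_pred[, m], obs$y[val_idx], k = top_k,
                        ids = obs$genotype[val_idx])
    } else NA_real_
    data.frame(model = m, pa = r$pooled, ci = ci)
  })
  structure(list(scheme = "external", engine = engine,
                 pa = do.call(rbind, pa_rows),
                 per_fold = do.call(rbind, per_fold),
                 predictions = avg_pred,
                 validation_obs = obs[val_idx, , drop = FALSE],
                 folds = fold, seed = seed),
            class = "cv_result")
}

#' @exportS3Method print cv_result
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation (%s engine)\n", x$scheme, x$engine))
  print(x$pa, row.names = FALSE)
  invisible(x)
}

#' Write a cv_result to CSV + JSON summary
#'
#' @param x a `cv_result`.
#' @param path output CSV path (a `.json` summary is written alongside).
#' @export
write_cv_result <- function(x, path) {
  utils::write.csv(x$pa, path, row.names = FALSE)
  jsonlite::write_json(list(scheme = x$scheme, engine = x$engine,
                            seed = x$seed, pa = x$pa),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}
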