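#' Stage-1 mixed-model analysis
#'
#' Plot-level records are analysed in two stages, as is standard for
#' multi-environment trials: (i) a combined all-random model over
#' environments for variance components and broad-sense heritability, and
#' (ii) per-environment fixed-genotype models yielding BLUEs (optionally
#' adjusted for days to anthesis) that feed the prediction stage.
#'
#' @name pheno_adjust
NULL

# random-effect terms for design columns that have >= 2 levels
.design_terms <- function(df, cols) {
  ok <- vapply(cols, function(f) {
    !is.null(df[[f]]) && length(unique(df[[f]])) >= 2L
  }, logical(1))
  cols[ok]
}

#' REML variance components for a trait
#'
#' Fits the combined multi-environment model with genotype, environment,
#' genotype-by-environment, incomplete block, row and column all random
#' (REML via lme4), and reports the variance decomposition, the proportions
#' of the genotype + G x E + residual total attributable to each of those
#' three sources, and broad-sense heritability on an entry-mean basis.
#'
#' @param plots plot table with columns `genotype`, `environment`,
#'   `replicate`, `block`, `row`, `col` and the trait.
#' @param trait trait column name.
#' @return list of class `variance_components`: variances, `proportions`
#'   (genotype, gxe, residual), `n_environments`, `n_replicates`, `H2` and
#'   a `converged` flag.
#' @export
reml_variance_components <- function(plots, trait) {
  stopifnot(trait %in% names(plots))
  df <- plots[!is.na(plots[[trait]]), , drop = FALSE]
  df$y <- df[[trait]]
  n_env <- length(unique(df$environment))
  n_rep <- length(unique(df$replicate))
  zero <- list(sigma2_g = 0, sigma2_gxe = 0, sigma2_env = 0,
               sigma2_block = 0, sigma2_row = 0, sigma2_col = 0,
               sigma2_e = 0)
  if (stats::var(df$y) == 0) {
    warning("trait '", trait, "' is constant; all variance components 0")
    out <- c(zero, list(proportions = c(genotype = NA, gxe = NA,
                                        residual = NA),
                        n_environments = n_env, n_replicates = n_rep,
                        H2 = NA_real_, converged = FALSE))
    class(out) <- "variance_components"
    return(out)
  }
  df$ge <- interaction(df$genotype, df$environment, drop = TRUE)
  terms <- c("genotype", if (n_env >= 2L) c("environment", "ge"),
             .design_terms(df, c("block", "row", "col")))
  form <- stats::as.formula(paste(
    "y ~", paste(sprintf("(1 | %s)", terms), collapse = " + ")))
  fit <- tryCatch(
    lme4::lmer(form, data = df,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("REML fit failed: ", conditionMessage(fit))
    out <- c(zero, list(proportions = c(genotype = NA, gxe = NA,
                                        residual = NA),
                        n_environments = n_env, n_replicates = n_rep,
                        H2 = NA_real_, converged = FALSE))
    class(out) <- "variance_components"
    return(out)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else 0
  }
  out <- list(sigma2_g = getv("genotype"), sigma2_gxe = getv("ge"),
              sigma2_env = getv("environment"),
              sigma2_block = getv("block"), sigma2_row = getv("row"),
              sigma2_col = getv("col"), sigma2_e = getv("Residual"))
  tot <- out$sigma2_g + out$sigma2_gxe + out$sigma2_e
  out$proportions <- c(genotype = out$sigma2_g, gxe = out$sigma2_gxe,
                       residual = out$sigma2_e) / tot
  out$n_environments <- n_env
  out$n_replicates <- n_rep
  out$H2 <- heritability(out$sigma2_g, out$sigma2_gxe, out$sigma2_e,
                         n_env, n_rep)
  conv <- fit@optinfo$conv$opt == 0 &&
    length(fit@optinfo$conv$lme4$messages) == 0L
  out$converged <- isTRUE(conv) ||
    all(grepl("singular|boundary",
              unlist(fit@optinfo$conv$lme4$messages)))
  class(out) <- "variance_components"
  out
}

#' @exportS3Method print variance_components
print.variance_components <- function(x, ...) {
  cat("REML variance components\n")
  v <- unlist(x[c("sigma2_g", "sigma2_gxe", "sigma2_env", "sigma2_block",
                  "sigma2_row", "sigma2_col", "sigma2_e")])
  print(round(v, 6))
  cat(sprintf("proportions (G / GxE / resid): %.3f / %.3f / %.3f\n",
              x$proportions[1], x$proportions[2], x$proportions[3]))
  cat(sprintf("H2 = %.3f (n = %d environments, r = %d replicates)\n",
              x$H2, x$n_environments, x$n_replicates))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' H2 = sigma2_g / (sigma2_g + sigma2_gxe / n + sigma2_e / (n r)), with n
#' environments and r replicates.
#'
#' @param sigma2_g,sigma2_gxe,sigma2_e variance components (or a
#'   `variance_components` object as first argument).
#' @param n_environments,n_replicates counts used for the entry-mean basis.
#' @return H2 in `[0, 1]`; `NA` with a warning when all three variances are
#'   zero.
#' @export
heritability <- function(sigma2_g, sigma2_gxe = NULL, sigma2_e = NULL,
                         n_environments = NULL, n_replicates = NULL) {
  if (inherits(sigma2_g, "variance_components")) {
    v <- sigma2_g
    return(heritability(v$sigma2_g, v$sigma2_gxe, v$sigma2_e,
                        v$n_environments, v$n_replicates))
  }
  stopifnot(n_environments >= 1, n_replicates >= 1)
  if (any(c(sigma2_g, sigma2_gxe, sigma2_e) < 0)) {
    stop("variance components must be nonnegative")
  }
  denom <- sigma2_g + sigma2_gxe / n_environments +
    sigma2_e / (n_environments * n_replicates)
  if (denom == 0) {
    warning("all variance components are zero; heritability undefined")
    return(NA_real_)
  }
  sigma2_g / denom
}

#' Per-environment BLUEs with an optional days-to-anthesis covariate
#'
#' Fits each environment separately with genotype fixed, an optional fixed
#' DTA slope (DTA centred within environment, so BLUEs are at the
#' environment-mean DTA), and incomplete block, row and column random with
#' REML variances. When all random variances are zero this reduces to
#' ordinary least-squares adjusted genotype means. Genotypes without
#' observations in an environment are absent from the output.
#'
#' @param plots plot table (see [reml_variance_components()]), with a `DTA`
#'   column when `use_dta_covariate` is `TRUE`.
#' @param trait trait column name.
#' @param use_dta_covariate include the fixed DTA slope (default `TRUE`).
#' @return data frame of class `adjusted_means`: `genotype`, `environment`,
#'   `trait`, `blue`, `se`, `converged`; attribute `dta_slope` holds the
#'   per-environment fitted slopes.
#' @export
blues_per_environment <- function(plots, trait, use_dta_covariate = TRUE) {
  stopifnot(trait %in% names(plots))
  if (use_dta_covariate && is.null(plots$DTA)) {
    stop("use_dta_covariate = TRUE but no DTA column present")
  }
  res <- list(); slopes <- c()
  for (env in unique(plots$environment)) {
    df <- plots[plots$environment == env & !is.na(plots[[trait]]), ,
                drop = FALSE]
    if (!nrow(df)) next
    df$y <- df[[trait]]
    df$genotype <- factor(df$genotype)
    rand <- .design_terms(df, c("block", "row", "col"))
    fixed <- "y ~ 0 + genotype"
    if (use_dta_covariate) {
      df$DTA_c <- df$DTA - mean(df$DTA)
      fixed <- paste(fixed, "+ DTA_c")
    }
    converged <- TRUE
    if (length(rand)) {
      form <- stats::as.formula(paste(
        fixed, "+", paste(sprintf("(1 | %s)", rand), collapse = " + ")))
      fit <- tryCatch(
        suppressMessages(lme4::lmer(form, data = df,
                                    control = lme4::lmerControl(
                                      check.nobs.vs.nlev = "ignore",
                                      check.nobs.vs.nRE = "ignore",
                                      calc.derivs = FALSE))),
        error = function(e) e)
      if (inherits(fit, "error")) {
        fit <- stats::lm(stats::as.formula(fixed), data = df)
        converged <- FALSE
      }
    } else {
      fit <- stats::lm(stats::as.formula(fixed), data = df)
    }
    cf <- if (inherits(fit, "lm")) stats::coef(fit) else lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    is_g <- grepl("^genotype", names(cf))
    if (use_dta_covariate) {
      slopes[env] <- unname(cf[["DTA_c"]])
    }
    res[[env]] <- data.frame(
      genotype = sub("^genotype", "", names(cf)[is_g]),
      environment = env, trait = trait,
      blue = unname(cf[is_g]), se = unname(se[is_g]),
      converged = converged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "dta_slope") <- slopes
  class(out) <- c("adjusted_means", class(out))
  out
}

#' Fast multi-response adjusted means (OLS)
#'
#' Per-environment genotype means adjusted for a fixed DTA slope via a
#' single multi-response least-squares fit, used for the high-dimensional
#' responses (hyperspectral bands, vegetation indices) where one mixed
#' model per band is not warranted. This is exactly the zero-random-
#' variance limit of [blues_per_environment()].
#'
#' @param df table with `genotype`, `environment`, optional `DTA`, and the
#'   value columns.
#' @param value_cols names of the response columns to adjust.
#' @param use_dta_covariate include the fixed DTA slope when a `DTA`
#'   column is present.
#' @return data frame `genotype`, `environment`, then one adjusted-mean
#'   column per response.
#' @export
adjust_means_ols <- function(df, value_cols, use_dta_covariate = TRUE) {
  stopifnot(all(value_cols %in% names(df)))
  use_dta <- use_dta_covariate && !is.null(df$DTA)
  out <- list()
  for (env in unique(df$environment)) {
    d <- df[df$environment == env, , drop = FALSE]
    g <- factor(d$genotype)
    x <- stats::model.matrix(~ 0 + g)
    if (use_dta) x <- cbind(x, DTA_c = d$DTA - mean(d$DTA))
    y <- as.matrix(d[, value_cols, drop = FALSE])
    cf <- stats::lm.fit(x, y)$coefficients
    is_g <- grepl("^g", rownames(cf)) & rownames(cf) != "DTA_c"
    out[[env]] <- data.frame(
      genotype = sub("^g", "", rownames(cf)[is_g]), environment = env,
      cf[is_g, , drop = FALSE], check.names = FALSE,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise Pearson correlations among traits, per environment
#'
#' Correlations are computed on per-environment BLUEs with pairwise-
#' complete observations and two-sided p-values; constant columns yield
#' `NA` correlations.
#'
#' @param blues_wide data frame with columns `genotype`, `environment` and
#'   one column per trait (wide adjusted means; see
#'   [adjusted_means_wide()]).
#' @return named list (one element per environment) of lists with matrices
#'   `r`, `p` and `n`.
#' @export
trait_correlations <- function(blues_wide) {
  vars <- setdiff(names(blues_wide), c("genotype", "environment"))
  out <- list()
  for (env in unique(blues_wide$environment)) {
    x <- as.matrix(blues_wide[blues_wide$environment == env, vars,
                              drop = FALSE])
    if (nrow(x) < 3L) stop("fewer than 3 genotypes in environment ", env)
    r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    n <- crossprod(!is.na(x))
    tt <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), df = pmax(n - 2, 1), lower.tail = FALSE)
    diag(p) <- 0
    out[[env]] <- list(r = r, p = p, n = n)
  }
  out
}

#' Reshape long adjusted means to one column per trait
#'
#' @param blues long `adjusted_means` table (possibly several traits bound
#'   together).
#' @return wide data frame `genotype`, `environment`, one column per trait.
#' @export
adjusted_means_wide <- function(blues) {
  stats::reshape(
    as.data.frame(blues)[, c("genotype", "environment", "trait", "blue")],
    idvar = c("genotype", "environment"), timevar = "trait",
    direction = "wide") -> w
  names(w) <- sub("^blue\\.", "", names(w))
  rownames(w) <- NULL
  w
}
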