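#' Labelled positive semi-definite kernels
#'
#' A `kernel` wraps a symmetric PSD similarity matrix together with its row
#' labels and resolution level. Levels: `"genotype"` (labels are genotype
#' ids), `"environment"` (environment ids), `"observation"` (one row per
#' genotype-environment record, labels `"genotype@environment"`).
#'
#' @param K symmetric numeric matrix.
#' @param labels character row/column keys; defaults to `rownames(K)`.
#' @param level one of `"genotype"`, `"environment"`, `"observation"`.
#' @param name short kernel name (e.g. `"G"`, `"H"`, `"V"`, `"W"`, `"GW"`).
#' @param q number of feature columns the kernel was averaged over, if any.
#' @param check_psd verify the smallest eigenvalue is above
#'   `-1e-8 * largest`; construction aborts otherwise.
#' @return object of class `kernel`.
#' @export
kernel <- function(K, labels = rownames(K), level = "genotype",
                   name = "K", q = NULL, check_psd = TRUE) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  level <- match.arg(level, c("genotype", "environment", "observation"))
  if (is.null(labels)) labels <- as.character(seq_len(nrow(K)))
  labels <- as.character(labels)
  if (length(labels) != nrow(K)) stop("labels must match kernel dimension")
  if (anyDuplicated(labels)) stop("kernel labels must be unique")
  sym_err <- max(abs(K - t(K)))
  if (sym_err > 1e-10 * max(1, max(abs(K)))) {
    stop("kernel matrix is not symmetric (max asymmetry ", sym_err, ")")
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- list(labels, labels)
  emin <- emax <- NA_real_
  if (check_psd) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    emax <- max(ev); emin <- min(ev)
    if (emin < -1e-8 * max(emax, .Machine$double.eps)) {
      stop("kernel '", name, "' is not PSD: smallest eigenvalue ", emin)
    }
  }
  structure(list(K = K, labels = labels, level = level, name = name,
                 q = q, emin = emin, emax = emax),
            class = "kernel")
}

#' @exportS3Method as.matrix kernel
as.matrix.kernel <- function(x, ...) x$K

#' @exportS3Method dim kernel
dim.kernel <- function(x) dim(x$K)

#' @exportS3Method print kernel
print.kernel <- function(x, ...) {
  cat(sprintf("kernel '%s' (%s level): %d x %d", x$name, x$level,
              nrow(x$K), ncol(x$K)))
  if (!is.null(x$q)) cat(sprintf(", q = %d", x$q))
  if (!is.na(x$emin)) {
    cat(sprintf(", eigenvalues in [%.3g, %.3g]", x$emin, x$emax))
  }
  cat("\n")
  invisible(x)
}

#' Observation keys for genotype-environment records
#'
#' @param genotype,environment character vectors of equal length.
#' @return character vector `"genotype@environment"`.
#' @export
obs_key <- function(genotype, environment) {
  paste(genotype, environment, sep = "@")
}

#' Expand a kernel to observation level
#'
#' Builds ZKZ' for the incidence matrix Z mapping each observation to its
#' genotype (or environment) label: entry (a, b) of the result is
#' K[level(a), level(b)]. Equivalent to indexing rows and columns of K, so
#' no explicit Z is formed.
#'
#' @param k a [kernel] at genotype or environment level.
#' @param obs data frame with columns `genotype` and `environment`, one row
#'   per observation, in the desired observation order.
#' @return a [kernel] at observation level, labels `obs_key(...)`, name
#'   `"<name>exp"`.
#' @export
expand_kernel <- function(k, obs) {
  stopifnot(inherits(k, "kernel"))
  if (k$level == "observation") stop("kernel is already at observation level")
  keys <- if (k$level == "genotype") as.character(obs$genotype)
          else as.character(obs$environment)
  unknown <- setdiff(unique(keys), k$labels)
  if (length(unknown)) {
    stop("label(s) absent from kernel '", k$name, "': ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  idx <- match(keys, k$labels)
  Kx <- k$K[idx, idx, drop = FALSE]
  kernel(Kx, labels = obs_key(obs$genotype, obs$environment),
         level = "observation", name = paste0(k$name, "exp"), q = k$q,
         check_psd = FALSE)
}

#' Linear (cross-product) kernel from a feature table
#'
#' Columns are centred and scaled to unit population standard deviation
#' (divisor n), zero-variance columns are dropped with a warning, and
#' K = SS'/q with q the number of retained columns. This is the form used
#' for the vegetation-index kernel V (q = number of indices), the
#' environmental-covariate kernel W (q = number of ECs) and the
#' hyperspectral kernel H (q = number of bands).
#'
#' @param x numeric matrix or data frame of features, rows keyed by
#'   `rownames`.
#' @param labels row keys; defaults to rownames.
#' @param level kernel level of the rows.
#' @param name kernel name.
#' @return a [kernel] with `q` recorded.
#' @export
linear_kernel <- function(x, labels = rownames(x), level = "observation",
                          name = "K") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("need at least two rows to build a kernel")
  if (anyNA(x)) {
    all_na <- rowSums(!is.na(x)) == 0L
    if (any(all_na)) stop("row(s) with all-missing features")
    stop("feature matrix contains missing values")
  }
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu, "-")^2))  # population sd
  keep <- sdev > .Machine$double.eps
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature column(s) dropped")
    x <- x[, keep, drop = FALSE]
    mu <- mu[keep]; sdev <- sdev[keep]
  }
  if (ncol(x) == 0L) stop("no informative feature columns left")
  s <- sweep(sweep(x, 2L, mu, "-"), 2L, sdev, "/")
  q <- ncol(s)
  kernel(tcrossprod(s) / q, labels = labels, level = level, name = name,
         q = q)
}

#' Hadamard interaction kernel
#'
#' Entrywise product of two observation-level kernels with identical label
#' order; used for the genotype-by-environment interaction term
#' GW = ZgGZg' o ZeWZe'. PSD by the Schur product theorem.
#'
#' @param g_exp,w_exp observation-level [kernel]s with identical labels.
#' @param name kernel name (default `"GW"`).
#' @return a [kernel] at observation level.
#' @export
interaction_kernel <- function(g_exp, w_exp, name = "GW") {
  stopifnot(inherits(g_exp, "kernel"), inherits(w_exp, "kernel"))
  if (g_exp$level != "observation" || w_exp$level != "observation") {
    stop("interaction kernels require observation-level inputs")
  }
  if (!identical(g_exp$labels, w_exp$labels)) {
    stop("kernel label order mismatch between '", g_exp$name, "' and '",
         w_exp$name, "'")
  }
  kernel(g_exp$K * w_exp$K, labels = g_exp$labels, level = "observation",
         name = name, check_psd = FALSE)
}

#' Write / read a kernel as labelled TSV with a JSON sidecar
#'
#' The TSV holds the square matrix with header labels and a leading label
#' column; `<path>.json` records level, name, q and the scaling convention.
#'
#' @param k a [kernel].
#' @param path output TSV path.
#' @return `read_kernel_tsv` returns the [kernel].
#' @export
write_kernel_tsv <- function(k, path) {
  df <- data.frame(label = k$labels, k$K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(level = k$level, name = k$name, q = k$q,
               scaling = "centered, population-sd scaled, K = SS'/q")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_kernel_tsv
#' @export
read_kernel_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  K <- as.matrix(df[, -1L, drop = FALSE])
  labels <- as.character(df[[1L]])
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list(level = "genotype", name = "K", q = NULL)
  rownames(K) <- labels
  kernel(K, labels = labels, level = meta$level, name = meta$name,
         q = if (is.null(meta$q)) NULL else as.integer(meta$q))
}
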