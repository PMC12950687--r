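#' Marker matrices and genomic relationships
#'
#' Genotype data are held as a plain numeric matrix of minor-allele dosages
#' (genotypes in rows, markers in columns) coded 0/1/2 with `NA` for missing
#' calls. Row and column names carry the genotype and marker identifiers and
#' are required by every function in this module.
#'
#' @name genotypes
NULL

#' Per-marker minor allele frequency
#'
#' Frequencies are computed on non-missing calls only. Markers coded on the
#' major allele (frequency > 0.5) are folded so the returned value is always
#' the minor-allele frequency.
#'
#' @param m dosage matrix (genotypes x markers), entries 0/1/2/NA.
#' @return named numeric vector, one frequency per marker; `NaN` for markers
#'   with no non-missing calls.
#' @export
marker_maf <- function(m) {
  p <- colMeans(m, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Marker quality control
#'
#' Removes markers that fail any of three rules, applied with strict
#' inequalities: missing-call fraction greater than `max_missing`, minor
#' allele frequency (on non-missing calls) below `min_maf`, or heterozygote
#' fraction (dosage-1 calls among non-missing calls) greater than `max_het`.
#' A marker failing several rules is attributed to the first failing rule in
#' the order missing, MAF, heterozygosity. The genotype set is never changed.
#'
#' @param m dosage matrix (genotypes x markers) with dimnames.
#' @param max_missing markers with missing fraction strictly above this are
#'   removed (default 0.80).
#' @param min_maf markers with MAF strictly below this are removed
#'   (default 0.05).
#' @param max_het markers with heterozygote fraction strictly above this are
#'   removed (default 0.10).
#' @return list with `markers` (the filtered matrix) and `report`, a
#'   `qc_report` with counts and per-rule marker id lists.
#' @export
filter_markers <- function(m, max_missing = 0.80, min_maf = 0.05,
                           max_het = 0.10) {
  stopifnot(is.matrix(m))
  if (ncol(m) == 0L || nrow(m) == 0L) stop("empty marker matrix")
  thr <- c(max_missing, min_maf, max_het)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  ids <- colnames(m)
  if (is.null(ids)) ids <- paste0("M", seq_len(ncol(m)))

  n_miss <- colSums(is.na(m))
  n_obs <- nrow(m) - n_miss
  miss_frac <- n_miss / nrow(m)
  maf <- marker_maf(m)
  het_frac <- colSums(m == 1, na.rm = TRUE) / pmax(n_obs, 1L)

  fail_miss <- miss_frac > max_missing
  # markers with zero informative calls can only fail the missing rule
  fail_maf <- !fail_miss & (is.nan(maf) | maf < min_maf)
  fail_het <- !fail_miss & !fail_maf & het_frac > max_het
  keep <- !(fail_miss | fail_maf | fail_het)

  report <- structure(list(
    n_input_markers   = ncol(m),
    n_removed_missing = sum(fail_miss),
    n_removed_maf     = sum(fail_maf),
    n_removed_het     = sum(fail_het),
    n_retained        = sum(keep),
    removed_missing   = ids[fail_miss],
    removed_maf       = ids[fail_maf],
    removed_het       = ids[fail_het]
  ), class = "qc_report")
  if (!any(keep)) warning("all markers removed by QC filters")
  list(markers = m[, keep, drop = FALSE], report = report)
}

#' @exportS3Method print qc_report
print.qc_report <- function(x, ...) {
  cat("Marker QC report\n")
  cat(sprintf("  input markers : %d\n", x$n_input_markers))
  cat(sprintf("  removed (missing > thr) : %d\n", x$n_removed_missing))
  cat(sprintf("  removed (MAF < thr)     : %d\n", x$n_removed_maf))
  cat(sprintf("  removed (het > thr)     : %d\n", x$n_removed_het))
  cat(sprintf("  retained : %d\n", x$n_retained))
  invisible(x)
}

#' Mean-dosage imputation
#'
#' Replaces each missing call by the marker's mean dosage over non-missing
#' calls. Output is real-valued; non-missing entries are unchanged.
#'
#' @param m dosage matrix with possible `NA` entries.
#' @return numeric matrix with no missing values.
#' @export
impute_mean <- function(m) {
  stopifnot(is.matrix(m))
  if (!anyNA(m)) return(m)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0L)) {
    bad <- colnames(m)[n_obs == 0L]
    if (is.null(bad)) bad <- which(n_obs == 0L)
    stop("marker(s) with no non-missing calls: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- mu[idx[, 2L]]
  m
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 additive relationship matrix: each marker column is centred by
#' twice its observed allele frequency and G = WW' / (2 * sum p (1 - p)).
#' Frequencies are the observed post-imputation allele frequencies, so the
#' mean diagonal is near 1 for an unstructured population.
#'
#' @param m imputed dosage matrix (no missing entries), at least two
#'   genotypes.
#' @return a [kernel] at genotype level named `"G"`.
#' @export
vanraden_g <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  if (anyNA(m)) stop("dosage matrix contains missing values; impute first")
  p <- colMeans(m) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= .Machine$double.eps) {
    stop("all markers monomorphic: VanRaden denominator is zero")
  }
  w <- sweep(m, 2L, 2 * p, "-")
  g <- tcrossprod(w) / denom
  kernel(g, labels = rownames(m), level = "genotype", name = "G")
}

#' Read and write dosage matrices
#'
#' Tab-separated text with genotypes in rows, markers in columns and `NA`
#' for missing calls; the first column holds genotype ids.
#'
#' @param m dosage matrix.
#' @param path file path.
#' @return `read_dosage_tsv` returns the dosage matrix with dimnames.
#' @export
write_dosage_tsv <- function(m, path) {
  df <- data.frame(genotype = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Read minor-allele dosages from a VCF
#'
#' Maps diploid GT fields to ALT-allele counts, then folds markers whose ALT
#' allele is the major allele so entries count the minor allele; the
#' REF/ALT-to-minor orientation of each folded marker is reported via a
#' message. Requires the optional vcfR package.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @return dosage matrix, genotypes x markers.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_dosage() requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/"), function(a) {
             sum(a == "1")
           }, numeric(1)))
  }
  d <- apply(gt, 2L, count_alt)
  d <- t(d)  # genotypes in rows
  colnames(d) <- rownames(gt)
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  flip <- !is.na(p_alt) & p_alt > 0.5
  if (any(flip)) {
    d[, flip] <- 2 - d[, flip]
    message(sum(flip), " marker(s) folded: REF is the minor allele")
  }
  d
}
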