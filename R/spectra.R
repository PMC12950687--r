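#' Canopy reflectance tables
#'
#' Plot-level reflectance is held in a data frame with key columns
#' `genotype`, `environment`, `plot` followed by one numeric column per
#' spectral band; band column names are the wavelengths in nm with
#' two-decimal precision (e.g. `"398.47"`). Helper [refl_wavelengths()]
#' recovers them.
#'
#' @name spectra
NULL

refl_band_cols <- function(r) {
  keys <- c("genotype", "environment", "plot")
  setdiff(names(r), keys)
}

#' @param r reflectance data frame.
#' @return numeric vector of band wavelengths in nm, in column order.
#' @rdname spectra
#' @export
refl_wavelengths <- function(r) {
  w <- suppressWarnings(as.numeric(refl_band_cols(r)))
  if (anyNA(w)) stop("non-numeric band column names in reflectance table")
  w
}

#' L2 normalisation of plot spectra
#'
#' Divides each plot's spectrum by its own Euclidean norm across bands, so
#' every row has unit norm. Within-plot band ratios are preserved.
#'
#' @param r reflectance data frame (see [spectra]).
#' @return the table with band columns rescaled row-wise.
#' @export
l2_normalize <- function(r) {
  bands <- refl_band_cols(r)
  x <- as.matrix(r[, bands, drop = FALSE])
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm <= .Machine$double.eps)) {
    bad <- which(nrm <= .Machine$double.eps)[1L]
    stop("zero-norm spectrum for plot ",
         paste(r$genotype[bad], r$environment[bad], r$plot[bad], sep = "/"))
  }
  r[, bands] <- x / nrm
  r
}

#' Vegetation indices from multispectral band means
#'
#' NDVI = (NIR - Red) / (NIR + Red) and
#' EVI = 2.5 (NIR - Red) / (NIR + 6 Red - 7.5 Blue + 1). Plots with a zero
#' NDVI denominator or a non-positive EVI denominator get `NA` with a
#' warning.
#'
#' @param blue,red,nir numeric vectors of plot-mean reflectance for the
#'   Blue, Red and NIR bands (same length; `blue` is only used by EVI).
#' @return data frame with columns `NDVI` and `EVI`.
#' @export
compute_vis <- function(blue, red, nir) {
  stopifnot(length(red) == length(nir), length(blue) == length(nir))
  ndvi_den <- nir + red
  ndvi <- ifelse(ndvi_den == 0, NA_real_, (nir - red) / ndvi_den)
  evi_den <- nir + 6 * red - 7.5 * blue + 1
  evi <- ifelse(evi_den <= 0, NA_real_, 2.5 * (nir - red) / evi_den)
  if (anyNA(ndvi)) warning(sum(is.na(ndvi)), " plot(s) with NDVI denominator 0")
  if (anyNA(evi)) warning(sum(is.na(evi)), " plot(s) with EVI denominator <= 0")
  data.frame(NDVI = ndvi, EVI = evi)
}

#' Multispectral band windows (nm)
#'
#' Sensor band windows used to average hyperspectral reflectance into the
#' five broad bands; bounds inclusive.
#' @export
msi_band_windows <- function() {
  data.frame(band = c("Blue", "Green", "Red", "RedEdge", "NIR"),
             lo = c(455, 545, 650, 705, 820),
             hi = c(495, 575, 685, 725, 860))
}

#' Average hyperspectral bands into multispectral band means
#'
#' @param r reflectance data frame.
#' @param windows band-window table as from [msi_band_windows()].
#' @return data frame with key columns and one column per broad band.
#' @export
msi_from_hyperspectral <- function(r, windows = msi_band_windows()) {
  w <- refl_wavelengths(r)
  x <- as.matrix(r[, refl_band_cols(r), drop = FALSE])
  out <- r[, c("genotype", "environment", "plot")]
  for (i in seq_len(nrow(windows))) {
    sel <- w >= windows$lo[i] & w <= windows$hi[i]
    if (!any(sel)) stop("no hyperspectral band inside window ",
                        windows$band[i])
    out[[windows$band[i]]] <- rowMeans(x[, sel, drop = FALSE])
  }
  out
}

#' Band-trait correlation profile
#'
#' Pearson correlation (with two-sided p-values) between per-band adjusted
#' means and a trait's adjusted means, computed within each environment on
#' matched (genotype, environment) keys and returned ordered by wavelength.
#' Band adjusted means are genotype means of the supplied (typically
#' L2-normalised) reflectance table within each environment.
#'
#' @param r reflectance data frame.
#' @param blues adjusted-means data frame with columns `genotype`,
#'   `environment`, `trait`, `blue` (as from [blues_per_environment()]).
#' @param trait trait name to profile.
#' @return data frame with columns `environment`, `wavelength`, `r`, `p`,
#'   `n`.
#' @export
band_trait_correlation <- function(r, blues, trait) {
  stopifnot(all(c("genotype", "environment", "trait", "blue") %in%
                  names(blues)))
  b <- blues[blues$trait == trait, , drop = FALSE]
  w <- refl_wavelengths(r)
  bands <- refl_band_cols(r)
  out <- list()
  for (env in unique(b$environment)) {
    renv <- r[r$environment == env, , drop = FALSE]
    if (!nrow(renv)) next
    # genotype-mean spectrum within environment
    x <- rowsum(as.matrix(renv[, bands, drop = FALSE]), renv$genotype)
    x <- x / as.vector(table(renv$genotype)[rownames(x)])
    benv <- b[b$environment == env, ]
    common <- intersect(rownames(x), benv$genotype)
    if (length(common) < 3L) {
      stop("fewer than 3 matched genotypes in environment ", env)
    }
    y <- benv$blue[match(common, benv$genotype)]
    xm <- x[common, , drop = FALSE]
    rr <- suppressWarnings(stats::cor(xm, y))
    n <- length(common)
    tt <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    out[[env]] <- data.frame(environment = env, wavelength = w,
                             r = as.vector(rr), p = as.vector(p), n = n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$environment, res$wavelength), ]
}
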