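#' Three-cube FRET calibration constants
#'
#' `a` corrects YFP cross-excitation, `b` CFP spectral crosstalk (both
#' determined per measurement day from donor-only / acceptor-only samples);
#' `G` is the dimensionless microscope constant relating sensitized
#' emission to donor quenching (2.75 for the setup the defaults mirror).
#'
#' @param a,b Nonnegative bleed-through factors.
#' @param G Positive instrument constant.
#' @return Object of class `"fret_calibration"`.
#' @export
fret_calibration <- function(a, b, G = 2.75) {
  stopifnot(a >= 0, b >= 0, G > 0)
  structure(list(a = a, b = b, G = G), class = "fret_calibration")
}

#' @export
print.fret_calibration <- function(x, ...) {
  cat(sprintf("<fret_calibration> a = %g, b = %g, G = %g\n", x$a, x$b, x$G))
  invisible(x)
}

#' Apparent FRET efficiency from three-cube intensities
#'
#' Pixel-wise (or scalar) sensitized-emission efficiency
#' `E_app = (I_FRET - a I_YFP - b I_CFP) / (I_FRET - a I_YFP + (G - b) I_CFP)`.
#' Intensities must be background-subtracted. A zero denominator yields
#' `NA` (flagged invalid), never an error. Negative numerators are
#' reported as negative `E_app` (diagnostic), not clamped.
#'
#' @param I_FRET,I_YFP,I_CFP Nonnegative scalars or identically shaped
#'   matrices.
#' @param cal A [fret_calibration].
#' @return `E_app`, same shape as the inputs.
#' @export
fret_eapp <- function(I_FRET, I_YFP, I_CFP, cal) {
  stopifnot(inherits(cal, "fret_calibration"))
  num <- I_FRET - cal$a * I_YFP - cal$b * I_CFP
  den <- I_FRET - cal$a * I_YFP + (cal$G - cal$b) * I_CFP
  e <- num / den
  e[den == 0] <- NA_real_
  e
}

#' Pixel validity gate on the CFP:YFP intensity ratio
#'
#' A pixel is valid iff both channels are positive and `I_CFP / I_YFP`
#' lies in `[bounds[1], bounds[2]]` (inclusive). The default bounds 0.01
#' and 100 encode a CFP:YFP ratio between 0.1:10 and 10:0.1.
#'
#' @param I_CFP,I_YFP Background-subtracted rasters of identical shape.
#' @param bounds Length-2 ratio bounds.
#' @return Logical mask, same shape.
#' @export
gate_pixels <- function(I_CFP, I_YFP, bounds = c(0.01, 100)) {
  stopifnot(identical(dim(I_CFP), dim(I_YFP)) ||
            length(I_CFP) == length(I_YFP))
  pos <- I_CFP > 0 & I_YFP > 0
  ratio <- ifelse(pos, I_CFP / I_YFP, NA_real_)
  ok <- pos & ratio >= bounds[1] & ratio <= bounds[2]
  ok[is.na(ok)] <- FALSE
  ok
}

#' Background subtraction with clamping at zero
#'
#' Subtracts a scalar background, or a background estimated as the mean
#' intensity over a user-supplied cell-free region mask, and clamps
#' negative results to 0.
#'
#' @param raster Intensity matrix.
#' @param background Nonnegative scalar, or `NULL` to estimate from
#'   `region`.
#' @param region Logical mask of cell-free pixels (required when
#'   `background` is `NULL`).
#' @return Raster of the same shape; the estimate used is attached as
#'   attribute `"background"`.
#' @export
subtract_background <- function(raster, background = NULL, region = NULL) {
  if (is.null(background)) {
    if (is.null(region) || !any(region))
      stop("background region is empty; supply a scalar background")
    background <- mean(raster[region])
  }
  stopifnot(background >= 0)
  out <- pmax(raster - background, 0)
  attr(out, "background") <- background
  out
}

#' Full three-cube FRET map with gating
#'
#' Convenience pipeline: background subtraction per channel, ratio gating,
#' then [fret_eapp]. The summary mean/median are taken over valid pixels
#' with nonnegative numerator (negative-numerator pixels are kept in the
#' map as diagnostics but excluded from summaries).
#'
#' @param I_CFP,I_YFP,I_FRET Raw intensity rasters, identical shape.
#' @param cal A [fret_calibration].
#' @param background Length-3 (CFP, YFP, FRET) scalar backgrounds, a single
#'   scalar for all channels, or 0.
#' @param bounds Gate bounds, see [gate_pixels].
#' @return Object of class `"eapp_map"`: `eapp` raster, logical `valid`
#'   mask, `mean`, `median`, `n_valid`.
#' @export
fret_eapp_map <- function(I_CFP, I_YFP, I_FRET, cal, background = 0,
                          bounds = c(0.01, 100)) {
  if (length(background) == 1L) background <- rep(background, 3L)
  C <- subtract_background(I_CFP, background[1])
  Y <- subtract_background(I_YFP, background[2])
  F_ <- subtract_background(I_FRET, background[3])
  valid <- gate_pixels(C, Y, bounds)
  e <- fret_eapp(F_, Y, C, cal)
  valid <- valid & !is.na(e)
  use <- valid & e >= 0
  structure(list(eapp = e, valid = valid,
                 mean = if (any(use)) mean(e[use]) else NA_real_,
                 median = if (any(use)) stats::median(e[use]) else NA_real_,
                 n_valid = sum(valid)),
            class = "eapp_map")
}

#' @export
print.eapp_map <- function(x, ...) {
  cat(sprintf("<eapp_map> %d x %d, %d valid pixels, mean E_app = %.3f\n",
              nrow(x$eapp), ncol(x$eapp), x$n_valid, x$mean))
  invisible(x)
}

#' Classify NFAT translocation from the nucleus/cytosol intensity ratio
#'
#' Three populations: inactive (ratio < 0.85), homogeneous (0.85-1.15,
#' boundaries included) and active (> 1.15), i.e. nuclear accumulation of
#' the transcription factor marks an activated Ca2+/calcineurin pathway.
#'
#' @param nucleus_mean,cytosol_mean Background-subtracted mean intensities
#'   (vectorized); `cytosol_mean` must be positive.
#' @param thresholds Length-2 category bounds.
#' @return Factor with levels `inactive`, `homogeneous`, `active`.
#' @export
nfat_classify <- function(nucleus_mean, cytosol_mean,
                          thresholds = c(0.85, 1.15)) {
  if (any(cytosol_mean <= 0)) stop("cytosol_mean must be > 0")
  ratio <- nucleus_mean / cytosol_mean
  cat_ <- ifelse(ratio < thresholds[1], "inactive",
          ifelse(ratio > thresholds[2], "active", "homogeneous"))
  factor(cat_, levels = c("inactive", "homogeneous", "active"))
}

#' Summarize an NFAT cell population
#'
#' @param cells Data frame with columns `nucleus_mean` and `cytosol_mean`
#'   (or a ready `ratio` column), one row per cell; alternatively a numeric
#'   vector of ratios.
#' @param thresholds Passed to [nfat_classify].
#' @return List of class `"nfat_summary"`: per-category `counts` and
#'   `fractions` (summing to 1), `n`, and `fraction_active` as the
#'   headline statistic.
#' @export
nfat_summarize <- function(cells, thresholds = c(0.85, 1.15)) {
  if (is.numeric(cells)) cells <- data.frame(ratio = cells)
  if (!nrow(cells)) stop("empty cell list")
  categories <- if (!is.null(cells$ratio))
    nfat_classify(cells$ratio, rep(1, nrow(cells)), thresholds)
  else
    nfat_classify(cells$nucleus_mean, cells$cytosol_mean, thresholds)
  counts <- table(categories)
  structure(list(counts = setNames(as.integer(counts), names(counts)),
                 fractions = setNames(as.numeric(counts) / nrow(cells),
                                      names(counts)),
                 n = nrow(cells),
                 fraction_active =
                   as.numeric(counts["active"]) / nrow(cells)),
            class = "nfat_summary")
}

#' @export
print.nfat_summary <- function(x, ...) {
  cat(sprintf(
    "<nfat_summary> %d cells: inactive %.1f%%, homogeneous %.1f%%, active %.1f%%\n",
    x$n, 100 * x$fractions["inactive"], 100 * x$fractions["homogeneous"],
    100 * x$fractions["active"]))
  invisible(x)
}

#' Per-cell nucleus/cytosol means from label masks
#'
#' @param image Intensity raster.
#' @param nucleus_labels,cytosol_labels Integer label rasters (0 =
#'   background; equal positive labels mark the same cell in both masks).
#' @param background Scalar background subtracted from the raw means.
#' @return Data frame with `cell`, `nucleus_mean`, `cytosol_mean`, `ratio`.
#' @export
nfat_cell_ratios <- function(image, nucleus_labels, cytosol_labels,
                             background = 0) {
  ids <- sort(setdiff(unique(as.vector(nucleus_labels)), 0))
  if (!length(ids)) stop("no labelled nuclei")
  res <- lapply(ids, function(id) {
    nm <- mean(image[nucleus_labels == id]) - background
    cm <- mean(image[cytosol_labels == id]) - background
    data.frame(cell = id, nucleus_mean = nm, cytosol_mean = cm,
               ratio = nm / cm)
  })
  do.call(rbind, res)
}

#' Read / write a grayscale intensity raster as TIFF
#'
#' 16-bit grayscale by default; intensities are stored and returned as
#' integer counts in `[0, 65535]`.
#'
#' @param path TIFF file.
#' @param raster Numeric matrix of counts for writing.
#' @return `read_image`: numeric matrix of counts.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname read_image
#' @export
write_image <- function(raster, path) {
  stopifnot(all(raster >= 0), all(raster <= 65535))
  tiff::writeTIFF(round(raster) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
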