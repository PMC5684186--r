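#' Construct a hyperspectral cube
#'
#' A `hypercube` holds a 3-D intensity or reflectance array with its
#' wavelength axis and pixel-footprint metadata. The spatial layout is
#' rows x cols x bands; rows index the scan (stage-motion) direction of a
#' push-broom instrument and cols the across-track detector positions.
#'
#' @param data numeric array, rows x cols x bands. Raw intensities must be
#'   non-negative; reflectance cubes may contain `NA` where the reference
#'   pair was degenerate (white == dark).
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, length equal to `dim(data)[3]`.
#' @param pixel_size_um pixel footprint edge length in micrometres
#'   (default 156, the nominal footprint of a 50 mm field of view across
#'   320 detector positions).
#' @param kind `"raw"` (detector counts) or `"reflectance"` (relative
#'   reflectance against a white/dark reference pair).
#' @return An object of class `hypercube`.
#' @seealso [compute_reflectance()], [crop_wavelengths()], [read_envi_cube()]
#' @export
hypercube <- function(data, wavelengths, pixel_size_um = 156,
                      kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x bands)", call. = FALSE)
  storage.mode(data) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stop("band count (", dim(data)[3], ") != length(wavelengths) (",
         length(wavelengths), ")", call. = FALSE)
  if (length(wavelengths) == 0L)
    stop("cube must have at least one band", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  if (kind == "raw" && any(data < 0, na.rm = TRUE))
    stop("raw intensities must be >= 0", call. = FALSE)
  structure(list(data = data, wavelengths = wavelengths,
                 pixel_size_um = pixel_size_um, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Construct a white/dark reference pair
#'
#' White and dark references of a push-broom line scanner are single line
#' scans (a white plate and a capped lens), so they are stored as
#' cols x bands matrices and broadcast along the scan direction when a
#' cube is calibrated.
#'
#' @param white,dark numeric cols x bands matrices of detector counts.
#'   `white >= dark` elementwise is required on the valid sensor region.
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(white, dark) {
  white <- as.matrix(white); dark <- as.matrix(dark)
  if (!identical(dim(white), dim(dark)))
    stop("white and dark references must have identical dimensions",
         call. = FALSE)
  if (any(white < dark, na.rm = TRUE))
    stop("white reference must be >= dark reference elementwise",
         call. = FALSE)
  structure(list(white = white, dark = dark), class = "reference_pair")
}

#' Convert raw counts to relative reflectance
#'
#' Relative reflectance of a sample pixel is its count normalised between
#' the dark and white reference at the same detector position and band:
#' `R = (S - B) / (W - B)`. Pixels where the references coincide
#' (`W == B`, a dead detector element) carry `NA` rather than Inf and are
#' excluded from all downstream statistics.
#'
#' @param sample a raw-kind [hypercube()].
#' @param refs a [reference_pair()] with `cols x bands` geometry matching
#'   the sample cube.
#' @return A reflectance-kind `hypercube` of the same spatial geometry.
#' @export
compute_reflectance <- function(sample, refs) {
  stopifnot(inherits(sample, "hypercube"), inherits(refs, "reference_pair"))
  if (sample$kind != "raw")
    stop("`sample` must be a raw-kind cube", call. = FALSE)
  d <- dim(sample$data)
  if (!identical(dim(refs$white), c(d[2], d[3])))
    stop("reference geometry (", paste(dim(refs$white), collapse = " x "),
         ") does not match cube cols x bands (", d[2], " x ", d[3], ")",
         call. = FALSE)
  denom <- refs$white - refs$dark
  bad <- !(denom > 0)                      # W == B: undefined reflectance
  out <- array(NA_real_, d)
  for (b in seq_len(d[3])) {
    num <- sweep(sample$data[, , b, drop = FALSE][, , 1], 2, refs$dark[, b])
    r <- sweep(num, 2, denom[, b], "/")
    if (any(bad[, b])) r[, bad[, b]] <- NA_real_
    out[, , b] <- r
  }
  hypercube(out, sample$wavelengths, sample$pixel_size_um,
            kind = "reflectance")
}

#' Crop the wavelength axis of a cube
#'
#' Retains exactly the bands whose wavelength lies in the closed interval
#' `[lo_nm, hi_nm]`, preserving order.
#'
#' @param cube a [hypercube()].
#' @param lo_nm,hi_nm interval bounds in nm, `lo_nm < hi_nm`.
#' @return A `hypercube` restricted to the selected bands.
#' @export
crop_wavelengths <- function(cube, lo_nm, hi_nm) {
  stopifnot(inherits(cube, "hypercube"))
  if (!(lo_nm < hi_nm)) stop("`lo_nm` must be < `hi_nm`", call. = FALSE)
  keep <- which(cube$wavelengths >= lo_nm & cube$wavelengths <= hi_nm)
  if (length(keep) == 0L)
    stop("no band falls inside [", lo_nm, ", ", hi_nm, "] nm", call. = FALSE)
  hypercube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
            cube$pixel_size_um, cube$kind)
}

#' Construct a leaf mask
#'
#' @param mask logical rows x cols matrix; `TRUE` marks leaf pixels.
#' @return An object of class `leaf_mask` (a logical matrix).
#' @export
leaf_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  mask[is.na(mask)] <- FALSE
  structure(mask, class = c("leaf_mask", "matrix", "array"))
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask> %d x %d, %d leaf pixels\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Number of leaf pixels in a mask
#' @param mask a [leaf_mask()].
#' @return Integer count of `TRUE` entries.
#' @export
n_leaf_pixels <- function(mask) sum(unclass(mask))

#' Segment the leaf from the background
#'
#' Thresholds the reflectance at the band nearest `band_nm` and keeps the
#' largest 4-connected component, with holes filled. The default band sits
#' in the 1,450 nm water absorption feature, where a hydrated leaf is much
#' darker than a dry background, so `leaf = reflectance < threshold` with
#' `comparison = "below"`.
#'
#' @param cube reflectance-kind [hypercube()].
#' @param band_nm wavelength (nm) of the thresholding band; the nearest
#'   band is used. Default 1450.
#' @param threshold reflectance threshold. Default 0.5.
#' @param comparison `"below"` (leaf darker than background, default) or
#'   `"above"`.
#' @return A [leaf_mask()]. If no pixel passes the threshold an empty mask
#'   is returned with a warning.
#' @export
segment_leaf <- function(cube, band_nm = 1450, threshold = 0.5,
                         comparison = c("below", "above")) {
  stopifnot(inherits(cube, "hypercube"))
  comparison <- match.arg(comparison)
  if (band_nm < min(cube$wavelengths) || band_nm > max(cube$wavelengths))
    stop("`band_nm` outside the cube's wavelength range", call. = FALSE)
  b <- which.min(abs(cube$wavelengths - band_nm))
  img <- cube$data[, , b]
  m <- if (comparison == "below") img < threshold else img > threshold
  m[is.na(m)] <- FALSE
  if (!any(m)) {
    warning("segmentation produced an empty mask", call. = FALSE)
    return(leaf_mask(m))
  }
  lab <- EBImage::bwlabel(m)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  m <- lab == keep
  m <- EBImage::fillHull(m) > 0
  leaf_mask(matrix(as.logical(m), nrow(img), ncol(img)))
}
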