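#' Construct a spectrum matrix
#'
#' Spectra are stored as a plain numeric matrix (one row per sample, one
#' column per band) carrying the wavelength axis as the `"wavelengths"`
#' attribute, following the flat-matrix convention of chemometrics codes.
#'
#' @param values numeric matrix or vector (a vector becomes a single row).
#' @param wavelengths numeric band axis in nm, one entry per column.
#' @return A matrix of class `spectrum_matrix`.
#' @export
spectrum_matrix <- function(values, wavelengths) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(values) != length(wavelengths))
    stop("column count (", ncol(values), ") != wavelength count (",
         length(wavelengths), ")", call. = FALSE)
  if (any(!is.finite(values)))
    stop("spectrum matrix must be finite", call. = FALSE)
  structure(values, wavelengths = wavelengths,
            class = c("spectrum_matrix", "matrix", "array"))
}

#' Wavelength axis of a spectrum matrix
#' @param m a [spectrum_matrix()].
#' @return Numeric vector of band wavelengths (nm).
#' @export
wavelengths <- function(m) attr(m, "wavelengths")

#' Standard normal variate transform
#'
#' Centres each spectrum (row) to mean 0 and scales it to unit sample
#' standard deviation (`n - 1` denominator). SNV removes per-sample
#' multiplicative scatter and additive offset; it is invariant to the
#' affine map `a * x + b` for `a > 0`, and idempotent.
#'
#' @param m a [spectrum_matrix()] whose rows each have nonzero sd.
#' @return The transformed `spectrum_matrix`.
#' @export
snv <- function(m) {
  stopifnot(inherits(m, "spectrum_matrix"))
  mu <- rowMeans(m)
  sd_ <- apply(m, 1, stats::sd)
  degenerate <- sd_ == 0 | !is.finite(sd_)
  if (any(degenerate))
    stop("SNV undefined for constant spectrum in row(s): ",
         paste(which(degenerate), collapse = ", "), call. = FALSE)
  spectrum_matrix((m - mu) / sd_, wavelengths(m))
}

#' Gap-segment first derivative
#'
#' Noise-robust finite difference: for each output position the derivative
#' is the mean of an upper segment of `segment` points minus the mean of a
#' lower segment of `segment` points, the two segments separated by `gap`
#' skipped points, divided by the centre-to-centre separation
#' `segment + gap` in index units (so a line of unit slope per band index
#' yields exactly 1). The band axis shrinks to the positions where both
#' segments fit (`n - 2 * segment - gap + 1` bands), and the wavelength
#' axis shrinks identically, taking the wavelength at the centre of each
#' derivative window.
#'
#' @param m a [spectrum_matrix()].
#' @param gap number of skipped points between the segments, >= 1.
#' @param segment segment length in points, >= 1.
#' @return A `spectrum_matrix` with `n_bands - 2 * segment - gap + 1`
#'   columns.
#' @export
gap_segment_first_derivative <- function(m, gap = 1L, segment = 2L) {
  stopifnot(inherits(m, "spectrum_matrix"))
  gap <- as.integer(gap); segment <- as.integer(segment)
  if (gap < 1L || segment < 1L)
    stop("`gap` and `segment` must be >= 1", call. = FALSE)
  nb <- ncol(m)
  span <- 2L * segment + gap
  if (nb < span)
    stop("derivative window (", span, " points) does not fit in ", nb,
         " bands", call. = FALSE)
  n_out <- nb - span + 1L
  sep <- segment + gap
  lower <- matrix(0, nrow(m), n_out)
  upper <- matrix(0, nrow(m), n_out)
  for (s in seq_len(segment)) {
    lower <- lower + m[, s:(s + n_out - 1L), drop = FALSE]
    upper <- upper + m[, (segment + gap + s):(segment + gap + s + n_out - 1L),
                       drop = FALSE]
  }
  d <- (upper - lower) / (segment * sep)
  # window centre: midpoint between the two segment centres
  centre <- (span - 1) / 2
  wl <- wavelengths(m)
  wl_out <- vapply(seq_len(n_out), function(j) {
    idx <- j + centre
    lo <- floor(idx); hi <- ceiling(idx)
    (wl[lo] + wl[hi]) / 2
  }, numeric(1))
  spectrum_matrix(d, wl_out)
}

#' Crop a spectrum matrix to a wavelength interval
#'
#' @param m a [spectrum_matrix()].
#' @param lo_nm,hi_nm closed interval bounds in nm.
#' @return The cropped `spectrum_matrix`.
#' @export
crop_spectra <- function(m, lo_nm, hi_nm) {
  stopifnot(inherits(m, "spectrum_matrix"))
  if (!(lo_nm < hi_nm)) stop("`lo_nm` must be < `hi_nm`", call. = FALSE)
  wl <- wavelengths(m)
  keep <- which(wl >= lo_nm & wl <= hi_nm)
  if (length(keep) == 0L)
    stop("no band falls inside [", lo_nm, ", ", hi_nm, "] nm", call. = FALSE)
  spectrum_matrix(m[, keep, drop = FALSE], wl[keep])
}

#' Mean spectrum over a masked region of a cube
#'
#' Per-band arithmetic mean over the pixels selected by the mask, with
#' invalid (`NA`) pixels excluded band-wise.
#'
#' @param cube a [hypercube()].
#' @param region a [leaf_mask()] matching the cube's spatial dimensions.
#' @return A single-row [spectrum_matrix()].
#' @export
mean_spectrum <- function(cube, region) {
  stopifnot(inherits(cube, "hypercube"))
  m <- unclass(region)
  d <- dim(cube$data)
  if (!identical(dim(m), d[1:2]))
    stop("mask shape does not match cube spatial dimensions", call. = FALSE)
  if (!any(m)) stop("region is empty", call. = FALSE)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  sel <- flat[as.vector(m), , drop = FALSE]
  mu <- colMeans(sel, na.rm = TRUE)
  if (any(!is.finite(mu)))
    stop("region has no valid pixel in some band", call. = FALSE)
  spectrum_matrix(matrix(mu, 1), cube$wavelengths)
}

#' Build a preprocessing recipe
#'
#' A recipe is an ordered list of steps drawn from `step_crop()`,
#' `step_snv()` and `step_derivative()`, applied left to right by
#' [apply_recipe()]. The default calibration recipe crops to the working
#' 932.1-2,217.8 nm window, applies SNV, then a gap-segment first
#' derivative with gap 1 and segment 2.
#'
#' @param ... recipe steps, in application order.
#' @return An object of class `preprocess_recipe`.
#' @examples
#' r <- preprocess_recipe(step_crop(932.1, 2217.8), step_snv(),
#'                        step_derivative(1, 2))
#' @export
preprocess_recipe <- function(...) {
  steps <- list(...)
  ok <- vapply(steps, function(s) inherits(s, "recipe_step"), logical(1))
  if (length(steps) && !all(ok))
    stop("all recipe arguments must be recipe steps", call. = FALSE)
  structure(list(steps = steps), class = "preprocess_recipe")
}

#' @rdname preprocess_recipe
#' @param lo_nm,hi_nm crop bounds in nm.
#' @export
step_crop <- function(lo_nm, hi_nm) {
  if (!(lo_nm < hi_nm)) stop("`lo_nm` must be < `hi_nm`", call. = FALSE)
  structure(list(type = "crop", lo_nm = lo_nm, hi_nm = hi_nm),
            class = "recipe_step")
}

#' @rdname preprocess_recipe
#' @export
step_snv <- function() structure(list(type = "snv"), class = "recipe_step")

#' @rdname preprocess_recipe
#' @param gap,segment gap-segment derivative parameters, each >= 1.
#' @export
step_derivative <- function(gap = 1L, segment = 2L) {
  if (gap < 1 || segment < 1)
    stop("`gap` and `segment` must be >= 1", call. = FALSE)
  structure(list(type = "derivative", gap = as.integer(gap),
                 segment = as.integer(segment)), class = "recipe_step")
}

#' @rdname preprocess_recipe
#' @export
default_recipe <- function() {
  preprocess_recipe(step_crop(932.1, 2217.8), step_snv(),
                    step_derivative(1L, 2L))
}

#' @export
print.preprocess_recipe <- function(x, ...) {
  if (!length(x$steps)) { cat("<preprocess_recipe> (identity)\n") }
  else {
    lab <- vapply(x$steps, function(s) switch(s$type,
      crop = sprintf("crop[%.1f, %.1f]", s$lo_nm, s$hi_nm),
      snv = "snv",
      derivative = sprintf("derivative(gap=%d, segment=%d)", s$gap,
                           s$segment)), character(1))
    cat("<preprocess_recipe>", paste(lab, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Apply a preprocessing recipe to spectra
#'
#' Steps are applied in listed order; every step is row-independent, so
#' the result for a sample does not depend on which other samples share
#' the matrix.
#'
#' @param m a [spectrum_matrix()].
#' @param recipe a [preprocess_recipe()].
#' @return The transformed `spectrum_matrix` (its wavelength axis reflects
#'   crops and derivative shrinkage).
#' @export
apply_recipe <- function(m, recipe) {
  stopifnot(inherits(m, "spectrum_matrix"),
            inherits(recipe, "preprocess_recipe"))
  for (s in recipe$steps) {
    m <- switch(s$type,
      crop = crop_spectra(m, s$lo_nm, s$hi_nm),
      snv = snv(m),
      derivative = gap_segment_first_derivative(m, s$gap, s$segment),
      stop("unknown recipe step type: ", s$type, call. = FALSE))
  }
  m
}

# Serialise/deserialise a recipe to a plain list (for JSON model storage).
recipe_to_list <- function(recipe) {
  lapply(recipe$steps, function(s) unclass(s))
}

recipe_from_list <- function(lst) {
  steps <- lapply(lst, function(s) {
    switch(s$type,
      crop = step_crop(s$lo_nm, s$hi_nm),
      snv = step_snv(),
      derivative = step_derivative(s$gap, s$segment),
      stop("unknown recipe step type: ", s$type, call. = FALSE))
  })
  do.call(preprocess_recipe, steps)
}
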