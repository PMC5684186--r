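#' Construct a concentration map
#'
#' A 2-D field of predicted concentrations (mg/kg) defined only inside a
#' leaf mask; background pixels carry `NA`. Values are clipped to
#' `clip_bounds` at construction, with the number of clipped pixels
#' recorded.
#'
#' @param values numeric rows x cols matrix of predictions.
#' @param mask a [leaf_mask()] of the same shape.
#' @param clip_bounds length-2 numeric `(lo, hi)`; use
#'   `c(-Inf, Inf)` to disable clipping.
#' @param provenance optional list of provenance fields (model id,
#'   recipe description) carried along unchanged.
#' @return An object of class `concentration_map`.
#' @export
concentration_map <- function(values, mask, clip_bounds = c(-Inf, Inf),
                              provenance = list()) {
  stopifnot(is.matrix(values))
  m <- unclass(mask)
  if (!identical(dim(values), dim(m)))
    stop("values and mask shapes differ", call. = FALSE)
  if (length(clip_bounds) != 2L || clip_bounds[1] > clip_bounds[2])
    stop("`clip_bounds` must be (lo, hi) with lo <= hi", call. = FALSE)
  values[!m] <- NA_real_
  inmask <- values[m]
  n_clipped <- sum(inmask < clip_bounds[1] | inmask > clip_bounds[2],
                   na.rm = TRUE)
  values[m] <- pmin(pmax(values[m], clip_bounds[1]), clip_bounds[2])
  structure(list(values = values, mask = leaf_mask(m),
                 clip_bounds = clip_bounds, n_clipped = n_clipped,
                 provenance = provenance),
            class = "concentration_map")
}

#' @export
print.concentration_map <- function(x, ...) {
  v <- x$values[unclass(x$mask)]
  cat(sprintf(
    "<concentration_map> %d x %d, %d leaf pixels, %.0f-%.0f mg/kg (%d clipped)\n",
    nrow(x$values), ncol(x$values), sum(unclass(x$mask)),
    min(v, na.rm = TRUE), max(v, na.rm = TRUE), x$n_clipped))
  invisible(x)
}

#' Map nitrate concentration pixel-wise over a leaf
#'
#' For every in-mask pixel the spectrum is extracted, the model's stored
#' preprocessing recipe applied, and the model evaluated; out-of-mask
#' pixels carry no value. Predictions are clipped to `clip_bounds`
#' (default `[0, 1.5 x]` the calibration maximum encoded in the bounds
#' argument by the caller) and the clipped-pixel count is recorded.
#' Pixels are processed in blocks of `block_size` spectra; because every
#' preprocessing step is row-independent, the result is independent of
#' the block size.
#'
#' @param cube reflectance-kind [hypercube()], already destriped.
#' @param model a `pls_model` whose recipe applies to the cube's
#'   wavelength axis.
#' @param mask a [leaf_mask()].
#' @param clip_bounds length-2 numeric; default `c(0, Inf)`.
#' @param block_size spectra per prediction block (default 4096).
#' @return A [concentration_map()].
#' @export
map_concentration <- function(cube, model, mask, clip_bounds = c(0, Inf),
                              block_size = 4096L) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "pls_model"))
  d <- dim(cube$data)
  m <- unclass(mask)
  if (!identical(dim(m), d[1:2]))
    stop("mask shape does not match cube", call. = FALSE)
  idx <- which(as.vector(m))
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  preds <- rep(NA_real_, length(idx))
  for (start in seq(1L, length(idx), by = block_size)) {
    stop_ <- min(start + block_size - 1L, length(idx))
    block <- flat[idx[start:stop_], , drop = FALSE]
    valid <- rowSums(!is.finite(block)) == 0L
    if (!any(valid)) next
    sm <- spectrum_matrix(block[valid, , drop = FALSE], cube$wavelengths)
    if (!is.null(model$recipe)) sm <- apply_recipe(sm, model$recipe)
    preds[(start:stop_)[valid]] <- predict(model, sm)
  }
  vals <- matrix(NA_real_, d[1], d[2])
  vals[idx] <- preds
  concentration_map(vals, mask, clip_bounds = clip_bounds,
                    provenance = list(
                      n_factors = model$n_factors,
                      recipe = if (is.null(model$recipe)) "none" else
                        paste(utils::capture.output(print(model$recipe)),
                              collapse = "")))
}

#' Mean concentration over a region
#'
#' @param map a [concentration_map()].
#' @param region a [leaf_mask()] selecting the region; it is intersected
#'   with the map's own mask.
#' @return Scalar mean in mg/kg.
#' @export
region_mean <- function(map, region) {
  stopifnot(inherits(map, "concentration_map"))
  sel <- unclass(map$mask) & unclass(region)
  v <- map$values[sel]
  v <- v[is.finite(v)]
  if (length(v) == 0L)
    stop("region does not intersect the mapped leaf", call. = FALSE)
  mean(v)
}

#' Render a concentration map to PNG and numeric CSV
#'
#' Writes a false-colour PNG (background neutral grey) and, alongside it,
#' a lossless CSV matrix of the mapped values with empty cells for
#' background, so the numbers behind the figure are always recoverable.
#'
#' @param map a [concentration_map()].
#' @param png_path output PNG path (`NULL` to skip).
#' @param csv_path output CSV path; defaults to the PNG path with a
#'   `.csv` extension.
#' @param palette a vector of colours (default
#'   `grDevices::hcl.colors(256, "viridis")`).
#' @param limits colourbar limits `(lo, hi)`; defaults to the in-mask
#'   value range.
#' @return Invisibly, a list with the paths and limits used.
#' @export
render_map <- function(map, png_path, csv_path = NULL,
                       palette = grDevices::hcl.colors(256, "viridis"),
                       limits = NULL) {
  stopifnot(inherits(map, "concentration_map"))
  if (is.null(csv_path) && !is.null(png_path))
    csv_path <- sub("\\.png$", ".csv", png_path)
  v <- map$values
  m <- unclass(map$mask)
  if (is.null(limits)) {
    rng <- range(v[m], na.rm = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    limits <- rng
  }
  if (!is.null(png_path)) {
    scaled <- (v - limits[1]) / (limits[2] - limits[1])
    scaled <- pmin(pmax(scaled, 0), 1)
    ci <- matrix(1L + as.integer(round(scaled * (length(palette) - 1L))),
                 nrow(v), ncol(v))
    rgb_ <- grDevices::col2rgb(palette) / 255
    img <- array(0.5, c(nrow(v), ncol(v), 3))   # neutral grey background
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m & is.finite(v)] <- rgb_[ch, ci[m & is.finite(v)]]
      img[, , ch] <- plane
    }
    png::writePNG(img, png_path)
  }
  if (!is.null(csv_path)) {
    # %.17g round-trips IEEE doubles exactly; background cells are empty
    lines <- apply(v, 1, function(row) {
      s <- sprintf("%.17g", row)
      s[!is.finite(row)] <- ""
      paste(s, collapse = ",")
    })
    writeLines(lines, csv_path)
  }
  invisible(list(png = png_path, csv = csv_path, limits = limits))
}

#' Read back the numeric CSV written by [render_map()]
#'
#' @param csv_path path to the CSV matrix.
#' @return Numeric matrix with `NA` for background cells.
#' @export
read_map_csv <- function(csv_path) {
  m <- as.matrix(utils::read.table(csv_path, sep = ",", header = FALSE,
                                   na.strings = "", colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}
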