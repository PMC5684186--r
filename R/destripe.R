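#' Stripe filter configuration
#'
#' Push-broom scanners image one spatial line per exposure while the stage
#' moves; per-column detector gain drift therefore produces stripes running
#' along the stage-motion (scan) direction, i.e. a pattern that varies
#' across columns and is nearly constant along rows. In the 2-D Fourier
#' domain that pattern concentrates on the line of zero (and near-zero)
#' row frequency, which a narrow notch can attenuate without touching the
#' rest of the image.
#'
#' @param stripe_axis `"along-track"` (stripes constant along rows,
#'   default for a push-broom system) or `"across-track"`.
#' @param notch_half_width_bins half-width of the notch in frequency bins
#'   perpendicular to the stripe spectrum, >= 1. Default 2.
#' @param dc_guard_bins number of low-frequency bins along the stripe
#'   spectrum protected from attenuation. The guard must cover the
#'   scene's smooth column profile: a 1-bin guard would force all column
#'   means equal, erasing real structure such as a narrow petiole, so the
#'   default is 8 (stripes of period shorter than `n_cols / 8` pixels are
#'   still fully inside the notch). A guard >= 1 keeps overall brightness
#'   untouched.
#' @param attenuation multiplicative factor in `[0, 1]` applied inside the
#'   notch; 0 removes the stripe frequencies, 1 is a no-op. Default 0.
#' @return An object of class `stripe_filter_config`.
#' @export
stripe_filter_config <- function(stripe_axis = c("along-track",
                                                 "across-track"),
                                 notch_half_width_bins = 2L,
                                 dc_guard_bins = 8L,
                                 attenuation = 0) {
  stripe_axis <- match.arg(stripe_axis)
  notch_half_width_bins <- as.integer(notch_half_width_bins)
  dc_guard_bins <- as.integer(dc_guard_bins)
  if (notch_half_width_bins < 1L)
    stop("`notch_half_width_bins` must be >= 1", call. = FALSE)
  if (dc_guard_bins < 0L)
    stop("`dc_guard_bins` must be >= 0", call. = FALSE)
  if (!is.numeric(attenuation) || attenuation < 0 || attenuation > 1)
    stop("`attenuation` must lie in [0, 1]", call. = FALSE)
  structure(list(stripe_axis = stripe_axis,
                 notch_half_width_bins = notch_half_width_bins,
                 dc_guard_bins = dc_guard_bins,
                 attenuation = attenuation),
            class = "stripe_filter_config")
}

# Frequency-bin index distances from DC for an axis of length n
# (0, 1, 2, ..., floor(n/2), ..., 2, 1 pattern).
freq_bin_dist <- function(n) {
  k <- 0:(n - 1)
  pmin(k, n - k)
}

# Logical mask of the stripe-frequency region for an nr x nc image.
# Stripes along rows live at near-zero row frequency and non-trivial
# column frequency; "across-track" swaps the roles.
stripe_region <- function(nr, nc, cfg) {
  dr <- freq_bin_dist(nr)
  dc <- freq_bin_dist(nc)
  if (cfg$stripe_axis == "along-track") {
    near_axis <- matrix(dr < cfg$notch_half_width_bins, nr, nc)
    guarded <- matrix(dc < max(cfg$dc_guard_bins, 1L), nr, nc,
                      byrow = TRUE)
  } else {
    near_axis <- matrix(dc < cfg$notch_half_width_bins, nr, nc,
                        byrow = TRUE)
    guarded <- matrix(dr < max(cfg$dc_guard_bins, 1L), nr, nc)
  }
  near_axis & !guarded
}

#' Remove stripe noise from a band image by Fourier notch filtering
#'
#' Computes the 2-D discrete Fourier transform, multiplies the
#' stripe-frequency region (near-zero frequency along the stripe direction,
#' outside the DC guard, with a cosine-tapered notch edge) by the
#' configured attenuation, and inverse-transforms, discarding the
#' imaginary residue. `NA` pixels are mean-inpainted before the transform
#' and restored afterwards.
#'
#' @param image numeric matrix (one band, rows x cols).
#' @param cfg a [stripe_filter_config()].
#' @return A real matrix of the same shape.
#' @export
destripe_fft <- function(image, cfg = stripe_filter_config()) {
  stopifnot(is.matrix(image), inherits(cfg, "stripe_filter_config"))
  nr <- nrow(image); nc <- ncol(image)
  na_mask <- !is.finite(image)
  if (all(na_mask)) {
    warning("image has no valid pixels; returning unchanged", call. = FALSE)
    return(image)
  }
  work <- image
  if (any(na_mask)) work[na_mask] <- mean(image[!na_mask])
  hw <- cfg$notch_half_width_bins
  dr <- freq_bin_dist(nr); dc <- freq_bin_dist(nc)
  # attenuation profile across the notch: full inside, cosine-tapered at
  # the edge bin, 1 outside
  taper <- function(d) {
    w <- rep(1, length(d))
    inside <- d < hw
    w[inside] <- cfg$attenuation
    edge <- d == hw
    w[edge] <- cfg$attenuation + (1 - cfg$attenuation) / 2
    w
  }
  if (cfg$stripe_axis == "along-track") {
    gain <- matrix(taper(dr), nr, nc)
    guard <- matrix(dc < max(cfg$dc_guard_bins, 1L), nr, nc, byrow = TRUE)
  } else {
    gain <- matrix(taper(dc), nr, nc, byrow = TRUE)
    guard <- matrix(dr < max(cfg$dc_guard_bins, 1L), nr, nc)
  }
  gain[guard] <- 1
  fw <- stats::fft(work)
  out <- Re(stats::fft(fw * gain, inverse = TRUE)) / (nr * nc)
  out[na_mask] <- NA_real_
  out
}

#' Destripe every band of a cube
#'
#' Applies [destripe_fft()] band by band; the wavelength axis is unchanged.
#'
#' @param cube a [hypercube()].
#' @param cfg a [stripe_filter_config()].
#' @return A `hypercube` of the same kind and geometry.
#' @export
destripe_cube <- function(cube, cfg = stripe_filter_config()) {
  stopifnot(inherits(cube, "hypercube"))
  out <- cube$data
  for (b in seq_len(dim(out)[3]))
    out[, , b] <- destripe_fft(out[, , b], cfg)
  # raw cubes may pick up tiny negative ringing; keep kind by flooring at 0
  if (cube$kind == "raw") out[out < 0] <- 0
  hypercube(out, cube$wavelengths, cube$pixel_size_um, cube$kind)
}

#' Fraction of image spectral energy in the stripe-frequency region
#'
#' Sum of squared Fourier magnitudes over the same frequency region the
#' notch filter attenuates, normalised by total spectral energy excluding
#' the DC bin. A constant image scores 0; a pure column-sinusoid scores 1.
#'
#' @param image numeric matrix; `NA` pixels are mean-inpainted.
#' @param cfg a [stripe_filter_config()] defining the region (only
#'   `stripe_axis`, `notch_half_width_bins` and `dc_guard_bins` matter).
#' @return A scalar in `[0, 1]`.
#' @export
stripe_energy <- function(image, cfg = stripe_filter_config()) {
  stopifnot(is.matrix(image))
  na_mask <- !is.finite(image)
  if (all(na_mask)) return(0)
  if (any(na_mask)) image[na_mask] <- mean(image[!na_mask])
  fw <- stats::fft(image)
  p <- Mod(fw)^2
  total <- sum(p) - p[1, 1]                 # exclude DC
  if (total <= 0) return(0)
  region <- stripe_region(nrow(image), ncol(image), cfg)
  sum(p[region]) / total
}

#' Report stripe-energy reduction of a filtering step
#'
#' @param before,after band images before and after destriping.
#' @param cfg a [stripe_filter_config()].
#' @return A list with `stripe_energy_before`, `stripe_energy_after` and
#'   `reduction_fraction` (`1 - after/before`; `NA` when `before == 0`).
#' @export
stripe_report <- function(before, after, cfg = stripe_filter_config()) {
  eb <- stripe_energy(before, cfg)
  ea <- stripe_energy(after, cfg)
  structure(list(stripe_energy_before = eb, stripe_energy_after = ea,
                 reduction_fraction = if (eb > 0) 1 - ea / eb else NA_real_),
            class = "stripe_report")
}

#' Smooth a concentration map across the stripe direction
#'
#' Directional moving average applied inside the leaf mask only: each leaf
#' pixel is replaced by the mean of the leaf pixels inside a centred
#' window taken across columns for `"along-track"` stripes (the direction
#' in which the stripe pattern varies). Background pixels are never mixed
#' in and remain unchanged.
#'
#' @param map a [concentration_map()].
#' @param window odd window length >= 1.
#' @param stripe_axis direction the stripes run in, as in
#'   [stripe_filter_config()]; smoothing is applied perpendicular to it
#'   (across columns for `"along-track"`).
#' @return A smoothed `concentration_map`.
#' @export
smooth_map <- function(map, window = 5L,
                       stripe_axis = c("along-track", "across-track")) {
  stopifnot(inherits(map, "concentration_map"))
  stripe_axis <- match.arg(stripe_axis)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  v <- map$values
  m <- unclass(map$mask)
  axis_len <- if (stripe_axis == "along-track") ncol(v) else nrow(v)
  if (window > axis_len)
    stop("`window` exceeds the image extent along the smoothing axis",
         call. = FALSE)
  if (window == 1L) return(map)
  half <- (window - 1L) %/% 2L
  num <- matrix(0, nrow(v), ncol(v))
  den <- matrix(0, nrow(v), ncol(v))
  vz <- ifelse(m & is.finite(v), v, 0)
  mz <- (m & is.finite(v)) * 1
  for (off in -half:half) {
    if (stripe_axis == "along-track") {
      cols <- seq_len(ncol(v)) + off
      ok <- cols >= 1 & cols <= ncol(v)
      num[, ok] <- num[, ok] + vz[, cols[ok]]
      den[, ok] <- den[, ok] + mz[, cols[ok]]
    } else {
      rows <- seq_len(nrow(v)) + off
      ok <- rows >= 1 & rows <= nrow(v)
      num[ok, ] <- num[ok, ] + vz[rows[ok], ]
      den[ok, ] <- den[ok, ] + mz[rows[ok], ]
    }
  }
  out <- v
  valid <- m & den > 0
  out[valid] <- num[valid] / den[valid]
  map$values <- out
  map
}
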