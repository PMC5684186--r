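#' Configuration of the synthetic leaf/spectra generator
#'
#' The generator produces mixture spectra from a Beer-Lambert-like forward
#' model: absorbance `A = baseline + (c / c_ref) * analyte + sum(s_j *
#' interferent_j)` on the configured wavelength axis, converted to
#' reflectance as `R = m * 10^(-A) + o + eps` with a per-sample
#' multiplicative scatter factor `m`, additive offset `o`, and band-wise
#' Gaussian noise `eps`. Each distortion exercises one preprocessing step:
#' SNV removes `m` and `o`, the gap-segment derivative removes smooth
#' baselines, the Fourier notch removes the column-gain stripes applied to
#' phantom cubes.
#'
#' The analyte signature is a sum of Gaussian absorption peaks (default
#' centres near 1,500 and 2,050 nm); interferents emulate the dominant
#' water bands near 1,450 and 1,940 nm. Default blade concentrations span
#' the calibration range 2,178-8,767 mg/kg; vein and petiole defaults sit
#' above 10,000 mg/kg, beyond the calibration ceiling, as in real leaves.
#'
#' @param n_bands number of bands (default 256).
#' @param wavelength_start_nm first band centre (default 913).
#' @param wavelength_step_nm band spacing (default 6.2).
#' @param analyte_peaks data frame `center_nm`, `width_nm`, `amplitude`
#'   describing the analyte absorption signature.
#' @param analyte_strength absorbance of the unit-amplitude signature at
#'   the reference concentration `c_ref_mg_kg` (default 0.15).
#' @param c_ref_mg_kg normalising concentration (default 5,000, mid
#'   calibration range).
#' @param interferent_peaks data frame as `analyte_peaks` for the
#'   water-like interferents.
#' @param interferent_sd relative sd of the per-sample interferent
#'   strength (default 0.15).
#' @param baseline_coef polynomial coefficients (intercept first) of the
#'   absorbance baseline over the normalised axis position in `[0, 1]`.
#' @param blade_range_mg_kg,vein_range_mg_kg,petiole_range_mg_kg
#'   concentration ranges per tissue, mg/kg.
#' @param scatter_range multiplicative scatter factor range (default
#'   `c(0.85, 1.15)`).
#' @param offset_sd sd of the additive reflectance offset (default 0.01).
#' @param noise_sd band-wise Gaussian reflectance noise sd (default
#'   0.004).
#' @param stripe_amplitude relative column-gain stripe amplitude applied
#'   to phantom cubes (default 0.1); `stripe_period` its period in
#'   columns (default 4).
#' @param background_reflectance flat background (stage) reflectance
#'   (default 0.85).
#' @param white_level,dark_level reference counts used when composing raw
#'   phantom cubes (defaults 3000 and 100).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_bands = 256L,
                           wavelength_start_nm = 913,
                           wavelength_step_nm = 6.2,
                           analyte_peaks = data.frame(
                             center_nm = c(1500, 2050),
                             width_nm = c(45, 60),
                             amplitude = c(1, 0.7)),
                           analyte_strength = 0.15,
                           c_ref_mg_kg = 5000,
                           interferent_peaks = data.frame(
                             center_nm = c(1450, 1940),
                             width_nm = c(55, 80),
                             amplitude = c(0.35, 0.45)),
                           interferent_sd = 0.15,
                           baseline_coef = c(0.25, 0.12, -0.06),
                           blade_range_mg_kg = c(2178, 8767),
                           vein_range_mg_kg = c(11000, 13000),
                           petiole_range_mg_kg = c(13000, 15000),
                           scatter_range = c(0.85, 1.15),
                           offset_sd = 0.01,
                           noise_sd = 0.004,
                           stripe_amplitude = 0.1,
                           stripe_period = 4,
                           background_reflectance = 0.85,
                           white_level = 3000,
                           dark_level = 100) {
  cfg <- list(n_bands = as.integer(n_bands),
              wavelength_start_nm = wavelength_start_nm,
              wavelength_step_nm = wavelength_step_nm,
              analyte_peaks = analyte_peaks,
              analyte_strength = analyte_strength,
              c_ref_mg_kg = c_ref_mg_kg,
              interferent_peaks = interferent_peaks,
              interferent_sd = interferent_sd,
              baseline_coef = baseline_coef,
              blade_range_mg_kg = blade_range_mg_kg,
              vein_range_mg_kg = vein_range_mg_kg,
              petiole_range_mg_kg = petiole_range_mg_kg,
              scatter_range = scatter_range,
              offset_sd = offset_sd,
              noise_sd = noise_sd,
              stripe_amplitude = stripe_amplitude,
              stripe_period = stripe_period,
              background_reflectance = background_reflectance,
              white_level = white_level,
              dark_level = dark_level)
  if (cfg$n_bands < 2L) stop("`n_bands` must be >= 2", call. = FALSE)
  if (cfg$wavelength_step_nm <= 0)
    stop("`wavelength_step_nm` must be > 0", call. = FALSE)
  for (rng in list(cfg$blade_range_mg_kg, cfg$vein_range_mg_kg,
                   cfg$petiole_range_mg_kg))
    if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2])
      stop("concentration ranges must be positive (lo, hi) pairs",
           call. = FALSE)
  structure(cfg, class = "phantom_config")
}

#' Wavelength axis implied by a phantom configuration
#' @param config a [phantom_config()].
#' @return Numeric vector of band centres (nm).
#' @export
phantom_wavelengths <- function(config) {
  config$wavelength_start_nm +
    config$wavelength_step_nm * (seq_len(config$n_bands) - 1)
}

# Evaluate a sum of Gaussian peaks on a wavelength axis; peaks whose
# centre falls off the axis are dropped with a warning.
gaussian_peaks <- function(wl, peaks) {
  out <- numeric(length(wl))
  if (is.null(peaks) || nrow(peaks) == 0L) return(out)
  for (i in seq_len(nrow(peaks))) {
    ctr <- peaks$center_nm[i]
    if (ctr < min(wl) || ctr > max(wl)) {
      warning("peak at ", ctr, " nm lies outside the wavelength axis; ",
              "truncated", call. = FALSE)
    }
    out <- out + peaks$amplitude[i] *
      exp(-0.5 * ((wl - ctr) / peaks$width_nm[i])^2)
  }
  out
}

#' Analyte absorbance signature on the configured axis
#'
#' @param config a [phantom_config()].
#' @return Non-negative numeric vector, one entry per band: the
#'   unit-concentration analyte absorbance (scaled by
#'   `analyte_strength`).
#' @export
make_signature <- function(config) {
  wl <- phantom_wavelengths(config)
  config$analyte_strength * gaussian_peaks(wl, config$analyte_peaks)
}

# Absorbance baseline: polynomial in the normalised axis position.
phantom_baseline <- function(config) {
  wl <- phantom_wavelengths(config)
  u <- (wl - min(wl)) / (max(wl) - min(wl))
  drop(outer(u, seq_along(config$baseline_coef) - 1, `^`) %*%
         config$baseline_coef)
}

phantom_interferents <- function(config) {
  gaussian_peaks(phantom_wavelengths(config), config$interferent_peaks)
}

# Deterministic noiseless reflectance for concentration c and interferent
# strength s (vectorised over bands).
forward_reflectance <- function(config, c_mg_kg, interferent_strength = 1,
                                scatter = 1, offset = 0) {
  A <- phantom_baseline(config) +
    (c_mg_kg / config$c_ref_mg_kg) * make_signature(config) +
    interferent_strength * phantom_interferents(config)
  scatter * 10^(-A) + offset
}

#' Generate a synthetic calibration set
#'
#' Draws `n_samples` concentrations uniformly from the blade range and
#' produces one reflectance spectrum per sample through the forward model
#' (scatter, offset, interferent variation and band noise as configured).
#'
#' @param config a [phantom_config()].
#' @param n_samples number of samples (default 210).
#' @param seed RNG seed (integer).
#' @return An object of class `calibration_table`: a list with `table`
#'   (data frame `sample_id`, `nitrate_mg_per_kg`), `spectra` (a
#'   [spectrum_matrix()]), and the generating `config` and `seed`.
#' @export
generate_calibration_set <- function(config = phantom_config(),
                                     n_samples = 210L, seed = 1L) {
  if (n_samples < 2L) stop("`n_samples` must be >= 2", call. = FALSE)
  set.seed(seed)
  wl <- phantom_wavelengths(config)
  conc <- stats::runif(n_samples, config$blade_range_mg_kg[1],
                       config$blade_range_mg_kg[2])
  base <- phantom_baseline(config)
  sig <- make_signature(config)
  intf <- phantom_interferents(config)
  spectra <- matrix(0, n_samples, config$n_bands)
  for (i in seq_len(n_samples)) {
    s <- stats::rnorm(1, 1, config$interferent_sd)
    m <- stats::runif(1, config$scatter_range[1], config$scatter_range[2])
    o <- stats::rnorm(1, 0, config$offset_sd)
    A <- base + (conc[i] / config$c_ref_mg_kg) * sig + s * intf
    spectra[i, ] <- m * 10^(-A) + o +
      stats::rnorm(config$n_bands, 0, config$noise_sd)
  }
  structure(list(
    table = data.frame(sample_id = sprintf("syn%03d", seq_len(n_samples)),
                       nitrate_mg_per_kg = conc),
    spectra = spectrum_matrix(spectra, wl),
    config = config, seed = seed),
    class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  s <- summarize_references(x)
  cat(sprintf(
    "<calibration_table> %d samples, %d bands; nitrate %.0f-%.0f mg/kg\n",
    s$n, ncol(x$spectra), s$min, s$max))
  invisible(x)
}

#' Write / read a calibration table as CSV
#'
#' Layout: `sample_id`, `nitrate_mg_per_kg`, then one column per band
#' named `wl_<nm>`.
#'
#' @param cal a `calibration_table`.
#' @param path CSV path.
#' @return `write_calibration_csv` returns the path invisibly;
#'   `read_calibration_csv` returns a `calibration_table` (without
#'   generator config).
#' @export
write_calibration_csv <- function(cal, path) {
  wl <- wavelengths(cal$spectra)
  df <- cbind(cal$table,
              as.data.frame(unclass(cal$spectra)[, , drop = FALSE]))
  names(df)[-(1:2)] <- sprintf("wl_%.1f", wl)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df))
  wl <- as.numeric(sub("^wl_", "", names(df)[wl_cols]))
  structure(list(
    table = df[, c("sample_id", "nitrate_mg_per_kg")],
    spectra = spectrum_matrix(as.matrix(df[, wl_cols]), wl),
    config = NULL, seed = NULL),
    class = "calibration_table")
}

# Procedural leaf geometry: superellipse blade + tapered petiole +
# branching veins, on an nr x nc grid with the leaf axis along columns.
# Returns list(mask, labels) with labels "blade"/"vein"/"petiole"/"" .
leaf_geometry <- function(nr, nc) {
  labels <- matrix("", nr, nc)
  r0 <- nr / 2
  pet_end <- 0.18 * nc
  blade_c0 <- (pet_end + nc * 0.97) / 2
  blade_a <- (nc * 0.97 - pet_end) / 2       # semi-axis along columns
  blade_b <- nr * 0.38                       # semi-axis along rows
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # superellipse exponent 2.5 gives a rounded leaf-blade outline
  blade <- (abs(cols - blade_c0) / blade_a)^2.5 +
    (abs(rows - r0) / blade_b)^2.5 <= 1
  labels[blade] <- "blade"
  # petiole: tapered band from the left edge into the blade
  pet_halfw <- 1.5 + 2.5 * (cols / pet_end)
  petiole <- cols <= pet_end & abs(rows - r0) <= pet_halfw
  labels[petiole] <- "petiole"
  # midrib along the leaf axis
  midrib <- blade & abs(rows - r0) <= 1.5
  labels[midrib] <- "vein"
  # branching secondary veins: straight offshoots from the midrib
  n_veins <- 6
  for (k in seq_len(n_veins)) {
    cx <- pet_end + (k / (n_veins + 1)) * (nc * 0.97 - pet_end)
    for (sgn in c(-1, 1)) {
      # vein climbs away from the midrib at ~35 degrees toward the tip
      len <- blade_b * (1 - 0.06 * k)
      t_ <- seq(0, 1, length.out = 200)
      vr <- round(r0 + sgn * t_ * len)
      vc <- round(cx + t_ * len * 0.9)
      ok <- vr >= 1 & vr <= nr & vc >= 1 & vc <= nc
      idx <- cbind(vr[ok], vc[ok])
      inside <- labels[idx] == "blade"
      labels[idx[inside, , drop = FALSE]] <- "vein"
    }
  }
  mask <- labels != ""
  list(mask = mask, labels = labels)
}

#' Generate a leaf-phantom hyperspectral cube with ground truth
#'
#' Builds a procedural leaf (superellipse blade, tapered petiole, midrib
#' and branching veins), assigns a concentration field (petiole >= vein >
#' blade, with a smooth centre-to-edge gradient inside the blade),
#' synthesises per-pixel raw spectra through the forward model, applies
#' column-gain stripes, and composes matching white/dark references, so
#' the whole pipeline can be scored against known truth.
#'
#' @param config a [phantom_config()].
#' @param nrow_px,ncol_px image dimensions (>= 64 each; defaults 128 and
#'   160).
#' @param seed RNG seed.
#' @return An object of class `leaf_phantom`: `cube` (raw
#'   [hypercube()]), `refs` (a [reference_pair()]),
#'   `concentration_truth` (matrix, `NA` off-leaf), `mask_truth`
#'   (a [leaf_mask()]), `region_labels` (character matrix), `config`,
#'   `seed`.
#' @export
generate_leaf_phantom <- function(config = phantom_config(),
                                  nrow_px = 128L, ncol_px = 160L,
                                  seed = 1L) {
  if (nrow_px < 64L || ncol_px < 64L)
    stop("phantom dimensions must be >= 64 x 64", call. = FALSE)
  set.seed(seed)
  nr <- as.integer(nrow_px); nc <- as.integer(ncol_px)
  geom <- leaf_geometry(nr, nc)
  labels <- geom$labels
  mask <- geom$mask
  # concentration truth
  conc <- matrix(NA_real_, nr, nc)
  blade_lvl <- mean(config$blade_range_mg_kg)
  vein_lvl <- mean(config$vein_range_mg_kg)
  pet_lvl <- mean(config$petiole_range_mg_kg)
  # centre-to-edge gradient inside the blade: centre ~ +15%, edge ~ -15%
  r0 <- nr / 2
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d_edge <- sqrt(((rows - r0) / (nr * 0.38))^2 +
                   ((cols - mean(which(colSums(mask) > 0))) /
                      (nc * 0.4))^2)
  grad <- 1 + 0.15 * (1 - pmin(d_edge, 1) * 2)
  conc[labels == "blade"] <- blade_lvl * grad[labels == "blade"]
  conc[labels == "vein"] <- vein_lvl
  conc[labels == "petiole"] <- pet_lvl
  wl <- phantom_wavelengths(config)
  nb <- config$n_bands
  base <- phantom_baseline(config)
  sig <- make_signature(config)
  intf <- phantom_interferents(config)
  # per-pixel reflectance: leaf via forward model, background flat
  n_px <- nr * nc
  refl <- matrix(config$background_reflectance, n_px, nb)
  leaf_idx <- which(as.vector(mask))
  cvec <- as.vector(conc)[leaf_idx]
  # smooth per-pixel interferent (water) variation across the leaf
  s_px <- 1 + config$interferent_sd * 0.3 *
    sin(2 * pi * as.vector(rows)[leaf_idx] / nr) *
    cos(2 * pi * as.vector(cols)[leaf_idx] / nc)
  A <- outer(cvec / config$c_ref_mg_kg, sig) + outer(s_px, intf) +
    matrix(base, length(leaf_idx), nb, byrow = TRUE)
  refl[leaf_idx, ] <- 10^(-A)
  if (config$noise_sd > 0)
    refl <- refl + matrix(stats::rnorm(n_px * nb, 0, config$noise_sd),
                          n_px, nb)
  # white/dark references: smooth lamp spectrum, mild per-column falloff
  lamp <- 0.8 + 0.4 * exp(-0.5 * ((wl - 1600) / 600)^2)
  colshape <- 1 - 0.1 * ((seq_len(nc) - nc / 2) / nc)^2
  white <- config$dark_level + config$white_level * outer(colshape, lamp)
  dark <- matrix(config$dark_level, nc, nb)
  # raw counts with column-gain stripes on the signal term
  gain <- 1 + config$stripe_amplitude *
    sin(2 * pi * seq_len(nc) / config$stripe_period +
          stats::runif(1, 0, 2 * pi))
  raw <- array(0, c(nr, nc, nb))
  span <- white - dark                      # nc x nb
  for (b in seq_len(nb)) {
    rb <- matrix(refl[, b], nr, nc)
    sb <- sweep(rb, 2, span[, b] * gain, "*")
    raw[, , b] <- sweep(sb, 2, dark[, b], "+")
  }
  raw[raw < 0] <- 0
  structure(list(
    cube = hypercube(raw, wl, kind = "raw"),
    refs = reference_pair(white, dark),
    concentration_truth = conc,
    mask_truth = leaf_mask(mask),
    region_labels = labels,
    config = config, seed = seed),
    class = "leaf_phantom")
}

#' @export
print.leaf_phantom <- function(x, ...) {
  cat(sprintf("<leaf_phantom> %d x %d px, %d bands, %d leaf pixels\n",
              dim(x$cube$data)[1], dim(x$cube$data)[2],
              dim(x$cube$data)[3], sum(unclass(x$mask_truth))))
  invisible(x)
}

#' Generate a synthetic leaf-storage time series
#'
#' Relative nitrate content decays exponentially with a per-temperature
#' rate (faster at higher storage temperature, reflecting
#' temperature-dependent nitrate reduction), while relative water content
#' decays slowly at a temperature-independent rate (saturated-humidity
#' storage). Observational noise is added on both; weights and initial
#' contents are drawn per leaf so the record carries a full
#' `FW/DW/PW/NC/PNC` set.
#'
#' @param temps storage temperatures in deg C (default `c(10, 20, 30,
#'   40)`).
#' @param days observation days (default `0:4`).
#' @param replicates leaves per temperature (default 8).
#' @param rnc_decay_per_day named or positional vector of RNC decay rates
#'   (per day), one per temperature; default `c(0.05, 0.15, 0.30,
#'   0.50)`.
#' @param rwc_decay_per_day temperature-independent RWC decay rate
#'   (default 0.01).
#' @param obs_noise_sd relative observational noise sd (default 0.02).
#' @param seed RNG seed.
#' @return Data frame of storage observations suitable for
#'   [storage_series()].
#' @export
generate_storage_series <- function(temps = c(10, 20, 30, 40),
                                    days = 0:4, replicates = 8L,
                                    rnc_decay_per_day = c(0.05, 0.15,
                                                          0.30, 0.50),
                                    rwc_decay_per_day = 0.01,
                                    obs_noise_sd = 0.02, seed = 1L) {
  if (replicates < 2L) stop("`replicates` must be >= 2", call. = FALSE)
  if (length(rnc_decay_per_day) != length(temps))
    stop("need one RNC decay rate per temperature", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (ti in seq_along(temps)) {
    for (rep_ in seq_len(replicates)) {
      PW <- stats::runif(1, 4, 6)
      DW <- 0.08 * PW
      PNC <- stats::runif(1, 3000, 5000)
      id <- sprintf("T%02d_r%02d", temps[ti], rep_)
      for (d in days) {
        rwc_true <- exp(-rwc_decay_per_day * d)
        rnc_true <- exp(-rnc_decay_per_day[ti] * d)
        rwc_obs <- rwc_true * (1 + stats::rnorm(1, 0, obs_noise_sd))
        rnc_obs <- rnc_true * (1 + stats::rnorm(1, 0, obs_noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = id, day = d, temperature_C = temps[ti],
          FW = DW + rwc_obs * (PW - DW), DW = DW, PW = PW,
          NC = PNC * rnc_obs, PNC = PNC)
      }
    }
  }
  do.call(rbind, rows)
}
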