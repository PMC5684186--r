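#' Nitrate content of a leaf sample from its aqueous extract
#'
#' A weighed fresh sample is extracted in a known volume of water and the
#' nitrate concentration of the extract measured (reflectometer role).
#' The tissue content is then
#' `NC_s = NC_l * V_l / W_s`, with units resolving as
#' mg/L x mL / g = (mg x 1e-3 L) / (1e-3 kg) = mg/kg fresh weight.
#'
#' @param NC_l extract nitrate concentration, mg/L (>= 0).
#' @param W_s sample fresh weight, g (> 0).
#' @param V_l extraction volume, mL (> 0).
#' @return Nitrate content of the tissue, mg/kg.
#' @examples
#' nitrate_content(100, 0.5, 1)  # 200 mg/kg
#' @export
nitrate_content <- function(NC_l, W_s, V_l) {
  if (any(W_s <= 0)) stop("`W_s` must be > 0", call. = FALSE)
  if (any(V_l <= 0)) stop("`V_l` must be > 0", call. = FALSE)
  if (any(NC_l < 0)) stop("`NC_l` must be >= 0", call. = FALSE)
  NC_l * V_l / W_s
}

#' Relative water content
#'
#' `RWC = (FW - DW) / (PW - DW)` where `FW` is the fresh weight at
#' measurement, `DW` the dry weight, and `PW` the initial fresh weight.
#' Not clamped: measurement noise can push RWC slightly above 1 and
#' clamping would hide it.
#'
#' @param FW fresh weight at measurement, g.
#' @param DW dry weight, g.
#' @param PW initial fresh weight, g (`PW > DW`).
#' @return Dimensionless RWC (1 at the initial state, 0 when fully dried).
#' @export
relative_water_content <- function(FW, DW, PW) {
  if (any(PW <= DW))
    stop("`PW` must exceed `DW` (zero denominator otherwise)",
         call. = FALSE)
  (FW - DW) / (PW - DW)
}

#' Relative nitrate content
#'
#' `RNC = NC / PNC`: current nitrate content normalised to the leaf's
#' initial content. Not clamped.
#'
#' @param NC current nitrate content, mg/kg.
#' @param PNC initial nitrate content, mg/kg (> 0).
#' @return Dimensionless RNC (1 at the initial state).
#' @export
relative_nitrate_content <- function(NC, PNC) {
  if (any(PNC <= 0)) stop("`PNC` must be > 0", call. = FALSE)
  NC / PNC
}

#' Summarise a leaf-storage time series
#'
#' Takes per-leaf storage observations (fresh/dry/initial weights and
#' mapped nitrate contents), derives RWC and RNC per observation, and
#' returns per-day, per-temperature group means with standard errors —
#' the quantities plotted in a storage-dynamics figure.
#'
#' @param observations data frame with columns `sample_id`, `day`
#'   (integer >= 0), `temperature_C`, `FW`, `DW`, `PW`, `NC`, `PNC`.
#' @return Data frame with one row per (day, temperature): `day`,
#'   `temperature_C`, `n`, `mean_rwc`, `se_rwc`, `mean_rnc`, `se_rnc`,
#'   sorted by temperature then day.
#' @export
storage_series <- function(observations) {
  need <- c("sample_id", "day", "temperature_C", "FW", "DW", "PW", "NC",
            "PNC")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop("observations missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !is.finite(observations$PNC) | observations$PNC <= 0 |
    !is.finite(observations$PW)
  if (any(bad))
    stop("missing or invalid baseline (PNC/PW) for sample(s): ",
         paste(unique(observations$sample_id[bad]), collapse = ", "),
         call. = FALSE)
  obs <- observations
  obs$rwc <- relative_water_content(obs$FW, obs$DW, obs$PW)
  obs$rnc <- relative_nitrate_content(obs$NC, obs$PNC)
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                    else NA_real_
  agg <- do.call(rbind, lapply(
    split(obs, list(obs$temperature_C, obs$day), drop = TRUE),
    function(g) data.frame(
      day = g$day[1], temperature_C = g$temperature_C[1], n = nrow(g),
      mean_rwc = mean(g$rwc), se_rwc = se(g$rwc),
      mean_rnc = mean(g$rnc), se_rnc = se(g$rnc))))
  if (any(agg$n < 2L))
    warning("some (day, temperature) cells have < 2 replicates; ",
            "their standard errors are NA", call. = FALSE)
  agg <- agg[order(agg$temperature_C, agg$day), ]
  rownames(agg) <- NULL
  agg
}
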