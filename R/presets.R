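## Calibration presets --------------------------------------------------------
##
## All calibration constants (beam parameters, published summary tables used
## as study-condition inputs, synthetic-generator defaults) live in a
## versioned YAML preset file shipped with the package, never in code.

#' Load the calibration presets
#'
#' @param path Path to a preset YAML file; defaults to the file shipped with
#'   the package.
#' @return Nested list of presets (see the file for the schema).
#' @export
bnct_presets <- function(path = system.file("extdata", "presets.yml",
                                            package = "borondose")) {
  if (!nzchar(path) || !file.exists(path))
    stop_borondose("preset file not found", "borondose_config_error")
  yaml::read_yaml(path)
}

#' Photon LQ reference parameters from the presets
#'
#' Derives `alpha` and `beta` from the preset `d10_gy` (the photon dose at
#' SF = 0.1) and the `alpha_beta_ratio_gy`, so that the endpoint constraint
#' `alpha*D10 + beta*D10^2 = ln 10` holds to machine precision.
#'
#' @param presets A preset list from [bnct_presets()].
#' @return An [lq_parameters()] object.
#' @export
lq_xray_parameters <- function(presets = bnct_presets()) {
  d10 <- presets$lq_xray$d10_gy
  r <- presets$lq_xray$alpha_beta_ratio_gy
  beta <- log(10) / (r * d10 + d10^2)
  lq_parameters(alpha = r * beta, beta = beta)
}

#' In vitro beam-fraction model from the presets
#'
#' Builds the [beam_fraction_model()] used for CBE derivation: the
#' time/dose ladder of the in vitro irradiation, the high-LET/gamma
#' composition taken from the boron-free beam row via
#' [beam_component_split()], and (optionally) the boron dose-rate calibrated
#' on the reference carrier's published CBE.
#'
#' @param presets A preset list from [bnct_presets()].
#' @param calibrate If `TRUE` (default) calibrate the boron rate on the
#'   reference carrier (`ref_carrier`).
#' @param ref_carrier Carrier used for calibration (default `"BPA"`).
#' @return A [beam_fraction_model()], calibrated unless `calibrate = FALSE`.
#' @export
invitro_beam_model <- function(presets = bnct_presets(), calibrate = TRUE,
                               ref_carrier = "BPA") {
  rbe_nh <- presets$factors$rbe_n
  sp <- beam_component_split(presets$beam_only_row$physical_gy,
                             presets$beam_only_row$photon_equivalent_gy_eq,
                             rbe_nh)
  mdl <- beam_fraction_model(
    ladder_time_s = presets$beam$in_vitro$ladder$time_s,
    ladder_dose_gy = presets$beam$in_vitro$ladder$dose_gy,
    nh_fraction = sp[["d_nh"]] / presets$beam_only_row$physical_gy,
    rbe_nh = rbe_nh
  )
  if (calibrate) {
    mdl <- calibrate_boron_rate(
      mdl,
      d_photon_ref = presets$endpoint$d_photon_ref_gy,
      endpoint_dose_ref = presets$endpoint$beam_dose_at_sf10_gy[[ref_carrier]],
      cbe_ref = presets$factors$cbe[[ref_carrier]]$tumor
    )
  }
  mdl
}

#' Preset tissue biodistribution grid as a data frame
#'
#' @param presets A preset list from [bnct_presets()].
#' @return Data frame with columns `carrier`, `time_h`, `tissue`, `mean`,
#'   `sd`, `n`.
#' @export
preset_tissue_grid <- function(presets = bnct_presets()) {
  g <- presets$tissue_biodistribution
  data.frame(carrier = g$carrier, time_h = g$time_h, tissue = g$tissue,
             mean = g$mean, sd = g$sd, n = as.integer(g$n),
             stringsAsFactors = FALSE)
}

#' Preset survival-group summaries as a data frame
#'
#' @param presets A preset list from [bnct_presets()].
#' @return Data frame with columns `group`, `n`, `mean`, `sd`, `median`, and
#'   attribute `censor_horizon_days`.
#' @export
preset_survival_groups <- function(presets = bnct_presets()) {
  g <- presets$survival_groups
  out <- data.frame(group = g$group, n = as.integer(g$n), mean = g$mean,
                    sd = g$sd, median = g$median, stringsAsFactors = FALSE)
  attr(out, "censor_horizon_days") <- g$censor_horizon_days
  out
}
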