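## Compound biological effectiveness (CBE) derivation -------------------------
##
## At a fixed survival endpoint (SF = 0.1) the photon-equivalent equation
##   d_photon_ref = CBE * D_B + RBE_NH * (D_N + D_H) + D_gamma
## is inverted for the carrier's CBE.  The decomposition of a boron group's
## endpoint dose is rarely published, so a beam-fraction model reconstructs
## it from (i) the irradiation-time -> beam-dose ladder of the experiment,
## (ii) the high-LET/gamma composition of the beam, and (iii) a boron
## dose-rate constant calibrated on a reference carrier with a known CBE.

#' Beam-fraction model for endpoint decomposition
#'
#' Describes how a clonogenic endpoint read off the shared beam physical-dose
#' axis decomposes into components.  The irradiation time at an endpoint dose
#' is obtained by inverting the time/dose ladder (piecewise-linear, with
#' boundary-slope extrapolation beyond the last rung); beam components scale
#' with the ladder dose via the fixed composition `nh_fraction`; the boron
#' dose grows linearly with time at `boron_rate` (Gy/s), normally set by
#' [calibrate_boron_rate()] rather than by hand.
#'
#' @param ladder_time_s Irradiation times of the ladder, seconds.
#' @param ladder_dose_gy Beam physical doses at those times, Gy.
#' @param nh_fraction Fraction of the beam dose carried by the high-LET
#'   nitrogen + hydrogen components (the remainder is gamma).
#' @param rbe_nh Common RBE of the high-LET components.
#' @param boron_rate Boron dose rate at the reference cellular loading, Gy/s,
#'   or `NA` before calibration.
#' @return An object of class `beam_fraction_model`.
#' @export
beam_fraction_model <- function(ladder_time_s, ladder_dose_gy,
                                nh_fraction, rbe_nh = 3.0,
                                boron_rate = NA_real_) {
  check_numeric_vec(ladder_time_s, "ladder_time_s", min = 0)
  check_numeric_vec(ladder_dose_gy, "ladder_dose_gy", min = 0)
  if (length(ladder_time_s) != length(ladder_dose_gy) || length(ladder_time_s) < 2L)
    stop_borondose("ladder needs >= 2 matching (time, dose) rungs",
                   "borondose_config_error")
  check_number(nh_fraction, "nh_fraction", min = 0)
  if (nh_fraction > 1)
    stop_borondose("'nh_fraction' must be in [0, 1]", "borondose_validation_error")
  check_number(rbe_nh, "rbe_nh", min = 0)
  if (!is.na(boron_rate)) check_number(boron_rate, "boron_rate", min = 0)
  structure(
    list(ladder_time_s = ladder_time_s, ladder_dose_gy = ladder_dose_gy,
         nh_fraction = nh_fraction, rbe_nh = rbe_nh, boron_rate = boron_rate),
    class = "beam_fraction_model"
  )
}

#' @export
print.beam_fraction_model <- function(x, ...) {
  cat("<beam_fraction_model>\n")
  cat("  ladder:", paste(sprintf("%gs->%.3gGy", x$ladder_time_s, x$ladder_dose_gy),
                         collapse = " "), "\n")
  cat(sprintf("  NH fraction %.4g, RBE_NH %.3g, boron rate %s\n",
              x$nh_fraction, x$rbe_nh,
              if (is.na(x$boron_rate)) "uncalibrated"
              else sprintf("%.4g Gy/s", x$boron_rate)))
  invisible(x)
}

#' Irradiation time at a beam dose (ladder inversion)
#'
#' @param model A [beam_fraction_model()].
#' @param beam_dose Beam physical dose, Gy.
#' @return Time in seconds.
#' @export
ladder_time_at_dose <- function(model, beam_dose) {
  stopifnot(inherits(model, "beam_fraction_model"))
  check_numeric_vec(beam_dose, "beam_dose", min = 0)
  interp_extrap(model$ladder_dose_gy, model$ladder_time_s, beam_dose)
}

#' Decompose an endpoint beam dose into mixed-field components
#'
#' @param model A calibrated [beam_fraction_model()].
#' @param beam_dose Endpoint position on the beam physical-dose axis, Gy.
#' @return A [dose_components()] object (lumped NH representation).
#' @export
endpoint_components <- function(model, beam_dose) {
  stopifnot(inherits(model, "beam_fraction_model"))
  check_number(beam_dose, "beam_dose", min = 0)
  if (is.na(model$boron_rate))
    stop_borondose("beam_fraction_model is uncalibrated: no boron rate; run calibrate_boron_rate()",
                   "borondose_config_error")
  t_s <- ladder_time_at_dose(model, beam_dose)
  dose_components_nh(
    d_boron = model$boron_rate * t_s,
    d_nh = model$nh_fraction * beam_dose,
    d_gamma = (1 - model$nh_fraction) * beam_dose
  )
}

#' Calibrate the boron dose-rate of a beam-fraction model
#'
#' Chooses the single boron dose-rate constant so that a reference carrier
#' with known CBE and known endpoint beam dose reproduces that CBE exactly
#' under [carrier_cbe()].
#'
#' @param model A [beam_fraction_model()].
#' @param d_photon_ref Photon reference dose at the endpoint, Gy.
#' @param endpoint_dose_ref The reference carrier's endpoint beam dose, Gy.
#' @param cbe_ref The reference carrier's known CBE.
#' @return The model with `boron_rate` set.
#' @export
calibrate_boron_rate <- function(model, d_photon_ref, endpoint_dose_ref,
                                 cbe_ref) {
  stopifnot(inherits(model, "beam_fraction_model"))
  check_number(d_photon_ref, "d_photon_ref", min = 0)
  check_number(endpoint_dose_ref, "endpoint_dose_ref", min = 0)
  check_number(cbe_ref, "cbe_ref")
  if (cbe_ref <= 0)
    stop_borondose("'cbe_ref' must be > 0", "borondose_validation_error")
  beam_weighted <- endpoint_dose_ref *
    (model$rbe_nh * model$nh_fraction + (1 - model$nh_fraction))
  num <- d_photon_ref - beam_weighted
  if (num <= 0)
    stop_borondose("weighted beam dose exceeds the photon reference: calibration impossible",
                   "borondose_inconsistent_error")
  t_ref <- ladder_time_at_dose(model, endpoint_dose_ref)
  if (t_ref <= 0)
    stop_borondose("reference endpoint maps to zero irradiation time",
                   "borondose_inconsistent_error")
  model$boron_rate <- num / cbe_ref / t_ref
  model
}

#' Carrier compound biological effectiveness
#'
#' Inverts the photon-equivalent dose equation at a fixed survival endpoint:
#' `CBE = (d_photon_ref - RBE_NH*(D_N + D_H) - D_gamma) / D_B`.
#'
#' The endpoint decomposition may be given explicitly as a
#' [dose_components()] object, or as a position on the beam physical-dose
#' axis together with a calibrated [beam_fraction_model()] that reconstructs
#' the components.  A CBE below 1 is valid (a carrier can be less effective
#' per Gy of capture dose than photons); a negative CBE is reported but
#' flagged with a warning since it signals an inconsistent decomposition.
#'
#' @param d_photon_ref Photon reference dose at the endpoint, Gy.
#' @param endpoint Either a [dose_components()] decomposition of the boron
#'   group's endpoint dose, or a numeric beam physical dose (Gy), in which
#'   case `model` is required.
#' @param model A calibrated [beam_fraction_model()] (used only when
#'   `endpoint` is numeric); also supplies `rbe_nh`.
#' @param rbe_nh Common RBE of the high-LET beam components when `endpoint`
#'   is a `dose_components` object (default 3.0).
#' @return Dimensionless CBE.
#' @export
#' @examples
#' # exact inversion when the decomposition is known:
#' cmp <- dose_components_nh(d_boron = 2, d_nh = 0.5, d_gamma = 1.1)
#' carrier_cbe(6.45, cmp)   # (6.45 - 3*0.5 - 1.1) / 2
carrier_cbe <- function(d_photon_ref, endpoint, model = NULL, rbe_nh = 3.0) {
  check_number(d_photon_ref, "d_photon_ref", min = 0)
  if (is.numeric(endpoint)) {
    if (is.null(model))
      stop_borondose("a beam_fraction_model is required when 'endpoint' is a beam dose",
                     "borondose_config_error")
    comps <- endpoint_components(model, endpoint)
    rbe_nh <- model$rbe_nh
  } else if (inherits(endpoint, "dose_components")) {
    comps <- endpoint
  } else {
    stop_borondose("'endpoint' must be a dose or a dose_components object",
                   "borondose_validation_error")
  }
  if (comps$d_boron <= 0)
    stop_borondose("boron component of the endpoint dose is zero: the carrier contributes nothing and CBE is undefined",
                   "borondose_validation_error")
  num <- d_photon_ref - rbe_nh * (comps$d_nitrogen + comps$d_hydrogen) -
    comps$d_gamma
  cbe <- num / comps$d_boron
  if (cbe < 0)
    warning(sprintf("derived CBE is negative (%.3g): weighted beam components exceed the photon reference",
                    cbe), call. = FALSE)
  cbe
}
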