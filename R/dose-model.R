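## Mixed-field dose model -----------------------------------------------------
##
## A BNCT irradiation deposits dose through four channels: the 10B(n,alpha)7Li
## capture reaction in boron-loaded tissue (D_B), the 14N(n,p)14C capture
## reaction (D_N), recoil protons from 1H(n,n)1H elastic scattering (D_H), and
## the gamma component of the beam (D_gamma).  The physical dose is their sum;
## the biologically weighted ("photon-equivalent") dose applies a
## carrier/tissue-specific compound biological effectiveness (CBE) factor to
## D_B and relative biological effectiveness factors RBE_N, RBE_H to the two
## high-LET beam components.

#' Beam specification
#'
#' Describes an irradiation field: neutron flux components, the gamma dose
#' rate, and the kerma coefficients converting fluence (and, for the boron
#' channel, boron concentration) into absorbed dose.  Kerma coefficients are
#' calibration inputs, not physical constants baked into the code; defaults
#' shipped with the package live in the example config
#' (`system.file("extdata", "presets.yml", package = "borondose")`).
#'
#' @param thermal_flux Thermal neutron flux, neutrons cm^-2 s^-1.
#' @param gamma_dose_rate Gamma dose rate, Gy s^-1.
#' @param kerma Named list/vector of kerma coefficients. `B10` is required by
#'   [boron_dose()] and has units Gy cm^2 per (ug 10B / g tissue); `N14` and
#'   `H1` (Gy cm^2, tissue composition folded in) are optional.
#' @param epithermal_flux,fast_flux Optional additional flux components,
#'   neutrons cm^-2 s^-1.
#' @return An object of class `beam_spec`.
#' @export
#' @examples
#' beam_spec(thermal_flux = 9.6e8, gamma_dose_rate = 9.2e-4,
#'           kerma = c(B10 = 8.66e-14))
beam_spec <- function(thermal_flux, gamma_dose_rate = 0, kerma = c(),
                      epithermal_flux = NA_real_, fast_flux = NA_real_) {
  check_number(thermal_flux, "thermal_flux", min = 0)
  check_number(gamma_dose_rate, "gamma_dose_rate", min = 0)
  check_number(epithermal_flux, "epithermal_flux", min = 0, allow_na = TRUE)
  check_number(fast_flux, "fast_flux", min = 0, allow_na = TRUE)
  kerma <- unlist(kerma)
  if (length(kerma)) {
    bad <- names(kerma)[!nzchar(names(kerma) %||% "")]
    if (is.null(names(kerma)) || any(!nzchar(names(kerma))))
      stop_borondose("kerma coefficients must be named by reaction channel",
                     "borondose_config_error")
    if (any(!is.finite(kerma)) || any(kerma <= 0))
      stop_borondose("kerma coefficients must be finite and > 0",
                     "borondose_config_error")
  }
  structure(
    list(thermal_flux = thermal_flux, epithermal_flux = epithermal_flux,
         fast_flux = fast_flux, gamma_dose_rate = gamma_dose_rate,
         kerma = kerma),
    class = "beam_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.beam_spec <- function(x, ...) {
  cat("<beam_spec>\n")
  cat(sprintf("  thermal flux     : %.3g n/cm^2/s\n", x$thermal_flux))
  if (!is.na(x$epithermal_flux))
    cat(sprintf("  epithermal flux  : %.3g n/cm^2/s\n", x$epithermal_flux))
  if (!is.na(x$fast_flux))
    cat(sprintf("  fast flux        : %.3g n/cm^2/s\n", x$fast_flux))
  cat(sprintf("  gamma dose rate  : %.3g Gy/s\n", x$gamma_dose_rate))
  if (length(x$kerma))
    cat("  kerma            :",
        paste(sprintf("%s=%.3g", names(x$kerma), x$kerma), collapse = ", "), "\n")
  invisible(x)
}

#' Exposure specification
#'
#' One tissue's irradiation condition: how long the beam is on and how much
#' boron the tissue carries.
#'
#' @param irradiation_time Irradiation time, seconds (>= 0).
#' @param boron_concentration Boron concentration in the tissue,
#'   ug 10B per g (>= 0).
#' @param tissue_label Free-text tissue label (e.g. `"tumor"`).
#' @return An object of class `exposure_spec`.
#' @export
exposure_spec <- function(irradiation_time, boron_concentration,
                          tissue_label = "") {
  check_number(irradiation_time, "irradiation_time", min = 0)
  check_number(boron_concentration, "boron_concentration", min = 0)
  structure(
    list(irradiation_time = irradiation_time,
         boron_concentration = boron_concentration,
         tissue_label = as.character(tissue_label)[1L]),
    class = "exposure_spec"
  )
}

#' Boron capture dose
#'
#' Physical dose from the 10B(n,alpha)7Li reaction:
#' `k_B10 * thermal_flux * irradiation_time * boron_concentration`.
#' Strictly linear in concentration, flux and time separately.
#'
#' @param beam A [beam_spec()] whose kerma map contains a `B10` entry.
#' @param exposure An [exposure_spec()].
#' @return Dose in Gy.
#' @export
#' @examples
#' b <- beam_spec(9.6e8, kerma = c(B10 = 8.66e-14))
#' boron_dose(b, exposure_spec(1200, 20.6, "tumor"))
boron_dose <- function(beam, exposure) {
  stopifnot(inherits(beam, "beam_spec"), inherits(exposure, "exposure_spec"))
  k <- beam$kerma["B10"]
  if (is.null(names(beam$kerma)) || !"B10" %in% names(beam$kerma)) {
    stop_borondose("beam_spec has no 'B10' kerma coefficient",
                   "borondose_config_error")
  }
  unname(k * beam$thermal_flux * exposure$irradiation_time *
           exposure$boron_concentration)
}

#' Physical dose components
#'
#' The four physical dose terms of a mixed BNCT field.  Components are kept
#' separate; use [dose_components_nh()] when only the lumped nitrogen+hydrogen
#' term is known (table-style inputs), which is sufficient whenever
#' `rbe_n == rbe_h`.
#'
#' @param d_boron,d_nitrogen,d_hydrogen,d_gamma Component doses in Gy (>= 0).
#' @return An object of class `dose_components`.
#' @export
#' @examples
#' dose_components(3.0, 0.25, 0.25, 1.1)
dose_components <- function(d_boron = 0, d_nitrogen = 0, d_hydrogen = 0,
                            d_gamma = 0) {
  check_number(d_boron, "d_boron", min = 0)
  check_number(d_nitrogen, "d_nitrogen", min = 0)
  check_number(d_hydrogen, "d_hydrogen", min = 0)
  check_number(d_gamma, "d_gamma", min = 0)
  structure(
    list(d_boron = d_boron, d_nitrogen = d_nitrogen,
         d_hydrogen = d_hydrogen, d_gamma = d_gamma, lumped_nh = FALSE),
    class = "dose_components"
  )
}

#' @rdname dose_components
#' @param d_nh Lumped nitrogen + hydrogen dose in Gy (>= 0); stored split
#'   evenly across the two channels (their sum, the only quantity that enters
#'   any weighted dose when `rbe_n == rbe_h`, is preserved exactly).
#' @export
dose_components_nh <- function(d_boron = 0, d_nh = 0, d_gamma = 0) {
  check_number(d_nh, "d_nh", min = 0)
  out <- dose_components(d_boron, d_nh / 2, d_nh / 2, d_gamma)
  out$lumped_nh <- TRUE
  out
}

#' @export
print.dose_components <- function(x, ...) {
  cat("<dose_components> (Gy)\n")
  if (x$lumped_nh) {
    cat(sprintf("  D_B = %.4g  D_N+D_H = %.4g (lumped)  D_gamma = %.4g\n",
                x$d_boron, x$d_nitrogen + x$d_hydrogen, x$d_gamma))
  } else {
    cat(sprintf("  D_B = %.4g  D_N = %.4g  D_H = %.4g  D_gamma = %.4g\n",
                x$d_boron, x$d_nitrogen, x$d_hydrogen, x$d_gamma))
  }
  cat(sprintf("  total physical dose = %.4g Gy\n", total_physical_dose(x)))
  invisible(x)
}

#' Radiobiological weighting factors
#'
#' CBE for the boron channel and RBE factors for the nitrogen and hydrogen
#' channels.  `cbe` may be `NA` to express that the factor is unknown for a
#' carrier/tissue pair (as for a novel carrier in normal brain); a weighted
#' dose is then only computable for boron-free fields.
#'
#' @param cbe Compound biological effectiveness (> 0, or `NA` for unknown).
#' @param rbe_n,rbe_h Relative biological effectiveness of the nitrogen
#'   capture and proton recoil components (> 0). Both default to 3.0, the
#'   conventional value for the high-LET beam components.
#' @return An object of class `radiobiological_factors`.
#' @export
radiobiological_factors <- function(cbe = NA_real_, rbe_n = 3.0, rbe_h = 3.0) {
  if (!is.na(cbe)) check_number(cbe, "cbe")
  check_number(rbe_n, "rbe_n")
  check_number(rbe_h, "rbe_h")
  if ((!is.na(cbe) && cbe <= 0) || rbe_n <= 0 || rbe_h <= 0)
    stop_borondose("all radiobiological factors must be > 0",
                   "borondose_validation_error")
  structure(list(cbe = cbe, rbe_n = rbe_n, rbe_h = rbe_h),
            class = "radiobiological_factors")
}

#' Total physical dose
#'
#' `D_B + D_N + D_H + D_gamma`.
#'
#' @param components A [dose_components()] object.
#' @return Dose in Gy.
#' @export
total_physical_dose <- function(components) {
  stopifnot(inherits(components, "dose_components"))
  components$d_boron + components$d_nitrogen + components$d_hydrogen +
    components$d_gamma
}

#' Photon-equivalent (biologically weighted) dose
#'
#' `D_B * CBE + D_N * RBE_N + D_H * RBE_H + D_gamma`, in Gy-Eq.  With all
#' factors equal to 1 this reduces to [total_physical_dose()].
#'
#' @param components A [dose_components()] object.
#' @param factors A [radiobiological_factors()] object.
#' @return Weighted dose in Gy-Eq.
#' @export
#' @examples
#' cmp <- dose_components_nh(d_boron = 3.0, d_nh = 0.5, d_gamma = 1.1)
#' photon_equivalent_dose(cmp, radiobiological_factors(cbe = 2.69))
photon_equivalent_dose <- function(components, factors) {
  stopifnot(inherits(components, "dose_components"),
            inherits(factors, "radiobiological_factors"))
  if (components$d_boron > 0 && is.na(factors$cbe)) {
    stop_borondose(
      "CBE factor unknown for this carrier/tissue: photon-equivalent dose of a boron-loaded field is undefined",
      "borondose_factor_unknown_error"
    )
  }
  cbe <- if (is.na(factors$cbe)) 0 else factors$cbe
  components$d_boron * cbe +
    components$d_nitrogen * factors$rbe_n +
    components$d_hydrogen * factors$rbe_h +
    components$d_gamma
}

#' Split a beam-only dose pair into high-LET and gamma parts
#'
#' A boron-free irradiation reported only as (physical total, photon-equivalent
#' total) determines its decomposition uniquely when the nitrogen and hydrogen
#' components share one RBE: solve `x + y = physical` and
#' `rbe_nh * x + y = photon_equivalent` for `x = D_N + D_H` and
#' `y = D_gamma`.  This turns a published beam-only table row into a usable
#' component decomposition.
#'
#' @param physical_total Physical dose, Gy.
#' @param photon_equivalent_total Weighted dose, Gy-Eq
#'   (>= `physical_total`).
#' @param rbe_nh Common RBE of the high-LET components (> 1).
#' @return Named numeric vector `c(d_nh = , d_gamma = )`.
#' @export
#' @examples
#' beam_component_split(1.6, 2.6, 3.0)  # c(d_nh = 0.5, d_gamma = 1.1)
beam_component_split <- function(physical_total, photon_equivalent_total,
                                 rbe_nh = 3.0) {
  check_number(physical_total, "physical_total", min = 0)
  check_number(photon_equivalent_total, "photon_equivalent_total", min = 0)
  check_number(rbe_nh, "rbe_nh")
  if (rbe_nh <= 1)
    stop_borondose("'rbe_nh' must be > 1 for the split to be identifiable",
                   "borondose_validation_error")
  if (photon_equivalent_total < physical_total - 1e-12)
    stop_borondose("photon-equivalent total below physical total is inconsistent with RBE >= 1",
                   "borondose_inconsistent_error")
  d_nh <- (photon_equivalent_total - physical_total) / (rbe_nh - 1)
  d_gamma <- physical_total - d_nh
  if (d_gamma < -1e-12)
    stop_borondose("inputs imply a negative gamma component; inconsistent dose pair",
                   "borondose_inconsistent_error")
  c(d_nh = d_nh, d_gamma = max(d_gamma, 0))
}

#' Reconstruct a tumor photon-equivalent dose from table-style inputs
#'
#' Published dose tables usually print, per group, only the total physical
#' dose and (for the boron-free beam) the pair (physical, photon-equivalent).
#' This helper rebuilds the full weighted dose: the beam-only pair is split
#' with [beam_component_split()], the boron component is the tumor physical
#' total minus the beam physical dose, and the weighted sum is recombined
#' with [photon_equivalent_dose()].
#'
#' @param physical_total Tumor total physical dose, Gy.
#' @param beam_physical,beam_photon_eq The boron-free beam's physical and
#'   photon-equivalent doses, Gy / Gy-Eq.
#' @param cbe Carrier CBE in the tumor.
#' @param rbe_nh Common RBE of the high-LET beam components (default 3.0).
#' @return Photon-equivalent dose, Gy-Eq.
#' @export
#' @examples
#' tumor_photon_equivalent(4.6, 1.6, 2.6, cbe = 2.69)
tumor_photon_equivalent <- function(physical_total, beam_physical,
                                    beam_photon_eq, cbe, rbe_nh = 3.0) {
  check_number(physical_total, "physical_total", min = 0)
  if (physical_total < beam_physical - 1e-12)
    stop_borondose("tumor physical dose below the beam-only dose is inconsistent",
                   "borondose_inconsistent_error")
  sp <- beam_component_split(beam_physical, beam_photon_eq, rbe_nh)
  cmp <- dose_components_nh(d_boron = max(physical_total - beam_physical, 0),
                            d_nh = sp[["d_nh"]], d_gamma = sp[["d_gamma"]])
  photon_equivalent_dose(cmp, radiobiological_factors(cbe = cbe,
                                                      rbe_n = rbe_nh,
                                                      rbe_h = rbe_nh))
}
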