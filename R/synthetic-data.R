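## Synthetic data generators --------------------------------------------------
##
## Every input table of the analysis chain can be generated with the
## statistical structure the analysis assumes, calibrated to the preset
## summaries, so the full pipeline is testable without wet-lab data.  All
## generators are deterministic under a fixed seed and leave the caller's RNG
## stream untouched.

#' Generate a colony-forming assay table
#'
#' Per-dish colony counts are Poisson with mean
#' `cells_seeded * pe_control * SF(dose)`; dose 0 rows are the unirradiated
#' control.  When `cells_seeded` is not given it is chosen per dose so the
#' expected count is `target_colonies` (the "predetermined number of cells"
#' dilution step of a real assay).
#'
#' @param params LQ parameters (anything accepted by [lq_survival()]) or a
#'   function `dose -> SF` for mixed-field survival models.
#' @param doses Dose ladder in Gy (must include 0 for the control unless
#'   `cells_seeded` rows are supplied for it separately).
#' @param pe_control Control plating efficiency in (0, 1].
#' @param dishes Dishes per condition (default 3).
#' @param cells_seeded Optional vector of cells seeded per dose.
#' @param target_colonies Expected colonies per dish for automatic seeding.
#' @param seed Optional integer seed (deterministic output).
#' @return Data frame with columns `group`, `dose_gy`, `cells_seeded`,
#'   `dish_id`, `colonies`.
#' @export
#' @examples
#' tab <- gen_colony_assay(lq_parameters(0.2, 0.03), seed = 1)
#' head(tab)
gen_colony_assay <- function(params, doses = c(0, 2, 4, 6, 8),
                             pe_control = 0.6, dishes = 3L,
                             cells_seeded = NULL, target_colonies = 150L,
                             seed = NULL) {
  check_numeric_vec(doses, "doses", min = 0)
  check_number(pe_control, "pe_control")
  if (pe_control <= 0 || pe_control > 1)
    stop_borondose("'pe_control' must be in (0, 1]", "borondose_validation_error")
  sf_fun <- if (is.function(params)) params else function(d) lq_survival(params, d)
  sf <- vapply(doses, sf_fun, 0)
  if (any(sf > 1 + 1e-9) || any(sf <= 0))
    stop_borondose("survival model must yield SF in (0, 1] on the dose ladder",
                   "borondose_validation_error")
  if (is.null(cells_seeded)) {
    cells_seeded <- ceiling(target_colonies / (pe_control * sf))
  }
  if (length(cells_seeded) != length(doses))
    stop_borondose("'cells_seeded' must match 'doses'", "borondose_validation_error")
  with_preserved_seed(seed, {
    rows <- lapply(seq_along(doses), function(i) {
      lam <- cells_seeded[i] * pe_control * sf[i]
      counts <- pmin(stats::rpois(dishes, lam), cells_seeded[i])
      data.frame(
        group = if (doses[i] == 0) "control" else sprintf("dose_%g", doses[i]),
        dose_gy = doses[i], cells_seeded = cells_seeded[i],
        dish_id = seq_len(dishes), colonies = counts,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Generate a tissue biodistribution table
#'
#' Per-animal concentrations are drawn from a normal distribution truncated
#' at zero with the preset cell means and SDs (tissue concentrations are
#' reported as symmetric mean +/- SD with small coefficients of variation,
#' so a truncated normal, not a log-normal, is the matching noise model).
#'
#' @param grid Data frame with columns `carrier`, `time_h`, `tissue`,
#'   `mean`, `sd`, `n` (see [preset_tissue_grid()]).
#' @param seed Optional integer seed.
#' @return Data frame with columns `carrier`, `time_h`, `tissue`,
#'   `animal_id`, `ug_b_per_g`.
#' @export
gen_tissue_biodistribution <- function(grid = preset_tissue_grid(),
                                       seed = NULL) {
  req <- c("carrier", "time_h", "tissue", "mean", "sd", "n")
  if (!all(req %in% names(grid)))
    stop_borondose(paste("grid needs columns:", paste(req, collapse = ", ")),
                   "borondose_validation_error")
  check_numeric_vec(grid$mean, "mean", min = 0)
  check_numeric_vec(grid$sd, "sd", min = 0)
  with_preserved_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      n <- grid$n[i]
      x <- stats::rnorm(n, grid$mean[i], grid$sd[i])
      for (tries in 1:100) {
        neg <- x < 0
        if (!any(neg)) break
        x[neg] <- stats::rnorm(sum(neg), grid$mean[i], grid$sd[i])
      }
      x[x < 0] <- 0
      data.frame(carrier = grid$carrier[i], time_h = grid$time_h[i],
                 tissue = grid$tissue[i], animal_id = seq_len(n),
                 ug_b_per_g = x, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate grouped animal survival records
#'
#' Survival times are log-normal, moment-matched to each group's preset
#' mean +/- SD (positive support and the right skew of small-animal survival
#' data); a degenerate group (`sd == 0`) yields all times equal to the preset
#' median.  Times at or beyond the censoring horizon are censored there,
#' emulating animals alive at study end.
#'
#' @param groups Data frame with columns `group`, `n`, `mean`, `sd`,
#'   `median` (see [preset_survival_groups()]).
#' @param censor_horizon_days Censoring horizon in days (default from the
#'   `censor_horizon_days` attribute of `groups`, else `Inf`).
#' @param seed Optional integer seed.
#' @return Data frame with columns `group`, `animal_id`, `days`, `event`.
#' @export
gen_survival <- function(groups = preset_survival_groups(),
                         censor_horizon_days = NULL, seed = NULL) {
  req <- c("group", "n", "mean", "sd", "median")
  if (!all(req %in% names(groups)))
    stop_borondose(paste("groups needs columns:", paste(req, collapse = ", ")),
                   "borondose_validation_error")
  if (any(groups$mean <= 0) || any(groups$sd < 0))
    stop_borondose("group means must be > 0 and SDs >= 0",
                   "borondose_validation_error")
  horizon <- censor_horizon_days %||%
    (attr(groups, "censor_horizon_days") %||% Inf)
  with_preserved_seed(seed, {
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      n <- groups$n[i]
      if (groups$sd[i] == 0) {
        t <- rep(groups$median[i], n)
      } else {
        sdlog2 <- log(1 + (groups$sd[i] / groups$mean[i])^2)
        meanlog <- log(groups$mean[i]) - sdlog2 / 2
        t <- stats::rlnorm(n, meanlog, sqrt(sdlog2))
      }
      ev <- as.integer(t < horizon)
      t <- pmin(t, horizon)
      data.frame(group = groups$group[i], animal_id = seq_len(n),
                 days = round(t, 1), event = ev, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a cellular uptake / washout table
#'
#' The exposure phase follows saturating first-order uptake,
#' `C(t) = Cmax * (1 - exp(-k t))`; the washout phase decays exponentially
#' from the end-of-exposure (24 h) concentration at a rate fixed so the
#' +1 h retention equals the configured target percentage.  Noise-free by
#' default; `cv > 0` adds multiplicative normal noise.
#'
#' @param presets A preset list from [bnct_presets()] (uses the
#'   `cellular_uptake` section).
#' @param exposure_times_h,washout_times_h Sampling times in hours.
#' @param cv Coefficient of variation of multiplicative noise (default 0).
#' @param seed Optional integer seed (only used when `cv > 0`).
#' @return Data frame with columns `cell_line`, `carrier`, `phase`,
#'   `time_h`, `ug_b_per_1e9_cells`.
#' @export
gen_cellular_uptake <- function(presets = bnct_presets(),
                                exposure_times_h = c(1, 6, 24),
                                washout_times_h = c(1, 6, 24),
                                cv = 0, seed = NULL) {
  cu <- presets$cellular_uptake
  check_number(cv, "cv", min = 0)
  with_preserved_seed(seed, {
    rows <- list()
    for (cl in cu$cell_lines) {
      for (ca in cu$carriers) {
        cmax <- cu$cmax_ug_b_per_1e9_cells[[ca]]
        k <- cu$uptake_rate_per_h[[ca]]
        ret1 <- cu$retention_1h_pct[[cl]][[ca]]
        if (is.null(ret1) || ret1 <= 0 || ret1 > 100)
          stop_borondose(sprintf("retention target for %s/%s must be in (0, 100]",
                                 cl, ca), "borondose_validation_error")
        conc_exp <- cmax * (1 - exp(-k * exposure_times_h))
        baseline <- cmax * (1 - exp(-k * 24))
        lambda <- -log(ret1 / 100)            # per hour; ret(1h) exact
        conc_wash <- baseline * exp(-lambda * washout_times_h)
        noisy <- function(x) {
          if (cv <= 0) return(x)
          pmax(x * (1 + stats::rnorm(length(x), 0, cv)), 0)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = cl, carrier = ca,
          phase = rep(c("exposure", "washout"),
                      c(length(exposure_times_h), length(washout_times_h))),
          time_h = c(exposure_times_h, washout_times_h),
          ug_b_per_1e9_cells = c(noisy(conc_exp), noisy(conc_wash)),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}
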