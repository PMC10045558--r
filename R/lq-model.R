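## Clonogenic survival and the linear-quadratic model -------------------------
##
## Survival fractions come from colony-forming assays: plating efficiency of a
## treated condition divided by the plating efficiency of the unirradiated
## control.  The photon dose-response is described by the LQ model
## SF(D) = exp(-alpha*D - beta*D^2); its inversion at a survival endpoint
## (conventionally SF = 0.1) gives the isoeffective photon dose from which
## beam RBE and carrier CBE factors are derived.

#' Survival fraction from colony counts
#'
#' Per-dish plating efficiencies (colonies / cells seeded) are averaged within
#' each condition and the treated mean is normalised by the control mean.  The
#' standard error is propagated from the replicate dishes of both conditions.
#'
#' @param treated,control Data frames with columns `cells_seeded` and
#'   `colonies`, one row per dish (typically 3 dishes per condition).
#' @return A list of class `survival_fraction` with elements `sf`, `se`,
#'   `n_treated`, `n_control`.
#' @export
#' @examples
#' trt <- data.frame(cells_seeded = 100, colonies = c(30, 35, 25))
#' ctl <- data.frame(cells_seeded = 100, colonies = c(60, 62, 58))
#' survival_fraction(trt, ctl)$sf
survival_fraction <- function(treated, control) {
  pe <- function(d, what) {
    if (!all(c("cells_seeded", "colonies") %in% names(d)))
      stop_borondose(sprintf("'%s' needs columns cells_seeded and colonies", what),
                     "borondose_validation_error")
    if (any(d$colonies < 0) || any(d$cells_seeded <= 0) ||
        any(d$colonies != round(d$colonies)))
      stop_borondose(sprintf("'%s' has invalid counts", what),
                     "borondose_validation_error")
    if (any(d$colonies > d$cells_seeded))
      stop_borondose(sprintf("'%s' has more colonies than cells seeded", what),
                     "borondose_validation_error")
    d$colonies / d$cells_seeded
  }
  pe_t <- pe(treated, "treated")
  pe_c <- pe(control, "control")
  m_c <- mean(pe_c)
  if (m_c <= 0)
    stop_borondose("control plating efficiency is zero: survival fraction undefined",
                   "borondose_undefined_sf_error")
  m_t <- mean(pe_t)
  if (m_t <= 0)
    stop_borondose("no colonies in any treated dish: survival fraction undefined",
                   "borondose_undefined_sf_error")
  sf <- m_t / m_c
  # delta-method SE from replicate dish scatter in both conditions
  rel_var <- function(x) {
    if (length(x) < 2L) return(NA_real_)
    stats::var(x) / length(x) / mean(x)^2
  }
  se <- sf * sqrt(rel_var(pe_t) + rel_var(pe_c))
  flagged <- sf > 1
  if (flagged)
    warning("survival fraction exceeds 1 (treated plating efficiency above control)",
            call. = FALSE)
  structure(list(sf = sf, se = se, n_treated = length(pe_t),
                 n_control = length(pe_c), flagged_gt1 = flagged),
            class = "survival_fraction")
}

#' @export
print.survival_fraction <- function(x, ...) {
  cat(sprintf("SF = %.4g (SE %.3g; %d treated / %d control dishes)\n",
              x$sf, x$se, x$n_treated, x$n_control))
  invisible(x)
}

#' LQ survival probability
#'
#' `SF(D) = exp(-alpha * D - beta * D^2)`.
#'
#' @param params An [lq_parameters()] object (or anything with `alpha`,
#'   `beta`, e.g. a fitted [lq_fit()] model).
#' @param dose Dose(s) in Gy (>= 0).
#' @return Survival fraction(s) in (0, 1].
#' @export
lq_survival <- function(params, dose) {
  check_numeric_vec(dose, "dose", min = 0)
  p <- as_lq_parameters(params)
  exp(-p$alpha * dose - p$beta * dose^2)
}

#' LQ model parameters
#'
#' @param alpha Linear coefficient, Gy^-1 (>= 0).
#' @param beta Quadratic coefficient, Gy^-2 (>= 0). Not both zero.
#' @return An object of class `lq_parameters`.
#' @export
lq_parameters <- function(alpha, beta) {
  check_number(alpha, "alpha", min = 0)
  check_number(beta, "beta", min = 0)
  if (alpha == 0 && beta == 0)
    stop_borondose("alpha and beta cannot both be zero",
                   "borondose_validation_error")
  structure(list(alpha = alpha, beta = beta), class = "lq_parameters")
}

as_lq_parameters <- function(x) {
  if (inherits(x, "lq_parameters")) return(x)
  if (inherits(x, "lq_fit")) return(lq_parameters(x$alpha, x$beta))
  if (is.list(x) && all(c("alpha", "beta") %in% names(x)))
    return(lq_parameters(x$alpha, x$beta))
  if (is.numeric(x) && length(x) == 2L)
    return(lq_parameters(x[[1L]], x[[2L]]))
  stop_borondose("cannot interpret 'params' as LQ parameters",
                 "borondose_validation_error")
}

#' @export
print.lq_parameters <- function(x, ...) {
  cat(sprintf("LQ parameters: alpha = %.5g /Gy, beta = %.5g /Gy^2 (alpha/beta = %.3g Gy)\n",
              x$alpha, x$beta, if (x$beta > 0) x$alpha / x$beta else Inf))
  invisible(x)
}

#' Isoeffective dose for a target survival fraction
#'
#' Inverts the LQ model: the unique non-negative root of
#' `beta*D^2 + alpha*D - ln(1/sf_target) = 0`, i.e.
#' `D = (-alpha + sqrt(alpha^2 + 4*beta*ln(1/sf)))/(2*beta)`, with the pure
#' exponential limit `ln(1/sf)/alpha` taken analytically when `beta` is zero.
#'
#' @inheritParams lq_survival
#' @param sf_target Target survival fraction in (0, 1].
#' @return Dose in Gy.
#' @export
#' @examples
#' p <- lq_parameters(0.217, 0.0217)
#' dose_for_sf(p, 0.1)
dose_for_sf <- function(params, sf_target) {
  check_number(sf_target, "sf_target")
  if (sf_target <= 0 || sf_target > 1)
    stop_borondose("'sf_target' must be in (0, 1]", "borondose_validation_error")
  p <- as_lq_parameters(params)
  L <- log(1 / sf_target)
  if (L == 0) return(0)
  if (p$beta == 0) return(L / p$alpha)
  (-p$alpha + sqrt(p$alpha^2 + 4 * p$beta * L)) / (2 * p$beta)
}

#' Beam relative biological effectiveness
#'
#' Ratio of the reference photon dose to the beam physical dose producing the
#' same survival endpoint (conventionally SF = 0.1).
#'
#' @param d_photon_ref Photon dose at the endpoint, Gy (> 0).
#' @param d_beam Beam physical dose at the same endpoint, Gy (> 0).
#' @return Dimensionless RBE.
#' @export
beam_rbe <- function(d_photon_ref, d_beam) {
  check_number(d_photon_ref, "d_photon_ref", min = 0)
  check_number(d_beam, "d_beam", min = 0)
  if (d_photon_ref <= 0 || d_beam <= 0)
    stop_borondose("endpoint doses must be > 0", "borondose_validation_error")
  d_photon_ref / d_beam
}

## -- LQ model fitting ---------------------------------------------------------

#' Fit the linear-quadratic model to clonogenic survival data
#'
#' Weighted least squares on the log scale: `-ln SF = alpha*D + beta*D^2`,
#' with weights `1/SE_ln^2` when standard errors are supplied (the standard
#' treatment for clonogenic data; it stabilises the low-SF tail).  Alpha and
#' beta are constrained to be non-negative; the unconstrained estimates are
#' kept in the returned object as diagnostics.
#'
#' @param dose Doses in Gy (>= 3 distinct positive values required).
#' @param sf Survival fractions in (0, 1], same length as `dose`.  Either a
#'   numeric vector or a list of [survival_fraction()] objects.
#' @param se Optional standard errors of `sf` (on the natural scale);
#'   extracted automatically when `sf` is a list of `survival_fraction`s.
#' @return An object of class `lq_fit` with elements `alpha`, `beta`,
#'   `unconstrained` (named vector), `dose`, `sf`, `se`, `weights`,
#'   `fitted` (fitted SF), `df.residual`.
#' @seealso [dose_for_sf()], [lq_survival()], [confint.lq_fit()]
#' @export
#' @examples
#' d <- c(2, 4, 6, 8)
#' s <- lq_survival(lq_parameters(0.2, 0.03), d)
#' coef(lq_fit(d, s))
lq_fit <- function(dose, sf, se = NULL) {
  if (is.list(sf) && all(vapply(sf, inherits, TRUE, "survival_fraction"))) {
    if (is.null(se)) se <- vapply(sf, `[[`, 0, "se")
    sf <- vapply(sf, `[[`, 0, "sf")
  }
  check_numeric_vec(dose, "dose", min = 0)
  check_numeric_vec(sf, "sf")
  if (length(dose) != length(sf))
    stop_borondose("'dose' and 'sf' must have the same length",
                   "borondose_validation_error")
  if (any(sf <= 0) || any(sf > 1 + 1e-9))
    stop_borondose("'sf' values must be in (0, 1]", "borondose_validation_error")
  keep <- dose > 0
  if (length(unique(dose[keep])) < 3L)
    stop_borondose("need at least 3 distinct positive doses to fit alpha and beta",
                   "borondose_insufficient_data_error")
  if (all(abs(sf - 1) < 1e-12))
    stop_borondose("all survival fractions are 1: degenerate fit",
                   "borondose_degenerate_fit_error")
  d <- dose[keep]
  y <- -log(sf[keep])
  if (!is.null(se)) {
    check_numeric_vec(se[keep][!is.na(se[keep])], "se", min = 0)
    se_ln <- se[keep] / sf[keep]          # delta method to the log scale
    w <- ifelse(is.na(se_ln) | se_ln <= 0, NA, 1 / se_ln^2)
    if (anyNA(w)) w[is.na(w)] <- max(w, na.rm = TRUE)
  } else {
    w <- rep(1, length(d))
  }
  X <- cbind(D = d, D2 = d^2)
  est <- nnls2(X, y, w)
  fit <- structure(
    list(alpha = est$coef[1L], beta = est$coef[2L],
         unconstrained = c(alpha = est$ols[1L], beta = est$ols[2L]),
         dose = dose, sf = sf, se = se, weights = w,
         df.residual = length(d) - 2L,
         call = match.call()),
    class = "lq_fit"
  )
  fit$fitted <- lq_survival(fit, dose)
  fit
}

#' Fit the LQ model directly from a colony-assay table
#'
#' Computes per-dose survival fractions (normalised to the dose-0 control via
#' [survival_fraction()]) and fits the LQ model.  The dish-level counts are
#' retained in the returned object, which lets [confint.lq_fit()] bootstrap
#' at the colony-count level.
#'
#' @param assay Data frame with columns `dose_gy`, `cells_seeded`, `dish_id`,
#'   `colonies`; rows with `dose_gy == 0` are the unirradiated control.
#' @return An [lq_fit()] object with the assay attached.
#' @export
#' @examples
#' assay <- gen_colony_assay(lq_parameters(0.2, 0.03), seed = 1)
#' fit <- lq_fit_assay(assay)
#' coef(fit)
lq_fit_assay <- function(assay) {
  req <- c("dose_gy", "cells_seeded", "colonies")
  if (!all(req %in% names(assay)))
    stop_borondose(paste("assay needs columns:", paste(req, collapse = ", ")),
                   "borondose_validation_error")
  ctl <- assay[assay$dose_gy == 0, ]
  if (!nrow(ctl))
    stop_borondose("assay has no dose-0 control rows",
                   "borondose_validation_error")
  doses <- sort(setdiff(unique(assay$dose_gy), 0))
  sfs <- lapply(doses, function(d) {
    survival_fraction(assay[assay$dose_gy == d, ], ctl)
  })
  fit <- lq_fit(doses, sfs)
  fit$assay <- assay
  fit
}

## tiny non-negative weighted least squares for the 2-column LQ design:
## unconstrained solve, then active-set clamping (exact for 2 parameters)
nnls2 <- function(X, y, w) {
  W <- w
  xtx <- crossprod(X * W, X)
  xty <- crossprod(X * W, y)
  ols <- tryCatch(drop(solve(xtx, xty)), error = function(e) c(NA_real_, NA_real_))
  one_col <- function(j) {
    b <- sum(W * y * X[, j]) / sum(W * X[, j]^2)
    max(b, 0)
  }
  coef <- ols
  if (anyNA(coef) || any(coef < 0)) {
    cand <- list(c(one_col(1L), 0), c(0, one_col(2L)))
    rss <- vapply(cand, function(b) sum(W * (y - X %*% b)^2), 0)
    coef <- cand[[which.min(rss)]]
  }
  list(coef = unname(coef), ols = unname(ols))
}

#' @export
print.lq_fit <- function(x, digits = 4, ...) {
  cat("Linear-quadratic clonogenic survival fit\n")
  cat(sprintf("  alpha = %.*g /Gy, beta = %.*g /Gy^2\n",
              digits, x$alpha, digits, x$beta))
  cat(sprintf("  dose at SF = 0.1: %.*g Gy\n", digits, dose_for_sf(x, 0.1)))
  invisible(x)
}

#' @export
coef.lq_fit <- function(object, ...) c(alpha = object$alpha, beta = object$beta)

#' @export
residuals.lq_fit <- function(object, type = c("log", "response"), ...) {
  type <- match.arg(type)
  if (type == "log") -log(object$sf) - (-log(object$fitted))
  else object$sf - object$fitted
}

#' Predict survival fractions from a fitted LQ model
#'
#' @param object An [lq_fit()] object.
#' @param newdose Doses (Gy) at which to evaluate the fitted curve; defaults
#'   to the doses used in the fit.
#' @param ... Unused.
#' @return Predicted survival fractions.
#' @export
predict.lq_fit <- function(object, newdose = object$dose, ...) {
  lq_survival(object, newdose)
}

#' @export
summary.lq_fit <- function(object, ...) {
  out <- list(
    coef = coef(object),
    unconstrained = object$unconstrained,
    alpha_beta_ratio = if (object$beta > 0) object$alpha / object$beta else Inf,
    d10 = dose_for_sf(object, 0.1),
    rss_log = sum(object$weights * residuals(object)[object$dose > 0]^2,
                  na.rm = TRUE),
    df.residual = object$df.residual
  )
  class(out) <- "summary.lq_fit"
  out
}

#' @export
print.summary.lq_fit <- function(x, digits = 4, ...) {
  cat("Linear-quadratic fit summary\n")
  cat(sprintf("  alpha      : %.*g /Gy\n", digits, x$coef["alpha"]))
  cat(sprintf("  beta       : %.*g /Gy^2\n", digits, x$coef["beta"]))
  cat(sprintf("  alpha/beta : %.*g Gy\n", digits, x$alpha_beta_ratio))
  cat(sprintf("  D(SF=0.1)  : %.*g Gy\n", digits, x$d10))
  cat(sprintf("  weighted RSS (log scale): %.*g on %d df\n",
              digits, x$rss_log, x$df.residual))
  if (any(x$unconstrained < 0, na.rm = TRUE))
    cat("  note: unconstrained estimate was negative (",
        paste(sprintf("%s=%.3g", names(x$unconstrained), x$unconstrained),
              collapse = ", "), "); constrained to the boundary\n", sep = "")
  invisible(x)
}

#' Bootstrap confidence intervals for LQ parameters
#'
#' Percentile intervals from a parametric bootstrap.  For fits built with
#' [lq_fit_assay()] the bootstrap works at the colony-count level: dish
#' counts are redrawn as Poisson around each condition's observed mean,
#' survival fractions recomputed and the model refitted, mirroring the
#' assay's actual noise process.  For fits from survival fractions alone,
#' replicate data sets are drawn on the log-survival scale as
#' `-ln SF* ~ N(-ln SF_obs, SE_ln^2)` (requires standard errors).
#'
#' @param object An [lq_fit()] object.
#' @param parm Parameters to report (default both).
#' @param level Confidence level (default 0.95).
#' @param B Number of bootstrap replicates (default 199).
#' @param seed Optional seed for reproducibility (RNG state is restored).
#' @param ... Unused.
#' @return Matrix with one row per parameter, columns lower/upper.
#' @export
confint.lq_fit <- function(object, parm = c("alpha", "beta"), level = 0.95,
                           B = 199L, seed = NULL, ...) {
  draws <- if (!is.null(object$assay)) {
    boot_lq_poisson(object$assay, B, seed)
  } else {
    if (is.null(object$se))
      stop_borondose("bootstrap CI needs standard errors (or an lq_fit_assay fit)",
                     "borondose_insufficient_data_error")
    keep <- object$dose > 0
    d <- object$dose[keep]
    y <- -log(object$sf[keep])
    se_ln <- object$se[keep] / object$sf[keep]
    w <- object$weights
    X <- cbind(d, d^2)
    with_preserved_seed(seed, {
      t(vapply(seq_len(B), function(i) {
        ystar <- y + stats::rnorm(length(y), 0, se_ln)
        nnls2(X, ystar, w)$coef
      }, numeric(2L)))
    })
  }
  colnames(draws) <- c("alpha", "beta")
  a <- (1 - level) / 2
  out <- t(apply(draws[, parm, drop = FALSE], 2L, stats::quantile,
                 probs = c(a, 1 - a), names = FALSE, na.rm = TRUE))
  colnames(out) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  out
}

## Poisson parametric bootstrap over dish counts; returns B x 2 coefficients
boot_lq_poisson <- function(assay, B, seed) {
  conds <- split(assay, assay$dose_gy)
  dose <- as.numeric(names(conds))
  lam <- vapply(conds, function(d) mean(d$colonies), 0)
  seeded <- lapply(conds, `[[`, "cells_seeded")
  ndish <- vapply(seeded, length, 0L)
  i0 <- which(dose == 0)
  pos <- which(dose > 0)
  X <- cbind(dose[pos], dose[pos]^2)
  with_preserved_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      pe <- vapply(seq_along(conds), function(j) {
        counts <- pmin(stats::rpois(ndish[j], lam[j]), seeded[[j]])
        p <- counts / seeded[[j]]
        c(mean(p), if (ndish[j] > 1L) stats::var(p) / ndish[j] else NA_real_)
      }, numeric(2L))
      m <- pe[1L, ]; v <- pe[2L, ]
      if (m[i0] <= 0 || any(m[pos] <= 0)) return(c(NA_real_, NA_real_))
      sf <- m[pos] / m[i0]
      # weights from the delta-method SE of -ln SF
      se_ln2 <- v[pos] / m[pos]^2 + v[i0] / m[i0]^2
      w <- ifelse(is.na(se_ln2) | se_ln2 <= 0, NA, 1 / se_ln2)
      if (anyNA(w)) w[is.na(w)] <- max(w, na.rm = TRUE)
      nnls2(X, -log(sf), w)$coef
    }, numeric(2L)))
  })
}

#' Plot a fitted LQ survival curve
#'
#' Observed survival fractions (log scale) with the fitted curve.
#'
#' @param x An [lq_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lq_fit <- function(x, ...) {
  dg <- seq(0, max(x$dose) * 1.05, length.out = 200L)
  graphics::plot(x$dose, x$sf, log = "y", xlab = "Dose (Gy)",
                 ylab = "Survival fraction", pch = 19, ...)
  graphics::lines(dg, lq_survival(x, dg))
  if (!is.null(x$se)) {
    graphics::arrows(x$dose, pmax(x$sf - x$se, 1e-6), x$dose, x$sf + x$se,
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}
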