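test_that("survival fraction normalises plating efficiency to control", {
  ctl <- data.frame(cells_seeded = 100, colonies = c(60, 62, 58))

  # treated PE equal to control -> SF = 1
  expect_equal(survival_fraction(ctl, ctl)$sf, 1.0)

  # hand arithmetic: mean(30,35,25)/100 = 0.30; control PE 0.60 -> 0.50
  trt <- data.frame(cells_seeded = 100, colonies = c(30, 35, 25))
  ctl2 <- data.frame(cells_seeded = 100, colonies = c(60, 60, 60))
  res <- survival_fraction(trt, ctl2)
  expect_equal(res$sf, 0.5)
  expect_true(res$se > 0)

  # degenerate inputs
  expect_error(
    survival_fraction(data.frame(cells_seeded = 100, colonies = c(0, 0, 0)), ctl),
    class = "borondose_undefined_sf_error")
  expect_error(
    survival_fraction(trt, data.frame(cells_seeded = 100, colonies = c(0, 0, 0))),
    class = "borondose_undefined_sf_error")
  expect_warning(
    survival_fraction(data.frame(cells_seeded = 100, colonies = c(70, 72, 71)), ctl2),
    "exceeds 1")
  expect_error(
    survival_fraction(data.frame(cells_seeded = 10, colonies = 20), ctl),
    class = "borondose_validation_error")
})

test_that("LQ survival model behaves as exp(-aD - bD^2)", {
  set.seed(21)
  for (i in 1:20) {
    a <- runif(1, 0.01, 0.5); b <- runif(1, 0, 0.1)
    p <- lq_parameters(a, max(b, 1e-6))
    expect_equal(lq_survival(p, 0), 1.0)
    d <- sort(runif(5, 0, 10))
    expect_true(all(diff(lq_survival(p, d)) < 0))  # strictly decreasing
  }
  # beta = 0 limit: pure exponential
  expect_equal(lq_survival(lq_parameters(0.3, 0), c(1, 5)),
               exp(-0.3 * c(1, 5)))
  expect_error(lq_survival(lq_parameters(0.1, 0.1), -1),
               class = "borondose_validation_error")
  expect_error(lq_parameters(0, 0), class = "borondose_validation_error")
})

test_that("endpoint-dose inversion is the exact inverse of the LQ model", {
  set.seed(22)
  for (i in 1:30) {
    p <- lq_parameters(runif(1, 0.01, 0.5), runif(1, 0, 0.1))
    s <- runif(1, 0.001, 1)
    expect_equal(lq_survival(p, dose_for_sf(p, s)), s, tolerance = 1e-9)
  }
  p <- lq_parameters(0.2, 0.03)
  expect_identical(dose_for_sf(p, 1), 0)
  # beta -> 0 analytic limit
  expect_equal(dose_for_sf(lq_parameters(0.25, 0), 0.1), log(10) / 0.25)
  # monotone decreasing in the target SF
  sf_seq <- c(0.9, 0.5, 0.1, 0.01)
  expect_true(all(diff(vapply(sf_seq, function(s) dose_for_sf(p, s), 0)) > 0))
  expect_error(dose_for_sf(p, 0), class = "borondose_validation_error")
  expect_error(dose_for_sf(p, 1.2), class = "borondose_validation_error")
})

test_that("any alpha/beta pair on the 6.45 Gy isoeffect line inverts to 6.45 Gy", {
  # constraint alpha*D + beta*D^2 = ln 10 at D = 6.45 (photon SF = 0.1)
  set.seed(23)
  for (ratio in c(1, 3, 10, 30, runif(3, 0.5, 50))) {
    beta <- log(10) / (ratio * 6.45 + 6.45^2)
    p <- lq_parameters(ratio * beta, beta)
    expect_equal(dose_for_sf(p, 0.1), 6.45, tolerance = 1e-9)
  }
  # the preset photon reference is built on that constraint
  expect_equal(dose_for_sf(lq_xray_parameters(), 0.1), 6.45, tolerance = 1e-12)
})

test_that("LQ fit recovers parameters exactly from noise-free data", {
  set.seed(31)
  for (i in 1:10) {
    a0 <- runif(1, 0.05, 0.4); b0 <- runif(1, 0.005, 0.08)
    d <- c(0, 1.5, 3, 5, 7.5)
    s <- lq_survival(lq_parameters(a0, b0), d)
    fit <- lq_fit(d, s)
    expect_equal(fit$alpha, a0, tolerance = 1e-6)
    expect_equal(fit$beta, b0, tolerance = 1e-6)
    # fit on its own output is idempotent
    refit <- lq_fit(d, predict(fit))
    expect_equal(coef(refit), coef(fit), tolerance = 1e-9)
  }
  expect_error(lq_fit(c(2, 2, 2), c(0.5, 0.4, 0.45)),
               class = "borondose_insufficient_data_error")
  expect_error(lq_fit(c(1, 2, 3), c(1, 1, 1)),
               class = "borondose_degenerate_fit_error")
})

test_that("LQ fit enforces non-negative parameters and reports diagnostics", {
  # data with upward curvature on the log scale but a negative linear trend
  d <- c(1, 2, 4, 8)
  y <- 0.05 * d^2 - 0.01 * d        # unconstrained alpha < 0
  fit <- lq_fit(d, exp(-pmax(y, 1e-6)))
  expect_gte(fit$alpha, 0)
  expect_gte(fit$beta, 0)
  expect_true(fit$unconstrained["alpha"] < 0)
  s <- summary(fit)
  expect_s3_class(s, "summary.lq_fit")
  expect_equal(unname(s$coef), c(fit$alpha, fit$beta))
})

test_that("bootstrap confidence intervals cover a planted truth", {
  p0 <- lq_parameters(0.217, 0.0217)
  assay <- gen_colony_assay(p0, doses = c(0, 2, 4, 6, 8), seed = 42)
  fit <- lq_fit_assay(assay)
  ci <- confint(fit, B = 399, seed = 1)
  # the SF-only fallback (log-normal parametric bootstrap) also works
  fit_sf <- lq_fit(fit$dose, fit$sf, fit$se)
  ci_sf <- confint(fit_sf, B = 199, seed = 2)
  expect_true(all(is.finite(ci_sf)))
  expect_true(ci["alpha", 1] <= 0.217 && 0.217 <= ci["alpha", 2])
  expect_true(ci["beta", 1] <= 0.0217 && 0.0217 <= ci["beta", 2])
  expect_true(all(ci[, 2] > ci[, 1]))
})

test_that("beam RBE is the isoeffective photon/beam dose ratio", {
  expect_equal(beam_rbe(5, 5), 1)
  expect_equal(beam_rbe(6.45, 3.225), 2)
  expect_error(beam_rbe(6.45, 0), class = "borondose_validation_error")

  # grid-search oracle: endpoint doses found by brute force on both curves
  photon <- lq_parameters(0.217, 0.0217)
  beam <- lq_parameters(0.9, 0.05)     # steeper high-LET response
  grid <- seq(0.001, 12, by = 0.001)
  d_ph <- grid[which.min(abs(lq_survival(photon, grid) - 0.1))]
  d_bm <- grid[which.min(abs(lq_survival(beam, grid) - 0.1))]
  rbe_grid <- d_ph / d_bm
  rbe_analytic <- beam_rbe(dose_for_sf(photon, 0.1), dose_for_sf(beam, 0.1))
  expect_equal(rbe_analytic, rbe_grid, tolerance = 0.01)
})

test_that("carrier CBE inverts the photon-equivalent equation exactly", {
  # boron-only field: reference equals the boron dose -> CBE = 1
  only_b <- dose_components_nh(d_boron = 2.5, d_nh = 0, d_gamma = 0)
  expect_equal(carrier_cbe(2.5, only_b), 1)

  # planted-CBE round trip through photon_equivalent_dose
  set.seed(41)
  for (i in 1:25) {
    cbe0 <- runif(1, 0.3, 4)
    cmp <- dose_components_nh(d_boron = runif(1, 0.5, 4),
                              d_nh = runif(1, 0, 1), d_gamma = runif(1, 0, 2))
    ref <- photon_equivalent_dose(cmp, radiobiological_factors(cbe0, 3, 3))
    expect_equal(carrier_cbe(ref, cmp), cbe0, tolerance = 1e-9)
  }

  expect_error(carrier_cbe(6.45, dose_components_nh(0, 0.5, 1.1)),
               class = "borondose_validation_error")
  expect_warning(
    cbe <- carrier_cbe(1.0, dose_components_nh(1, 0.5, 1.1)),
    "negative")
  expect_lt(cbe, 0)
})

test_that("beam-fraction model calibration reproduces the reference CBE", {
  m <- beam_fraction_model(ladder_time_s = c(0, 600, 1200, 1800),
                           ladder_dose_gy = c(0, 0.48, 1.01, 1.21),
                           nh_fraction = 0.3125, rbe_nh = 3)
  # ladder inversion: interior interpolation and extrapolation beyond 30 min
  expect_equal(ladder_time_at_dose(m, 0.48), 600)
  expect_equal(ladder_time_at_dose(m, 0.745), 600 + 600 * 0.265 / 0.53)
  expect_gt(ladder_time_at_dose(m, 1.48), 1800)

  expect_error(endpoint_components(m, 0.75), class = "borondose_config_error")

  mc <- calibrate_boron_rate(m, d_photon_ref = 6.45,
                             endpoint_dose_ref = 0.75, cbe_ref = 2.69)
  expect_equal(carrier_cbe(6.45, 0.75, mc), 2.69, tolerance = 1e-12)

  # decomposition at the calibration point reconstructs the reference dose
  cmp <- endpoint_components(mc, 0.75)
  expect_equal(photon_equivalent_dose(cmp, radiobiological_factors(2.69, 3, 3)),
               6.45, tolerance = 1e-12)
})
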