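test_that("boron capture dose is linear in concentration, fluence and time", {
  k <- 2.5e-13
  beam <- beam_spec(thermal_flux = 1e9, kerma = c(B10 = k))

  expect_identical(boron_dose(beam, exposure_spec(600, 0)), 0)

  # hand computation: k * flux * t * C
  expect_equal(boron_dose(beam, exposure_spec(100, 10)),
               10 * k * 1e9 * 100, tolerance = 1e-12)

  # degree-1 homogeneity in each argument separately
  set.seed(11)
  for (i in 1:20) {
    conc <- runif(1, 1, 50); t <- runif(1, 10, 2000); s <- runif(1, 0.1, 5)
    base <- boron_dose(beam, exposure_spec(t, conc))
    expect_equal(boron_dose(beam, exposure_spec(t, s * conc)), s * base)
    expect_equal(boron_dose(beam, exposure_spec(s * t, conc)), s * base)
    beam2 <- beam_spec(thermal_flux = s * 1e9, kerma = c(B10 = k))
    expect_equal(boron_dose(beam2, exposure_spec(t, conc)), s * base)
  }

  expect_error(boron_dose(beam_spec(1e9), exposure_spec(600, 10)),
               class = "borondose_config_error")
  expect_error(exposure_spec(-1, 10), class = "borondose_validation_error")
  expect_error(beam_spec(-1), class = "borondose_validation_error")
})

test_that("total physical dose is the component sum", {
  expect_identical(total_physical_dose(dose_components(0, 0, 0, 0)), 0)

  set.seed(7)
  for (i in 1:50) {
    x <- runif(4, 0, 2)
    cmp <- dose_components(x[1], x[2], x[3], x[4])
    expect_equal(total_physical_dose(cmp), sum(x), tolerance = 1e-12)
  }

  # boron-free field equals the beam-only dose
  cmp <- dose_components(0, 0.2, 0.3, 1.1)
  expect_equal(total_physical_dose(cmp), 1.6)

  expect_error(dose_components(-0.1, 0, 0, 0),
               class = "borondose_validation_error")
})

test_that("photon-equivalent dose reduces to the physical dose at unit factors", {
  unit <- radiobiological_factors(cbe = 1, rbe_n = 1, rbe_h = 1)
  expect_equal(
    photon_equivalent_dose(dose_components(0.5, 0.2, 0.3, 1.1), unit), 2.1)
  expect_equal(
    photon_equivalent_dose(dose_components(0, 0, 0, 0),
                           radiobiological_factors(5, 3, 3)), 0)
  set.seed(3)
  for (i in 1:25) {
    x <- runif(4, 0, 3)
    cmp <- dose_components(x[1], x[2], x[3], x[4])
    expect_identical(photon_equivalent_dose(cmp, unit),
                     total_physical_dose(cmp))
  }
})

test_that("photon-equivalent dose applies CBE/RBE weights and guards unknown CBE", {
  f <- radiobiological_factors(cbe = 2.69, rbe_n = 3, rbe_h = 3)
  cmp <- dose_components_nh(d_boron = 3.0, d_nh = 0.5, d_gamma = 1.1)
  expect_equal(photon_equivalent_dose(cmp, f), 2.69 * 3 + 3 * 0.5 + 1.1)

  # unknown CBE: weighted dose undefined for a boron-loaded field ...
  unknown <- radiobiological_factors(cbe = NA)
  expect_error(photon_equivalent_dose(cmp, unknown),
               class = "borondose_factor_unknown_error")
  # ... but fine for a boron-free one
  beam_only <- dose_components_nh(d_boron = 0, d_nh = 0.5, d_gamma = 1.1)
  expect_equal(photon_equivalent_dose(beam_only, unknown), 2.6)

  expect_error(radiobiological_factors(cbe = -1),
               class = "borondose_validation_error")
})

test_that("beam-only dose pair splits uniquely and round-trips", {
  # published beam-only row: 1.6 Gy physical, 2.6 Gy-Eq at RBE 3
  sp <- beam_component_split(1.6, 2.6, 3.0)
  expect_equal(unname(sp), c(0.5, 1.1), tolerance = 1e-12)

  # equal totals mean no high-LET component
  sp0 <- beam_component_split(2.3, 2.3, 3.0)
  expect_equal(unname(sp0), c(0, 2.3))

  # split -> recombine is the identity on valid pairs
  set.seed(5)
  for (i in 1:30) {
    nh <- runif(1, 0, 2); g <- runif(1, 0, 2); rbe <- runif(1, 1.5, 4)
    phys <- nh + g
    pe <- rbe * nh + g
    sp <- beam_component_split(phys, pe, rbe)
    cmp <- dose_components_nh(0, sp[["d_nh"]], sp[["d_gamma"]])
    expect_equal(total_physical_dose(cmp), phys, tolerance = 1e-12)
    expect_equal(
      photon_equivalent_dose(cmp, radiobiological_factors(1, rbe, rbe)),
      pe, tolerance = 1e-12)
  }

  expect_error(beam_component_split(2.6, 1.6, 3),
               class = "borondose_inconsistent_error")
  expect_error(beam_component_split(1, 4, 3),
               class = "borondose_inconsistent_error")
  expect_error(beam_component_split(1.6, 2.6, 1),
               class = "borondose_validation_error")
})

test_that("tumor photon-equivalent reconstruction uses the beam row correctly", {
  # D_B = 4.6 - 1.6 = 3.0; weighted = 2.69*3 + 3*0.5 + 1.1
  expect_equal(tumor_photon_equivalent(4.6, 1.6, 2.6, cbe = 2.69),
               2.69 * 3 + 1.5 + 1.1, tolerance = 1e-12)
  expect_error(tumor_photon_equivalent(1.0, 1.6, 2.6, cbe = 2),
               class = "borondose_inconsistent_error")
})
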