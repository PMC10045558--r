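test_that("generators are deterministic under a fixed seed", {
  p0 <- lq_parameters(0.217, 0.0217)
  expect_identical(gen_colony_assay(p0, seed = 5), gen_colony_assay(p0, seed = 5))
  expect_identical(gen_tissue_biodistribution(seed = 5),
                   gen_tissue_biodistribution(seed = 5))
  expect_identical(gen_survival(seed = 5), gen_survival(seed = 5))
  expect_identical(gen_cellular_uptake(cv = 0.05, seed = 5),
                   gen_cellular_uptake(cv = 0.05, seed = 5))
  expect_false(identical(gen_survival(seed = 5), gen_survival(seed = 6)))

  # a generator must not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(gen_survival(seed = 123)); after <- runif(3)
  expect_identical(before, after)
})

test_that("colony generator emulates Poisson dish counts under the truth", {
  p0 <- lq_parameters(0.217, 0.0217)
  tab <- gen_colony_assay(p0, doses = c(0, 2, 4, 6, 8), seed = 1)
  expect_equal(nrow(tab), 5 * 3)
  expect_true(all(tab$colonies <= tab$cells_seeded))
  expect_true(all(tab$colonies >= 0 & tab$colonies == round(tab$colonies)))

  # SF == 1 everywhere: treated dishes are distributed like control dishes
  flat <- gen_colony_assay(function(d) 1, doses = c(0, 2, 4), seed = 2)
  expect_true(length(unique(flat$cells_seeded)) == 1L)

  # an SF model exceeding 1 is rejected
  expect_error(gen_colony_assay(function(d) 1.2, doses = c(0, 2, 4)),
               class = "borondose_validation_error")

  # recovery loop: fit on generated data lands inside the bootstrap CI
  assay <- gen_colony_assay(p0, doses = c(0, 2, 4, 6, 8), seed = 7)
  fit <- lq_fit_assay(assay)
  ci <- confint(fit, B = 399, seed = 11)
  expect_true(ci["alpha", 1] <= 0.217 && 0.217 <= ci["alpha", 2])
  expect_true(ci["beta", 1] <= 0.0217 && 0.0217 <= ci["beta", 2])
})

test_that("tissue generator is calibrated to the preset summary grid", {
  grid <- preset_tissue_grid()

  # SD = 0: every replicate equals the preset mean, and the ratio pipeline
  # reproduces the printed tumor/blood column exactly
  grid0 <- grid; grid0$sd <- 0
  tab0 <- gen_tissue_biodistribution(grid0, seed = 3)
  s0 <- summarize_tissue(tab0)
  expect_equal(s0$mean[match(paste(grid0$carrier, grid0$time_h, grid0$tissue),
                             paste(s0$carrier, s0$time_h, s0$tissue))],
               grid0$mean)
  r0 <- tissue_ratios(s0)
  key <- paste(r0$carrier, r0$time_h)
  expect_equal(r0$t_bl_display[match(c("BPA 2.5", "BPA 8", "BPA 24"), key)],
               c(2.7, 3.8, 2.8))
  expect_equal(r0$t_bl_display[match(c("cRGD-MID-AC 2.5", "cRGD-MID-AC 8",
                                       "cRGD-MID-AC 24"), key)],
               c(0.2, 0.4, 0.7))

  # calibrated noise: cell means recovered within 2 SD / sqrt(n) in >= 95%
  # of cells over 200 regenerations
  set.seed(55)
  seeds <- sample.int(1e6, 200)
  hits <- 0L; total <- 0L
  for (sd_i in seeds) {
    s <- summarize_tissue(gen_tissue_biodistribution(grid, seed = sd_i))
    m <- match(paste(grid$carrier, grid$time_h, grid$tissue),
               paste(s$carrier, s$time_h, s$tissue))
    dev <- abs(s$mean[m] - grid$mean) <= 2 * grid$sd / sqrt(grid$n)
    hits <- hits + sum(dev); total <- total + length(dev)
  }
  expect_gte(hits / total, 0.95)

  expect_error(gen_tissue_biodistribution(transform(grid, mean = -mean)),
               class = "borondose_validation_error")
})

test_that("survival generator matches its calibration targets", {
  groups <- preset_survival_groups()

  # degenerate scale: all times equal the preset median, %ILS exact
  g0 <- groups; g0$sd <- 0
  rec0 <- gen_survival(g0, censor_horizon_days = Inf, seed = 1)
  med0 <- tapply(rec0$days, rec0$group, unique)
  expect_equal(as.numeric(med0[g0$group]), g0$median)

  # censoring horizon below all times: everything censored, KM flat at 1
  recc <- gen_survival(groups[1, , drop = FALSE], censor_horizon_days = 10,
                       seed = 2)
  expect_true(all(recc$event == 0) && all(recc$days == 10))
  expect_equal(km_survival_at(km_curve(recc$days, recc$event), 99), 1)

  # moment-matched log-normal calibration: for the two lowest-variation
  # groups the sample median lands within +/-4 days of the preset median in
  # >= 90% of 500 regenerations (small-n sample-median spread rules this out
  # for the wider groups); for every group the Monte-Carlo centre of the
  # sample medians sits within 2 days of the model median implied by mean/SD
  low_cv <- c("untreated", "BNCT using BPA 2.5 h")
  set.seed(66)
  seeds <- sample.int(1e6, 500)
  meds <- sapply(seeds, function(sd_i) {
    rec <- gen_survival(groups, seed = sd_i)
    tapply(rec$days, rec$group, function(x) unname(median_survival(km_curve(x, rep(1, length(x))))))[groups$group]
  })
  within4 <- rowMeans(abs(meds - groups$median) <= 4)
  names(within4) <- groups$group
  expect_true(all(within4[low_cv] >= 0.9))
  sdlog2 <- log(1 + (groups$sd / groups$mean)^2)
  model_median <- exp(log(groups$mean) - sdlog2 / 2)
  expect_true(all(abs(apply(meds, 1, median) - model_median) < 2))

  expect_error(gen_survival(transform(groups, sd = -1)),
               class = "borondose_validation_error")
})

test_that("cellular uptake generator hits retention targets and orderings", {
  up <- gen_cellular_uptake()   # noise-free

  # retention at +1 h equals the configured target for every cell/carrier
  r1 <- retention_rate(up, 1)
  cu <- bnct_presets()$cellular_uptake
  for (i in seq_len(nrow(r1))) {
    target <- cu$retention_1h_pct[[r1$cell_line[i]]][[r1$carrier[i]]]
    expect_equal(r1$retention_pct[i], target, tolerance = 0.1 / target)
  }
  f98 <- r1[r1$cell_line == "F98", ]
  expect_equal(f98$retention_pct[match(c("BPA", "cRGD-MID-AC", "cRGD+MID"),
                                       f98$carrier)],
               c(14.7, 74.6, 65.2), tolerance = 1e-9)

  # BPA washes out faster than the albumin conjugate at every washout time
  for (tw in c(1, 6, 24)) {
    rw <- retention_rate(up[up$cell_line == "F98", ], tw)
    expect_lt(rw$retention_pct[rw$carrier == "BPA"],
              rw$retention_pct[rw$carrier == "cRGD-MID-AC"])
  }

  # zero washout rate (retention target 100%) keeps retention at 100 always
  p100 <- bnct_presets()
  for (cl in p100$cellular_uptake$cell_lines)
    p100$cellular_uptake$retention_1h_pct[[cl]] <-
      lapply(p100$cellular_uptake$retention_1h_pct[[cl]], function(x) 100)
  up100 <- gen_cellular_uptake(p100)
  for (tw in c(1, 6, 24))
    expect_true(all(retention_rate(up100, tw)$retention_pct == 100))

  # invalid retention target is rejected
  pbad <- bnct_presets()
  pbad$cellular_uptake$retention_1h_pct$F98$BPA <- 120
  expect_error(gen_cellular_uptake(pbad), class = "borondose_validation_error")

  # exposure concentrations rise monotonically during uptake
  f98_bpa <- up[up$cell_line == "F98" & up$carrier == "BPA" &
                  up$phase == "exposure", ]
  expect_true(all(diff(f98_bpa$ug_b_per_1e9_cells[order(f98_bpa$time_h)]) > 0))
})
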