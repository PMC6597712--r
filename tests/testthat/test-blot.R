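test_that("loading normalization rescales lanes by their loading factor", {
  mk <- function(load_scale) {
    DensitometryTable(data.frame(
      lane = paste0("L", 1:4), role = c(rep("standard", 3), "unknown"),
      band_density = c(1000, 2000, 3000, 1500),
      load1 = 400 * load_scale, load2 = 500 * load_scale,
      load3 = 600 * load_scale,
      known_conc = c(2, 4, 6, NA)))
  }
  eq <- normalizeLoading(mk(rep(1, 4)))
  expect_equal(laneData(eq)$band_density, c(1000, 2000, 3000, 1500))
  # one lane loaded 10% high against three equal lanes
  hi <- normalizeLoading(mk(c(1, 1, 1, 1.1)))
  d <- laneData(hi)
  grand <- mean(c(1, 1, 1, 1.1) * 500)
  expect_equal(d$band_density[4], 1500 / (1.1 * 500 / grand))
  expect_equal(d$loading_factor[4], 1.1 * 500 / grand)
  bad <- mk(rep(1, 4))
  bad@lanes$load2[1] <- 0
  expect_error(normalizeLoading(bad), "loading density")
})

test_that("large loading corrections are flagged", {
  g <- genBlot(loadingCv = 0.05, cfg = genConfig(1))
  n <- normalizeLoading(g$table)
  expect_false(any(laneData(n)$loading_flagged))
  # corrections on default synthetic blots stay below 10%
  expect_true(all(abs(laneData(n)$loading_factor - 1) < 0.1))
})

test_that("calibration fit is exact on exact standards", {
  tab <- DensitometryTable(data.frame(
    lane = paste0("S", 1:5), role = "standard",
    band_density = 100 + 250 * c(2, 3.5, 5, 6.5, 8),
    load1 = 500, load2 = 500, load3 = 500,
    known_conc = c(2, 3.5, 5, 6.5, 8)))
  fit <- fitCalibration(tab)
  expect_equal(unname(coef(fit)["slope"]), 250)
  expect_equal(unname(coef(fit)["intercept"]), 100)
  expect_equal(rSquared(fit), 1)
  dup <- DensitometryTable(data.frame(
    lane = paste0("S", 1:3), role = "standard",
    band_density = c(10, 11, 12), load1 = 1, load2 = 1, load3 = 1,
    known_conc = c(2, 3.5, 5)))
  dup@lanes$known_conc <- c(4, 4, 4)
  expect_error(fitCalibration(dup), "distinct standard")
})

test_that("interpolation inverts the calibration with flags", {
  fit <- new("CalibrationFit", slope = 200, intercept = 100,
             rSquared = 1, range = c(2, 8))
  expect_equal(as.numeric(interpolateConcentration(fit, 100 + 200 * 5)), 5)
  expect_equal(as.numeric(interpolateConcentration(fit, 100)), 0)
  lo <- interpolateConcentration(fit, 50)
  expect_true(attr(lo, "clipped"))
  expect_true(attr(lo, "extrapolated"))
  mid <- interpolateConcentration(fit, 100 + 200 * c(3, 7))
  expect_equal(as.numeric(mid), c(3, 7))
  expect_false(any(attr(mid, "extrapolated")))
})

test_that("per-cell amount follows the lane bookkeeping", {
  expect_equal(perCellAmount(4, 0.025, 1.875e5), 4 * 0.025 * 1e6 / 1.875e5)
  expect_equal(round(perCellAmount(4, 0.025, 1.875e5), 3), 0.533)
  expect_equal(perCellAmount(4, 0.025, 2 * 1.875e5),
               perCellAmount(4, 0.025, 1.875e5) / 2)
  expect_equal(perCellAmount(0, 0.025, 1e5), 0)
  expect_error(perCellAmount(4, 0.025, 0), "positive")
})

test_that("cellular concentration converts mass to molarity via the sequence", {
  cc <- cellularConcentration(130e-6 * 2627)
  expect_equal(cc$ugPerMl, 130, tolerance = 1e-9)
  expect_equal(cc$uMRounded, 9)
  half <- cellularConcentration(130e-6 * 2627, cellVolumeUm3 = 2 * 2627)
  expect_equal(half$ugPerMl, 65, tolerance = 1e-9)
  expect_equal(half$uM, cc$uM / 2, tolerance = 1e-9)
  expect_equal(cellularConcentration(0)$uM, 0)
  expect_error(cellularConcentration(1, sequence = ""), "empty sequence")
})

test_that("molecular weight matches tabulated values and an independent oracle", {
  expect_equal(molecularWeight("G"), 75.07, tolerance = 1e-4)
  expect_equal(molecularWeight("GG"), 132.12, tolerance = 1e-3)
  expect_error(molecularWeight("GXZ"), "unknown residue")
  expect_equal(nchar(asynSequence()), 140)
  expect_lt(abs(molecularWeight(asynSequence()) - 14460), 1)
  skip_if_not_installed("seqinr")
  expect_equal(molecularWeight(asynSequence()),
               seqinr::pmw(strsplit(asynSequence(), "")[[1]]),
               tolerance = 1e-4)
})

test_that("extinction coefficients follow aromatic composition", {
  expect_equal(extinctionCoefficient(asynSequence()), 5960)
  expect_equal(extinctionCoefficient("WWW"), 3 * 5500)
  expect_warning(eps <- extinctionCoefficient("GAV"), "impossible")
  expect_equal(eps, 0)
})

test_that("mass and molar units round-trip to machine precision", {
  mw <- molecularWeight(asynSequence())
  ug <- 217.3
  um <- ug * 1000 / mw
  expect_equal(um * mw / 1000, ug, tolerance = 1e-12)
})

test_that("the full blot chain recovers generator concentrations", {
  g <- genBlot(unknownConcs = c(3, 6), cfg = genConfig(2))
  out <- blotConcentrationChain(g$table)
  expect_equal(out$lysate_conc_ug_ml, c(3, 6), tolerance = 1e-9)
  expect_equal(out$pg_per_cell,
               perCellAmount(c(3, 6), 0.025, 7.5e6 * 0.025),
               tolerance = 1e-9)
  # loading variation is corrected by the nonspecific bands
  gl <- genBlot(unknownConcs = c(3, 6), loadingCv = 0.05,
                cfg = genConfig(3, noiseSd = 20))
  outl <- blotConcentrationChain(gl$table)
  expect_true(all(abs(outl$lysate_conc_ug_ml - c(3, 6)) / c(3, 6) < 0.1))
})
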