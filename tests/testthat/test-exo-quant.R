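make_step_trace <- function(basal = 100, stim = 200, nh4cl = 300,
                            tStim = 60, tNH4Cl = 420, duration = 600) {
  tt <- seq(0, duration, by = 2)
  vv <- ifelse(tt < tStim, basal, ifelse(tt < tNH4Cl, stim, nh4cl))
  TimeSeriesTrace(tt, vv, tStim = tStim, tNH4Cl = tNH4Cl)
}

test_that("trace validity catches malformed inputs", {
  expect_error(TimeSeriesTrace(c(0, 2, 1), c(1, 2, 3)),
               "strictly increasing")
  expect_error(TimeSeriesTrace(0:2, c(1, NA, 3)), "finite")
  expect_error(TimeSeriesTrace(0:10, rep(1, 11), tStim = 50, tNH4Cl = 20),
               "tStim must precede")
})

test_that("normalization maps basal to 0, NH4Cl plateau to 1, midpoint to 0.5", {
  tr <- make_step_trace(basal = 100, stim = 200, nh4cl = 300)
  nt <- normalizeTrace(tr)
  vv <- values(nt)
  tt <- times(nt)
  expect_equal(unique(vv[tt < 60]), 0)
  expect_equal(unique(vv[tt >= 440]), 1)
  expect_equal(unique(vv[tt >= 60 & tt < 420]), 0.5)
})

test_that("normalization is idempotent and errors on flat traces", {
  tr <- make_step_trace()
  nt <- normalizeTrace(tr)
  nt2 <- normalizeTrace(nt)
  expect_equal(values(nt2), values(nt))
  flat <- TimeSeriesTrace(seq(0, 600, 2), rep(5, 301), tStim = 60,
                          tNH4Cl = 420)
  expect_error(normalizeTrace(flat), "degenerate trace")
  expect_error(percentExocytosis(flat), "degenerate trace")
})

test_that("percent exocytosis reproduces plateau ratios and flags extremes", {
  expect_equal(pctExocytosis(percentExocytosis(make_step_trace(100, 300, 300))),
               100)
  expect_equal(pctExocytosis(percentExocytosis(make_step_trace(100, 100, 300))),
               0)
  r <- percentExocytosis(make_step_trace(100, 90, 300))
  expect_equal(pctExocytosis(r), 0)
  expect_true("clipped_negative" %in% flags(r))
  r2 <- percentExocytosis(make_step_trace(100, 320, 300))
  expect_gt(pctExocytosis(r2), 100)
  expect_true("over_100" %in% flags(r2))
})

test_that("percent exocytosis closes the loop on generated traces", {
  for (f in c(0.25, 0.7)) {
    g <- genExoTrace(stimRiseFraction = f, cfg = genConfig(1, noiseSd = 0))
    expect_equal(pctExocytosis(percentExocytosis(g$trace)), 100 * f)
  }
})

test_that("percent exocytosis is invariant to positive affine rescaling", {
  g <- genExoTrace(stimRiseFraction = 0.4, cfg = genConfig(3, noiseSd = 2))
  tr <- g$trace
  scaled <- TimeSeriesTrace(times(tr), 3.7 * values(tr) + 55,
                            tStim = stimTime(tr), tNH4Cl = nh4clTime(tr))
  expect_equal(pctExocytosis(percentExocytosis(scaled)),
               pctExocytosis(percentExocytosis(tr)), tolerance = 1e-10)
})

test_that("percent exocytosis increases strictly with the stimulated rise", {
  pct <- vapply(c(0.1, 0.3, 0.5, 0.8), function(f)
    pctExocytosis(percentExocytosis(
      genExoTrace(stimRiseFraction = f, cfg = genConfig(1))$trace)),
    numeric(1))
  expect_true(all(diff(pct) > 0))
})

test_that("reacidification lowers measured exocytosis only when present", {
  base <- genExoTrace(stimRiseFraction = 0.6, cfg = genConfig(1))
  rea <- genExoTrace(stimRiseFraction = 0.6, reacidRate = 0.005,
                     tBaf = NA, cfg = genConfig(1))
  none <- genExoTrace(stimRiseFraction = 0.6, reacidRate = 0,
                      cfg = genConfig(1))
  expect_equal(pctExocytosis(percentExocytosis(none$trace)),
               pctExocytosis(percentExocytosis(base$trace)))
  expect_lt(pctExocytosis(percentExocytosis(rea$trace)),
            pctExocytosis(percentExocytosis(base$trace)))
})

test_that("spontaneous release reads pre-stimulus drift against the dynamic range", {
  tt <- seq(0, 600, 2)
  basal <- 100
  nh4cl <- 300
  drift <- ifelse(tt < 20, basal,
                  ifelse(tt < 120, basal + 0.02 * (nh4cl - basal),
                         ifelse(tt < 420, 200, nh4cl)))
  tr <- TimeSeriesTrace(tt, drift, tStim = 120, tNH4Cl = 420)
  expect_equal(spontaneousRelease(tr, preStimWindow = c(0, 120)), 2,
               tolerance = 1e-10)
  flat <- make_step_trace(tStim = 120)
  expect_equal(spontaneousRelease(flat, preStimWindow = c(0, 120)), 0)
  expect_error(spontaneousRelease(flat, preStimWindow = c(0, 40)),
               "at least 60 s")
})

test_that("window preconditions are enforced", {
  tr <- make_step_trace()
  expect_error(percentExocytosis(tr, basalWindow = c(0, 2)), "samples")
})
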