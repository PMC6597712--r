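test_that("generators are bit-identical under a fixed seed and leave the global RNG alone", {
  cfg <- genConfig(seed = 11, noiseSd = 2)
  a <- genExoTrace(stimRiseFraction = 0.3, cfg = cfg)
  b <- genExoTrace(stimRiseFraction = 0.3, cfg = cfg)
  expect_identical(values(a$trace), values(b$trace))
  expect_identical(genTirfMovie(nEvents = 4, cfg = cfg)$truth,
                   genTirfMovie(nEvents = 4, cfg = cfg)$truth)
  expect_identical(laneData(genBlot(loadingCv = 0.1, cfg = cfg)$table),
                   laneData(genBlot(loadingCv = 0.1, cfg = cfg)$table))
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(genExoTrace(cfg = cfg))
  expect_identical(runif(1), x1)
})

test_that("zero noise reproduces the noiseless model exactly", {
  g <- genExoTrace(stimRiseFraction = 0, cfg = genConfig(1, noiseSd = 0))
  v <- values(g$trace)
  tt <- times(g$trace)
  expect_true(all(v[tt < 420] == 100))
  expect_true(all(v[tt >= 420] == 300))
  g1 <- genExoTrace(stimRiseFraction = 1, cfg = genConfig(1, noiseSd = 0))
  v1 <- values(g1$trace)
  expect_equal(unique(v1[times(g1$trace) >= 200]), 300)
  q <- genQuenchCurve(quenchFraction = 0, cfg = genConfig(1))
  expect_true(all(values(q$trace) == 1))
  q5 <- genQuenchCurve(quenchFraction = 0.5, rate = 0.01, duration = 2000,
                       cfg = genConfig(1))
  expect_equal(tail(values(q5$trace), 1), 0.5, tolerance = 1e-6)
})

test_that("exo-trace generator rejects inconsistent epoch annotations", {
  expect_error(genExoTrace(tStim = 500, tNH4Cl = 420), "invalid annotation")
  expect_error(genExoTrace(tNH4Cl = 700, duration = 600), "invalid annotation")
  expect_error(genExoTrace(basalLevel = 400, nh4clLevel = 300), "basalLevel")
  expect_error(genExoTrace(stimRiseFraction = 1.5), "stimRiseFraction")
})

test_that("TIRF generator refuses placements it cannot separate", {
  expect_error(genTirfMovie(nEvents = 200, imageShape = c(32, 32),
                            cfg = genConfig(1)),
               "placement error")
})

test_that("empty TIRF movie is constant background", {
  g <- genTirfMovie(nEvents = 0, background = 7, cfg = genConfig(1))
  expect_true(all(frames(g$movie) == 7))
  expect_equal(nrow(g$truth$events), 0)
})

test_that("cell-image generator hits its target shell fraction and validates inputs", {
  for (f in c(0, 0.4, 1)) {
    g <- genCellImage(trueShellFraction = f, cfg = genConfig(2))
    expect_lt(abs(g$truth$achievedShellFraction - f), 0.02)
  }
  expect_error(genCellImage(shellWidthNm = 40, pixelSizeNm = 100),
               "below one pixel")
  expect_error(genCellImage(trueShellFraction = 1.2), "trueShellFraction")
})

test_that("coloc generator ground-truth MOC matches its overlap mode", {
  idt <- genColocPair("identical", cfg = genConfig(3))
  expect_equal(idt$truth$moc, 1, tolerance = 1e-12)
  dis <- genColocPair("disjoint", cfg = genConfig(3))
  expect_lt(dis$truth$moc, 1e-12)
  par <- genColocPair("partial", nPuncta = 10, nShared = 7,
                      cfg = genConfig(3))
  expect_gt(par$truth$moc, 0.5)
  expect_lt(par$truth$moc, 1)
  expect_error(genColocPair("partial", nPuncta = 5, nShared = 7),
               "nShared")
})

test_that("shift-table generator leaves prolines without amide entries", {
  g <- genShiftTables(cfg = genConfig(4))
  d <- residueData(g$wt)
  expect_true(all(is.na(d$H[d$aa == "P"])))
  expect_true(all(is.na(d$N[d$aa == "P"])))
  expect_false(anyNA(d$CA))
})

test_that("binding-profile generator produces a flat profile when fractions agree", {
  g <- genBindingProfile(boundFreeFraction = 0.6, unboundFreeFraction = 0.6,
                         cfg = genConfig(5))
  p <- intensityRatioProfile(g$lipid, g$free)
  expect_equal(unique(round(as.data.frame(p)$value, 10)), 0.6)
})

test_that("estimator error grows monotonically with generator noise", {
  mae <- vapply(c(1, 4, 16), function(ns) {
    errs <- vapply(1:20, function(s) {
      g <- genExoTrace(stimRiseFraction = 0.5,
                       cfg = genConfig(s, noiseSd = ns))
      abs(pctExocytosis(percentExocytosis(g$trace)) - 50)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mae) > 0))
})
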