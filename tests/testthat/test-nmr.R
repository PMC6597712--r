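mini_table <- function(residue, aa, ...) {
  ResidueTable(data.frame(residue = residue, aa = aa, ...))
}

test_that("amide CSD is zero against itself and matches hand arithmetic", {
  g <- genShiftTables(cfg = genConfig(1))
  self <- amideCSD(g$wt, g$wt)
  expect_true(all(as.data.frame(self)$value == 0))
  # dHN = 0.1, dN = 0.5 -> sqrt(0.5 * (0.01 + 0.25 / 25)) = 0.1
  wt <- mini_table(1:3, c("A", "K", "V"), H = c(8, 8, 8),
                   N = c(120, 120, 120))
  mut <- mini_table(1:3, c("A", "K", "V"), H = c(8.1, 8, 8),
                    N = c(120.5, 120, 120))
  p <- as.data.frame(amideCSD(mut, wt))
  expect_equal(p$value[1], 0.1, tolerance = 1e-12)
  expect_equal(p$value[2:3], c(0, 0))
})

test_that("amide CSD is symmetric in which table is called mutant", {
  g <- genShiftTables(perturbMagnitude = 0.2,
                      cfg = genConfig(2, noiseSd = 0.01))
  a <- as.data.frame(amideCSD(g$mut, g$wt))
  b <- as.data.frame(amideCSD(g$wt, g$mut))
  expect_equal(a, b)
})

test_that("CSD profile peaks at the injected perturbation site", {
  for (site in c(30, 70)) {
    g <- genShiftTables(perturbSite = site, cfg = genConfig(3))
    p <- as.data.frame(amideCSD(g$mut, g$wt))
    expect_equal(p$residue[which.max(p$value)], site)
  }
})

test_that("CSD respects the residue range and missing amides", {
  g <- genShiftTables(cfg = genConfig(4))
  p <- as.data.frame(amideCSD(g$mut, g$wt, residueRange = c(1, 102)))
  expect_true(all(p$residue <= 102))
  pro <- which(strsplit(residueSequence(g$wt), "")[[1]] == "P")
  expect_false(any(p$residue %in% pro))
  expect_error(amideCSD(mini_table(1, "A", H = 8, N = 120),
                        mini_table(2, "A", H = 8, N = 120)),
               "no common residues")
})

test_that("secondary shifts recover a constructed helical bump", {
  rc <- randomCoilTable()
  aa <- c("A", "E", "K", "V", "G")
  coil <- rc$CA[match(aa, rc$aa)]
  bump <- c(0, 3, 3, 3, 0)
  tab <- mini_table(1:5, aa, CA = coil + bump)
  p <- as.data.frame(secondaryShift(tab, rc, nucleus = "CA"))
  expect_equal(p$value, bump, tolerance = 1e-12)
  # glycine has no CB random-coil value and is dropped from CB profiles
  tab2 <- mini_table(1:2, c("A", "G"), CB = c(20, 30))
  p2 <- as.data.frame(secondaryShift(tab2, rc, nucleus = "CB"))
  expect_equal(p2$residue, 1L)
  expect_error(secondaryShift(mini_table(1, "X", CA = 50), rc),
               "absent from the random-coil table")
})

test_that("carbon re-referencing recovers injected offsets and is idempotent", {
  for (off in c(-0.3, -0.1, 0.1, 0.3)) {
    g <- genShiftTables(carbonOffset = off, cfg = genConfig(5))
    rr <- rereferenceCarbon(g$mut, g$wt)
    expect_equal(rr$offset, -off, tolerance = 1e-9)
    again <- rereferenceCarbon(rr$corrected, g$wt)
    expect_lt(abs(again$offset), 1e-9)
    # amide columns are untouched by the carbon correction
    expect_identical(residueData(rr$corrected)$H, residueData(g$mut)$H)
  }
  g0 <- genShiftTables(carbonOffset = 0, cfg = genConfig(5))
  expect_equal(rereferenceCarbon(g0$mut, g0$wt)$offset, 0, tolerance = 1e-12)
})

test_that("re-referencing requires enough carbon-bearing residues", {
  small <- mini_table(111:113, c("A", "K", "V"), CA = c(52, 56, 62),
                      CB = c(19, 32, 31))
  expect_error(rereferenceCarbon(small, small), "insufficient overlap")
})

test_that("intensity ratios are exact for trivial constructions", {
  g <- genBindingProfile(cfg = genConfig(6))
  self <- intensityRatioProfile(g$free, g$free)
  expect_true(all(as.data.frame(self)$value == 1))
  zero <- ResidueTable(transform(residueData(g$free), intensity = 0))
  p0 <- intensityRatioProfile(zero, g$free)
  expect_true(all(as.data.frame(p0)$value == 0))
  # residues with free intensity at the floor are excluded and listed
  d <- residueData(g$free)
  d$intensity[5] <- 0
  p <- intensityRatioProfile(g$lipid, ResidueTable(d), floor = 0)
  expect_true(5 %in% p@excluded)
  all_zero <- ResidueTable(transform(d, intensity = 0))
  expect_error(intensityRatioProfile(g$lipid, all_zero), "all residues")
})

test_that("the fitted release boundary recovers the injected residue across seeds", {
  mids <- vapply(1:20, function(s) {
    g <- genBindingProfile(boundaryResidue = 70,
                           cfg = genConfig(s, noiseSd = 0.05))
    fitBindingBoundary(intensityRatioProfile(g$lipid, g$free))$midpoint
  }, numeric(1))
  expect_true(all(abs(mids - 70) <= 1))
})

test_that("region summaries average constructed step profiles correctly", {
  prof <- new("ResidueProfile", residue = 1:40,
              value = c(rep(2, 20), rep(6, 20)), quantity = "test")
  rs <- regionSummary(prof, regions = list(lo = c(1, 20), hi = c(21, 40)))
  expect_equal(rs$mean, c(2, 6))
  expect_equal(rs$sd, c(0, 0))
  all_r <- regionSummary(prof, regions = list(all = c(1, 40)))
  expect_equal(all_r$mean, 4)
  expect_error(regionSummary(prof, regions = list(bad = c(50, 60))),
               "empty region")
})
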