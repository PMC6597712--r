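test_that("membrane shell matches the pixel-counting geometric oracle", {
  mask <- disk_mask(64, 20)
  shell <- membraneShell(mask, shellWidthNm = 800, pixelSizeNm = 100)
  d <- nrow(mask)
  # oracle: pixels of the mask whose distance to the nearest background
  # pixel is at most 8 px, by direct enumeration
  bg <- which(!mask, arr.ind = TRUE)
  oracle <- mask
  for (i in which(mask)) {
    rc <- c((i - 1) %% d + 1, (i - 1) %/% d + 1)
    mind <- min(sqrt((bg[, 1] - rc[1])^2 + (bg[, 2] - rc[2])^2))
    oracle[i] <- mind <= 8
  }
  expect_identical(unname(shell), unname(oracle & mask))
  expect_error(membraneShell(mask, shellWidthNm = 50, pixelSizeNm = 100),
               "below one pixel")
})

test_that("a cell thinner than the shell degrades to the whole mask with a warning", {
  mask <- disk_mask(32, 5)
  expect_warning(shell <- membraneShell(mask, 800, 100), "thinner")
  expect_identical(unname(shell > 0), unname(mask))
})

test_that("uniform intensity gives shell fraction equal to the area ratio", {
  mask <- disk_mask(64, 22)
  img <- MaskedImagePair(channelR = matrix(0, 64, 64),
                         channelG = matrix(1, 64, 64) * mask,
                         cellMask = mask, pixelSize = 100)
  res <- membraneProximalFraction(img)
  shell <- membraneShell(mask, 800, 100)
  expect_identical(shellFraction(res), sum(shell) / sum(mask))
})

test_that("shell fraction recovers the generator's ground truth", {
  for (f in c(0.25, 0.40)) {
    g <- genCellImage(trueShellFraction = f, cfg = genConfig(7))
    est <- shellFraction(membraneProximalFraction(g$image))
    expect_lt(abs(est - f), 0.03)
  }
})

test_that("shell fraction is monotone in shell width and errors on empty intensity", {
  g <- genCellImage(trueShellFraction = 0.4, cfg = genConfig(8))
  # the widest shell exceeds the cell radius and swallows the whole mask
  widths <- c(400, 800, 1600, 8000)
  fr <- vapply(widths, function(w)
    shellFraction(suppressWarnings(
      membraneProximalFraction(g$image, shellWidthNm = w))),
    numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(tail(fr, 1), 1)
  dark <- MaskedImagePair(matrix(0, 64, 64), matrix(0, 64, 64),
                          disk_mask(64, 20))
  expect_error(membraneProximalFraction(dark), "zero total intensity")
})

test_that("released fraction is a plain shell-intensity ratio", {
  mask <- disk_mask(48, 16)
  mk <- function(scale) MaskedImagePair(matrix(0, 48, 48),
                                        matrix(scale, 48, 48) * mask,
                                        mask)
  expect_equal(as.numeric(releasedFraction(mk(1), mk(1))), 1)
  expect_equal(as.numeric(releasedFraction(mk(1), mk(2))), 0.5)
  # common rescaling of both images cancels
  expect_equal(as.numeric(releasedFraction(mk(3), mk(6))), 0.5)
  over <- releasedFraction(mk(2), mk(1))
  expect_true("over_1" %in% attr(over, "flags"))
})

test_that("Manders overlap matches hand-evaluated fixtures", {
  img <- MaskedImagePair(channelR = matrix(c(1, 2), 1, 2),
                         channelG = matrix(c(2, 1), 1, 2))
  expect_equal(mandersOverlap(img), 0.8, tolerance = 1e-15)
  same <- MaskedImagePair(matrix(1:9, 3, 3) * 1.0, matrix(1:9, 3, 3) * 1.0)
  expect_equal(mandersOverlap(same), 1, tolerance = 1e-15)
  disj <- MaskedImagePair(channelR = matrix(c(1, 0), 1, 2),
                          channelG = matrix(c(0, 1), 1, 2))
  expect_equal(mandersOverlap(disj), 0)
  zero <- MaskedImagePair(matrix(0, 2, 2), matrix(1, 2, 2))
  expect_error(mandersOverlap(zero), "all zero")
})

test_that("Manders overlap is symmetric, scale invariant and bounded", {
  set.seed(123)
  for (i in 1:20) {
    R <- matrix(runif(64), 8, 8)
    G <- matrix(runif(64), 8, 8)
    a <- MaskedImagePair(R, G)
    b <- MaskedImagePair(G, R)
    s <- MaskedImagePair(5 * R, 0.2 * G)
    m <- mandersOverlap(a)
    expect_equal(mandersOverlap(b), m, tolerance = 1e-12)
    expect_equal(mandersOverlap(s), m, tolerance = 1e-12)
    expect_gte(m, 0)
    expect_lte(m, 1)
  }
})

test_that("MOC estimate agrees with the generator's direct evaluation", {
  p <- genColocPair("partial", cfg = genConfig(9))
  expect_equal(mandersOverlap(p$image), p$truth$moc, tolerance = 1e-12)
})

test_that("line profiles interpolate bilinearly with nm distances", {
  const <- MaskedImagePair(matrix(3, 16, 16), matrix(5, 16, 16),
                           pixelSize = 50)
  pr <- lineProfile(const, c(2, 2), c(2, 12))
  expect_true(all(pr$R == 3))
  expect_true(all(pr$G == 5))
  expect_equal(max(pr$distance_nm), 10 * 50)
  grad <- MaskedImagePair(matrix(rep(0:15, each = 16), 16, 16),
                          matrix(0, 16, 16) + 1, pixelSize = 100)
  pg <- lineProfile(grad, c(8, 0), c(8, 15))
  expect_equal(pg$R, seq(0, 15, length.out = nrow(pg)), tolerance = 1e-10)
  expect_error(lineProfile(const, c(2, 2), c(2, 2)), "zero-length")
  expect_error(lineProfile(const, c(-1, 2), c(2, 12)), "inside the image")
})

test_that("colocalized puncta counting matches the generator's shared puncta", {
  p <- genColocPair("partial", nPuncta = 10, nShared = 7,
                    cfg = genConfig(10))
  cnt <- countColocalizedPuncta(p$image, detectChannel = "R")
  expect_equal(as.integer(cnt), 7)
  expect_equal(attr(cnt, "nDetected"), 10)
  # zero label channel co-labels nothing
  dark <- MaskedImagePair(channelR = channelR(p$image),
                          channelG = matrix(0, 96, 96))
  expect_equal(as.integer(countColocalizedPuncta(dark, "R")), 0)
  empty <- MaskedImagePair(matrix(0, 32, 32), matrix(0, 32, 32))
  expect_equal(as.integer(countColocalizedPuncta(empty, "R")), 0)
})
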