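# position sampler with a minimum pairwise separation (rejection sampling)
sample_positions <- function(n, row_range, col_range, min_sep,
                             existing = NULL, max_tries = 20000L) {
  pos <- if (is.null(existing)) matrix(numeric(0), 0, 2) else existing
  n_existing <- nrow(pos)
  tries <- 0L
  while (nrow(pos) < n + n_existing) {
    if ((tries <- tries + 1L) > max_tries)
      stop("placement error: cannot place ", n,
           " puncta at the requested separation")
    cand <- c(stats::runif(1, row_range[1], row_range[2]),
              stats::runif(1, col_range[1], col_range[2]))
    if (nrow(pos) == 0 ||
        all(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2) >= min_sep))
      pos <- rbind(pos, cand)
  }
  unname(pos[seq_len(nrow(pos)) > n_existing, , drop = FALSE])
}

#' Generate a TIRF movie with injected exocytic flash events
#'
#' Each event appears at its onset frame as a symmetric 2-D Gaussian flash
#' of peak pixel amplitude \code{flashAmplitude} and decays exponentially
#' over \code{flashDecayFrames}. Events are placed at least
#' \code{2 * flashSigmaPx} from the borders and pairwise separated in space
#' beyond the detector resolution, so the zero-noise fixture is
#' unambiguous; if that separation cannot be honoured a placement error is
#' raised rather than silently overlapping events.
#'
#' @param nEvents number of events to inject.
#' @param flashAmplitude peak pixel intensity of a flash at onset (a.u.).
#' @param flashSigmaPx flash Gaussian sigma (px).
#' @param flashDecayFrames exponential decay constant (frames).
#' @param nFrames,imageShape movie size; \code{imageShape} is (rows, cols).
#' @param frameInterval s per frame.
#' @param pixelSizeNm nm per pixel.
#' @param background constant background level (a.u.).
#' @param poissonNoise if TRUE, apply Poisson shot noise to the intensity
#'   (in addition to the additive Gaussian noise from \code{cfg}).
#' @param cfg a \code{\link{genConfig}}; \code{noiseSd} is in a.u.
#' @return list(movie = \linkS4class{TirfMovie}, truth = list(events =
#'   data.frame(frame, t, row, col) with 0-based pixel coordinates)).
#' @examples
#' g <- genTirfMovie(nEvents = 3, cfg = genConfig(seed = 7))
#' nrow(g$truth$events)
#' @export
genTirfMovie <- function(nEvents = 12, flashAmplitude = 10,
                         flashSigmaPx = 1.5, flashDecayFrames = 4,
                         nFrames = 60, imageShape = c(64, 64),
                         frameInterval = 1, pixelSizeNm = 100,
                         background = 10, poissonNoise = FALSE,
                         cfg = genConfig()) {
  # spatial margin keeps flashes clear of the detector's border
  # exclusion; the temporal margin leaves room for the rolling-median
  # background to be estimated before the first onset
  margin <- max(4 * flashSigmaPx, 5)
  sep <- max(6 * flashSigmaPx, 8)
  frame_min <- 9L
  frame_max <- nFrames - 2L * flashDecayFrames
  if (frame_max < frame_min && nEvents > 0)
    stop("movie too short for the requested flash decay")
  with_seed(cfg$seed, {
    arr <- array(background, c(nFrames, imageShape[1], imageShape[2]))
    truth <- data.frame(frame = integer(), t = numeric(),
                        row = numeric(), col = numeric())
    if (nEvents > 0) {
      pos <- sample_positions(nEvents,
                              c(margin, imageShape[1] - 1 - margin),
                              c(margin, imageShape[2] - 1 - margin), sep)
      onset <- sample(frame_min:frame_max, nEvents, replace = TRUE)
      mass <- flashAmplitude / punctum_peak_fraction(flashSigmaPx)
      for (i in seq_len(nEvents)) {
        spot <- render_punctum(imageShape[1], imageShape[2],
                               pos[i, 1], pos[i, 2], flashSigmaPx, mass)
        for (f in onset[i]:nFrames) {
          arr[f, , ] <- arr[f, , ] +
            spot * exp(-(f - onset[i]) / flashDecayFrames)
        }
      }
      truth <- data.frame(frame = onset, t = (onset - 1) * frameInterval,
                          row = pos[, 1], col = pos[, 2])
      truth <- truth[order(truth$frame), ]
      rownames(truth) <- NULL
    }
    if (poissonNoise)
      arr[] <- stats::rpois(length(arr), pmax(arr, 0))
    if (cfg$noiseSd > 0)
      arr <- arr + stats::rnorm(length(arr), 0, cfg$noiseSd)
    list(movie = TirfMovie(arr, frameInterval, pixelSizeNm),
         truth = list(events = truth))
  })
}

# elliptical cell mask centered in the image (0-based center coordinates)
ellipse_mask <- function(shape, semi_row, semi_col) {
  r0 <- (shape[1] - 1) / 2
  c0 <- (shape[2] - 1) / 2
  rr <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  ((rr - r0) / semi_row)^2 + ((cc - c0) / semi_col)^2 <= 1
}

#' Generate a cell image with a known membrane-proximal vesicle fraction
#'
#' Places Gaussian vesicle puncta inside an elliptical cell mask such that
#' the fraction of total fluorescence falling in the outer membrane shell
#' equals \code{trueShellFraction}. Puncta are rendered by analytic
#' integration of the Gaussian over pixels, and centers keep a 2.5-sigma
#' margin from the shell boundaries so the achieved (noiseless) shell
#' fraction matches the target up to small tail leakage; the achieved
#' value is recorded in the ground truth.
#'
#' @param trueShellFraction target fraction in [0, 1] of vesicle intensity
#'   in the membrane-proximal shell.
#' @param nVesicles number of puncta.
#' @param shellWidthNm shell width (nm); must be at least one pixel.
#' @param imageShape image size (rows, cols).
#' @param pixelSizeNm nm per pixel (default 100, making an 800 nm shell
#'   8 px wide).
#' @param vesicleSigmaPx punctum Gaussian sigma (px).
#' @param cfg a \code{\link{genConfig}}; \code{noiseSd} is in units of one
#'   punctum's integrated intensity.
#' @return list(image = \linkS4class{MaskedImagePair} with vesicles in the
#'   G channel, truth = list(trueShellFraction, achievedShellFraction)).
#' @export
genCellImage <- function(trueShellFraction = 0.4, nVesicles = 20,
                         shellWidthNm = 800, imageShape = c(128, 128),
                         pixelSizeNm = 100, vesicleSigmaPx = 1.2,
                         cfg = genConfig()) {
  if (trueShellFraction < 0 || trueShellFraction > 1)
    stop("trueShellFraction must lie in [0, 1]")
  shell_px <- round(shellWidthNm / pixelSizeNm)
  if (shell_px < 1) stop("shell width is below one pixel")
  mask <- ellipse_mask(imageShape, 0.40 * imageShape[1], 0.45 * imageShape[2])
  d <- mask_distance(mask)
  margin <- 2.5 * vesicleSigmaPx
  shell_ok <- mask & d >= margin & d <= shell_px - margin + 1
  interior_ok <- mask & d >= shell_px + margin
  if (!any(shell_ok) || !any(interior_ok))
    stop("mask geometry leaves no room for punctum placement")
  f <- trueShellFraction
  ns <- if (f == 0) 0L else if (f == 1) nVesicles else
    max(1L, min(nVesicles - 1L, round(f * nVesicles)))
  ni <- nVesicles - ns
  amp_i <- 1
  amp_s <- if (ns == 0) 0 else if (ni == 0) 1 else (f / (1 - f)) * (ni / ns)
  with_seed(cfg$seed, {
    pick <- function(region, k) {
      idx <- which(region, arr.ind = TRUE)
      sel <- idx[sample(nrow(idx), k, replace = FALSE), , drop = FALSE]
      # subpixel jitter around the chosen pixel centers
      cbind(sel[, 1] - 1 + stats::runif(k, -0.4, 0.4),
            sel[, 2] - 1 + stats::runif(k, -0.4, 0.4))
    }
    img <- matrix(0, imageShape[1], imageShape[2])
    if (ns > 0) for (p in seq_len(ns)) {
      pos <- pick(shell_ok, 1)
      img <- img + render_punctum(imageShape[1], imageShape[2],
                                  pos[1], pos[2], vesicleSigmaPx, amp_s)
    }
    if (ni > 0) for (p in seq_len(ni)) {
      pos <- pick(interior_ok, 1)
      img <- img + render_punctum(imageShape[1], imageShape[2],
                                  pos[1], pos[2], vesicleSigmaPx, amp_i)
    }
    shell <- mask & d <= shell_px
    achieved <- if (sum(img[mask]) > 0) sum(img[shell]) / sum(img[mask]) else NA
    if (cfg$noiseSd > 0) {
      img <- img + stats::rnorm(length(img), 0, cfg$noiseSd)
      img[img < 0] <- 0
    }
    pair <- MaskedImagePair(channelR = matrix(0, imageShape[1], imageShape[2]),
                            channelG = img, cellMask = mask,
                            pixelSize = pixelSizeNm)
    list(image = pair,
         truth = list(trueShellFraction = f,
                      achievedShellFraction = achieved,
                      shellWidthNm = shellWidthNm))
  })
}

#' Generate a two-channel colocalization image pair
#'
#' Produces puncta in two channels with controlled overlap for validating
#' Manders overlap and colocalized-puncta counting. Modes: "identical"
#' (G = R, MOC 1), "disjoint" (spatially separated supports, MOC ~ 0) and
#' "partial" (\code{nShared} of \code{nPuncta} puncta present in both
#' channels). The ground-truth MOC is evaluated directly from the
#' noiseless images.
#'
#' @param overlapMode one of "identical", "disjoint", "partial".
#' @param nPuncta puncta per channel.
#' @param nShared for "partial": puncta shared by both channels.
#' @param imageShape image size (rows, cols).
#' @param sigmaPx punctum sigma (px).
#' @param amplitude integrated punctum intensity (a.u.).
#' @param pixelSizeNm nm per pixel.
#' @param cfg a \code{\link{genConfig}}; \code{noiseSd} in a.u.
#' @return list(image = \linkS4class{MaskedImagePair},
#'   truth = list(moc, nPuncta, nShared)).
#' @export
genColocPair <- function(overlapMode = c("partial", "identical", "disjoint"),
                         nPuncta = 10, nShared = 7, imageShape = c(96, 96),
                         sigmaPx = 1.5, amplitude = 100, pixelSizeNm = 100,
                         cfg = genConfig()) {
  overlapMode <- match.arg(overlapMode)
  if (overlapMode == "partial" && nShared > nPuncta)
    stop("nShared cannot exceed nPuncta")
  margin <- max(4 * sigmaPx, 6)
  sep <- 6 * sigmaPx
  render_all <- function(pos) {
    img <- matrix(0, imageShape[1], imageShape[2])
    for (i in seq_len(nrow(pos)))
      img <- img + render_punctum(imageShape[1], imageShape[2],
                                  pos[i, 1], pos[i, 2], sigmaPx, amplitude)
    img
  }
  with_seed(cfg$seed, {
    if (overlapMode == "disjoint") {
      mid <- (imageShape[2] - 1) / 2
      gap <- 6 * sigmaPx
      posR <- sample_positions(nPuncta, c(margin, imageShape[1] - 1 - margin),
                               c(margin, mid - gap), sep)
      posG <- sample_positions(nPuncta, c(margin, imageShape[1] - 1 - margin),
                               c(mid + gap, imageShape[2] - 1 - margin), sep)
    } else {
      posR <- sample_positions(nPuncta, c(margin, imageShape[1] - 1 - margin),
                               c(margin, imageShape[2] - 1 - margin), sep)
      posG <- if (overlapMode == "identical") posR else {
        shared <- posR[seq_len(nShared), , drop = FALSE]
        extra <- sample_positions(nPuncta - nShared,
                                  c(margin, imageShape[1] - 1 - margin),
                                  c(margin, imageShape[2] - 1 - margin), sep,
                                  existing = posR)
        rbind(shared, extra)
      }
    }
    R <- render_all(posR)
    G <- render_all(posG)
    moc_true <- sum(R * G) / sqrt(sum(R^2) * sum(G^2))
    if (cfg$noiseSd > 0) {
      R <- pmax(R + stats::rnorm(length(R), 0, cfg$noiseSd), 0)
      G <- pmax(G + stats::rnorm(length(G), 0, cfg$noiseSd), 0)
    }
    pair <- MaskedImagePair(channelR = R, channelG = G,
                            pixelSize = pixelSizeNm)
    list(image = pair,
         truth = list(moc = moc_true, nPuncta = nPuncta,
                      nShared = if (overlapMode == "partial") nShared
                                else if (overlapMode == "identical") nPuncta
                                else 0L,
                      positionsR = posR, positionsG = posG))
  })
}
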