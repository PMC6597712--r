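#' Membrane-proximal shell of a cell mask
#'
#' The shell is the mask minus its inward Euclidean erosion by
#' \code{round(shellWidthNm / pixelSizeNm)} pixels, computed with a
#' Euclidean distance transform so the shell is isotropic. If the cell is
#' thinner than the shell (erosion empties the mask) the whole mask is
#' returned with a warning flag.
#'
#' @param mask logical matrix, the cell mask.
#' @param shellWidthNm shell width in nm (~800 nm in the default
#'   membrane-proximal analysis).
#' @param pixelSizeNm nm per pixel.
#' @return logical matrix, the shell region, with attribute \code{"flag"}
#'   set to \code{"shell_is_mask"} in the degenerate case.
#' @export
membraneShell <- function(mask, shellWidthNm = 800, pixelSizeNm = 100) {
  px <- round(shellWidthNm / pixelSizeNm)
  if (px < 1) stop("shell width is below one pixel")
  d <- mask_distance(mask)
  interior <- mask & d > px
  if (!any(interior)) {
    warning("cell thinner than shell; shell equals the whole mask")
    shell <- mask
    attr(shell, "flag") <- "shell_is_mask"
    return(shell)
  }
  shell <- mask & !interior
  shell
}

#' Membrane-proximal fluorescence fraction
#'
#' Fraction of total cellular fluorescence in the membrane-proximal outer
#' shell: shell-summed intensity divided by mask-summed intensity. This is
#' the "% membrane-proximal recycling endosomes" statistic when applied to
#' a recycling-endosome marker channel.
#'
#' @param img a \linkS4class{MaskedImagePair} (background-subtracted).
#' @param channel which channel to quantify, "G" or "R".
#' @param shellWidthNm shell width in nm.
#' @return A \linkS4class{ShellResult}.
#' @examples
#' g <- genCellImage(trueShellFraction = 0.4)
#' shellFraction(membraneProximalFraction(g$image))
#' @export
membraneProximalFraction <- function(img, channel = c("G", "R"),
                                     shellWidthNm = 800) {
  channel <- match.arg(channel)
  ch <- if (channel == "G") channelG(img) else channelR(img)
  mask <- cellMask(img)
  shell <- membraneShell(mask, shellWidthNm, pixelSize(img))
  total <- sum(ch[mask])
  if (total <= 0) stop("undefined fraction: zero total intensity in mask")
  fl <- if (!is.null(attr(shell, "flag"))) attr(shell, "flag")
        else character()
  new("ShellResult", shellFraction = sum(ch[shell]) / total,
      shellWidth = shellWidthNm, shellPixelCount = sum(shell),
      maskPixelCount = sum(mask), flags = fl)
}

#' Released fraction of membrane-proximal vesicles
#'
#' Ratio of shell-summed fluorescence at the end of the stimulation period
#' to shell-summed fluorescence after subsequent NH4Cl addition (which
#' dequenches all membrane-proximal vesicles). Values are expected at or
#' below 1; larger values are flagged. Both images must share the same
#' mask (registered acquisitions of the same cell).
#'
#' @param imgPostStim,imgPostNH4Cl \linkS4class{MaskedImagePair} objects
#'   with identical masks.
#' @param channel channel to quantify.
#' @param shellWidthNm shell width in nm.
#' @return numeric(1) ratio, with attribute \code{"flags"}.
#' @export
releasedFraction <- function(imgPostStim, imgPostNH4Cl,
                             channel = c("G", "R"), shellWidthNm = 800) {
  channel <- match.arg(channel)
  if (!identical(cellMask(imgPostStim), cellMask(imgPostNH4Cl)))
    stop("images must share the same cell mask")
  shell <- membraneShell(cellMask(imgPostStim), shellWidthNm,
                         pixelSize(imgPostStim))
  pick <- function(img) if (channel == "G") channelG(img) else channelR(img)
  denom <- sum(pick(imgPostNH4Cl)[shell])
  if (denom <= 0) stop("undefined fraction: zero NH4Cl shell intensity")
  ratio <- sum(pick(imgPostStim)[shell]) / denom
  attr(ratio, "flags") <- if (ratio > 1) "over_1" else character()
  ratio
}

#' Manders overlap coefficient
#'
#' Intensity-weighted colocalization between the two channels:
#' \code{MOC = sum(R * G) / sqrt(sum(R^2) * sum(G^2))}, in [0, 1]. By
#' default evaluated inside the cell mask (excluding extracellular
#' background); set \code{restrictToMask = FALSE} for whole-field
#' evaluation.
#'
#' @param img a \linkS4class{MaskedImagePair}.
#' @param restrictToMask evaluate inside the cell mask only.
#' @return numeric(1) in [0, 1].
#' @examples
#' p <- genColocPair("identical")
#' mandersOverlap(p$image)  # 1
#' @export
mandersOverlap <- function(img, restrictToMask = TRUE) {
  if (restrictToMask) {
    sel <- cellMask(img)
    R <- channelR(img)[sel]
    G <- channelG(img)[sel]
  } else {
    R <- as.vector(channelR(img))
    G <- as.vector(channelG(img))
  }
  if (all(R == 0) || all(G == 0))
    stop("undefined MOC: a channel is all zero in the evaluation region")
  sum(R * G) / sqrt(sum(R^2) * sum(G^2))
}

#' Intensity profile along a line
#'
#' Bilinear samples of both channels along the segment from \code{p0} to
#' \code{p1} (0-based pixel (row, col) coordinates), averaged across the
#' perpendicular width, with the distance axis in nm.
#'
#' @param img a \linkS4class{MaskedImagePair}.
#' @param p0,p1 numeric(2), 0-based (row, col) endpoints inside the image.
#' @param widthPx integer, perpendicular averaging width in pixels.
#' @param samplesPerPx sampling density along the line.
#' @return data.frame with columns distance_nm, R, G.
#' @export
lineProfile <- function(img, p0, p1, widthPx = 1, samplesPerPx = 1) {
  d <- dim(channelR(img))
  for (p in list(p0, p1))
    if (p[1] < 0 || p[1] > d[1] - 1 || p[2] < 0 || p[2] > d[2] - 1)
      stop("line endpoints must lie inside the image")
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length line")
  n <- max(2L, ceiling(len * samplesPerPx) + 1L)
  tt <- seq(0, 1, length.out = n)
  rows <- p0[1] + tt * (p1[1] - p0[1])
  cols <- p0[2] + tt * (p1[2] - p0[2])
  # unit perpendicular for width averaging
  perp <- c(-(p1[2] - p0[2]), p1[1] - p0[1]) / len
  offs <- seq(-(widthPx - 1) / 2, (widthPx - 1) / 2, length.out = widthPx)
  sample_ch <- function(m) {
    rowMeans(vapply(offs, function(o)
      bilinear(m, rows + o * perp[1], cols + o * perp[2]),
      numeric(n)))
  }
  data.frame(distance_nm = tt * len * pixelSize(img),
             R = sample_ch(channelR(img)),
             G = sample_ch(channelG(img)))
}

#' Count colocalized puncta
#'
#' Detects puncta in one channel (smoothed strict local maxima above a
#' robust threshold, inside the cell mask) and counts those whose mean
#' intensity in the other (label) channel within one sigma of the punctum
#' center exceeds \code{overlapThreshold} times the label-channel
#' background (median inside the mask).
#'
#' @param img a \linkS4class{MaskedImagePair}.
#' @param detectChannel channel in which puncta are detected ("R" or "G").
#' @param punctaSigmaPx expected punctum sigma (px), used for smoothing
#'   and the label-averaging radius.
#' @param overlapThreshold multiple of the label background a punctum's
#'   label-channel mean must exceed to count as co-labeled.
#' @param thresholdSd detection threshold in robust SD units.
#' @return integer count of co-labeled puncta, with attribute
#'   \code{"nDetected"} (total puncta found in the detect channel).
#' @export
countColocalizedPuncta <- function(img, detectChannel = c("R", "G"),
                                   punctaSigmaPx = 1.5,
                                   overlapThreshold = 2, thresholdSd = 5) {
  detectChannel <- match.arg(detectChannel)
  det <- if (detectChannel == "R") channelR(img) else channelG(img)
  lab <- if (detectChannel == "R") channelG(img) else channelR(img)
  mask <- cellMask(img)
  sm <- smooth_gaussian(det, punctaSigmaPx)
  # relative floor keeps FFT ripple below threshold on noise-free images
  thr <- max(thresholdSd * stats::mad(sm[mask],
                                      center = stats::median(sm[mask])),
             1e-6 * max(abs(sm)))
  peaks <- local_maxima_2d(sm) & mask & sm > thr & sm > 0
  idx <- which(peaks, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    out <- 0L
    attr(out, "nDetected") <- 0L
    return(out)
  }
  bglab <- stats::median(lab[mask])
  # floor guards the zero-background case against numerical Gaussian tails
  lab_thr <- max(overlapThreshold * bglab, 1e-6 * max(lab))
  rr <- matrix(seq_len(nrow(det)), nrow(det), ncol(det))
  cc <- matrix(seq_len(ncol(det)), nrow(det), ncol(det), byrow = TRUE)
  colabeled <- 0L
  for (i in seq_len(nrow(idx))) {
    within <- (rr - idx[i, 1])^2 + (cc - idx[i, 2])^2 <=
      max(punctaSigmaPx, 1)^2
    if (mean(lab[within]) > lab_thr)
      colabeled <- colabeled + 1L
  }
  out <- colabeled
  attr(out, "nDetected") <- nrow(idx)
  out
}
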