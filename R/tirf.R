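#' Detect exocytic flash events in a TIRF movie
#'
#' Automates the counting of exocytic fusion events that appear as
#' spreading flashes of fluorescence. The per-pixel background is a
#' rolling temporal median; the background-subtracted stack is Gaussian
#' smoothed per frame and events are strict spatiotemporal local maxima
#' exceeding \code{thresholdSd} robust (MAD-based) standard deviations of
#' the smoothed stack. Detections within the spatiotemporal exclusion
#' radius are deduplicated keeping the brightest.
#'
#' @param movie a \linkS4class{TirfMovie}.
#' @param thresholdSd detection threshold in robust SD units.
#' @param minSigmaPx Gaussian smoothing sigma (px), matched to the
#'   expected flash size.
#' @param exclusionRadius numeric(2): (frames, px) within which two
#'   detections are considered the same event.
#' @param medianWindow odd integer, rolling-median window (frames); the
#'   movie must be at least this long.
#' @return An \linkS4class{EventList} with event times (s) and 0-based
#'   pixel coordinates.
#' @examples
#' g <- genTirfMovie(nEvents = 5, cfg = genConfig(seed = 3))
#' nEvents(detectEvents(g$movie))
#' @export
detectEvents <- function(movie, thresholdSd = 5, minSigmaPx = 1.5,
                         exclusionRadius = c(3, 4), medianWindow = 15) {
  a <- frames(movie)
  nf <- dim(a)[1]
  if (nf < medianWindow)
    stop("movie shorter than the rolling-median window")
  # per-pixel rolling temporal median background
  bg <- apply(a, c(2, 3), function(v)
    stats::runmed(v, medianWindow, endrule = "median"))
  diffs <- a - bg
  sm <- array(0, dim(a))
  for (f in seq_len(nf))
    sm[f, , ] <- smooth_gaussian(diffs[f, , ], minSigmaPx)
  # the relative floor keeps numerical dust below threshold on
  # noise-free stacks, where the MAD collapses to zero
  thr <- max(thresholdSd * stats::mad(as.vector(sm), center = 0),
             1e-6 * max(abs(sm)))
  cand <- local_maxima_3d(sm) & sm > thr & sm > 0
  # replicate-padding inflates smoothed noise at the image border;
  # exclude a margin of the smoothing kernel radius
  border <- ceiling(2.5 * minSigmaPx)
  nr <- dim(a)[2]; nc <- dim(a)[3]
  if (2 * border < min(nr, nc)) {
    cand[, c(seq_len(border), nr - border + seq_len(border)), ] <- FALSE
    cand[, , c(seq_len(border), nc - border + seq_len(border))] <- FALSE
  }
  # exocytic flashes appear abruptly and then decay: keep only onset
  # maxima, where the previous frame's response is well below the peak
  # (suppresses secondary maxima riding on a flash's own decay tail)
  prev <- array(0, dim(sm))
  prev[2:nf, , ] <- sm[seq_len(nf - 1), , ]
  cand <- cand & (prev < 0.5 * sm)
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(EventList(params = list(thresholdSd = thresholdSd,
                                   minSigmaPx = minSigmaPx,
                                   exclusionRadius = exclusionRadius,
                                   medianWindow = medianWindow)))
  amp <- sm[cand]
  ord <- order(amp, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  amp <- amp[ord]
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    prior <- which(keep)
    dup <- length(prior) > 0 &&
      any(abs(idx[prior, 1] - idx[i, 1]) <= exclusionRadius[1] &
          sqrt((idx[prior, 2] - idx[i, 2])^2 +
               (idx[prior, 3] - idx[i, 3])^2) <= exclusionRadius[2])
    keep[i] <- !dup
  }
  idx <- idx[keep, , drop = FALSE]
  amp <- amp[keep]
  ev <- data.frame(t = (idx[, 1] - 1) * frameInterval(movie),
                   frame = as.integer(idx[, 1]),
                   row = idx[, 2] - 1, col = idx[, 3] - 1,
                   amplitude = amp)
  ev <- ev[order(ev$frame, ev$row, ev$col), ]
  rownames(ev) <- NULL
  EventList(ev, params = list(thresholdSd = thresholdSd,
                              minSigmaPx = minSigmaPx,
                              exclusionRadius = exclusionRadius,
                              medianWindow = medianWindow))
}

#' Cumulative event curve and mean release rate
#'
#' Bins detected events into a nondecreasing cumulative count versus time
#' and reports the mean release rate over the stimulated epoch.
#'
#' @param events an \linkS4class{EventList}.
#' @param binWidth bin width (s).
#' @param tStim start of the stimulated epoch (s).
#' @param tEnd end of the stimulated epoch (s); defaults to the last event
#'   time (or \code{tStim} if there are none).
#' @return list with \code{curve} (data.frame time, cumulative) and
#'   \code{rate} (events/s over [tStim, tEnd]).
#' @export
cumulativeEventCurve <- function(events, binWidth = 10, tStim = 0,
                                 tEnd = NULL) {
  tt <- events(events)$t
  if (is.null(tEnd)) tEnd <- if (length(tt)) max(tt) else tStim
  if (tEnd < tStim) stop("tEnd must not precede tStim")
  grid <- seq(tStim, max(tEnd, tStim + binWidth), by = binWidth)
  cum <- vapply(grid, function(g) sum(tt <= g), numeric(1))
  rate <- if (tEnd > tStim) sum(tt >= tStim & tt <= tEnd) / (tEnd - tStim)
          else 0
  list(curve = data.frame(time = grid, cumulative = cum), rate = rate)
}
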