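#' Normalize a quench curve to its pre-stimulation baseline
#'
#' Divides the curve by the mean fluorescence before stimulation so that
#' pre-stimulation values sit at 1.0 and post-stimulation values are
#' fractional fluorescence.
#'
#' @param curve a \linkS4class{TimeSeriesTrace} with t = 0 at stimulation
#'   (tStim annotation, default 0 when absent).
#' @return A normalized \linkS4class{TimeSeriesTrace}.
#' @export
normalizeQuench <- function(curve) {
  ts <- stimTime(curve)
  if (is.na(ts)) ts <- 0
  pre <- values(curve)[times(curve) < ts]
  if (length(pre) < 1) stop("no pre-stimulation samples")
  m <- mean(pre)
  if (m <= 0) stop("nonpositive pre-stimulation mean")
  TimeSeriesTrace(times(curve), values(curve) / m, tStim = ts,
                  id = paste0(traceId(curve), "-normalized"))
}

#' Fractional quench of an endocytosis curve
#'
#' For a normalized quench curve, the quenched fraction is
#' \code{1 - mean(F)} over the endpoint window (default the final 100 s
#' of the course), clipped to [0, 1] with flags. An integrated mode is
#' provided that averages \code{1 - F} over the whole post-stimulation
#' epoch instead of the endpoint window.
#'
#' @param curve a normalized \linkS4class{TimeSeriesTrace}.
#' @param endpointWindow seconds at the end of the course to average.
#' @param method "endpoint" (final-window mean) or "integrated"
#'   (time-averaged quench over the post-stimulation epoch).
#' @return numeric(1) in [0, 1] with attribute \code{"flags"}.
#' @examples
#' g <- genQuenchCurve(quenchFraction = 0.5)
#' fractionalQuench(normalizeQuench(g$trace))
#' @export
fractionalQuench <- function(curve, endpointWindow = 100,
                             method = c("endpoint", "integrated")) {
  method <- match.arg(method)
  tt <- times(curve)
  vv <- values(curve)
  ts <- stimTime(curve)
  if (is.na(ts)) ts <- 0
  if (method == "endpoint") {
    sel <- tt >= max(tt) - endpointWindow
    if (!any(sel)) stop("empty endpoint window")
    q <- 1 - mean(vv[sel])
  } else {
    sel <- tt >= ts
    if (!any(sel)) stop("no post-stimulation samples")
    q <- mean(1 - vv[sel])
  }
  fl <- character()
  if (q < 0) {
    fl <- "clipped_negative"
    q <- 0
  } else if (q > 1) {
    fl <- "clipped_over_1"
    q <- 1
  }
  attr(q, "flags") <- fl
  q
}

#' Endocytosis relative to a paired control
#'
#' Percent endocytosis of a test curve relative to its paired control
#' (the control is defined as 100% endocytosis):
#' \code{100 * fractionalQuench(test) / fractionalQuench(control)}.
#' Both curves are normalized to their pre-stimulation baselines first.
#'
#' @param test,control \linkS4class{TimeSeriesTrace} quench curves.
#' @param endpointWindow,method passed to \code{\link{fractionalQuench}}.
#' @return numeric(1), percent.
#' @examples
#' ctl <- genQuenchCurve(0.5, cfg = genConfig(1))
#' tst <- genQuenchCurve(0.25, cfg = genConfig(2))
#' relativeEndocytosis(tst$trace, ctl$trace)  # ~50
#' @export
relativeEndocytosis <- function(test, control, endpointWindow = 100,
                                method = c("endpoint", "integrated")) {
  method <- match.arg(method)
  qt <- fractionalQuench(normalizeQuench(test), endpointWindow, method)
  qc <- fractionalQuench(normalizeQuench(control), endpointWindow, method)
  if (qc <= 0)
    stop("zero control quench: no endocytosis to normalize against")
  100 * as.numeric(qt) / as.numeric(qc)
}
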