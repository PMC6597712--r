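default_windows <- function(trace, basalWindow, stimWindow, nh4clWindow) {
  ts <- stimTime(trace)
  tn <- nh4clTime(trace)
  if (is.null(basalWindow)) {
    if (is.na(ts)) stop("no tStim annotation and no basalWindow given")
    basalWindow <- c(min(times(trace)), ts)
  }
  if (is.null(stimWindow)) {
    if (is.na(tn)) stop("no tNH4Cl annotation and no stimWindow given")
    stimWindow <- c(tn - 60, tn)
  }
  if (is.null(nh4clWindow)) {
    if (is.na(tn)) stop("no tNH4Cl annotation and no nh4clWindow given")
    nh4clWindow <- c(tn + 10, tn + 40)
  }
  list(basal = basalWindow, stim = stimWindow, nh4cl = nh4clWindow)
}

# robust SD of the basal samples; guards the normalization denominator
basal_robust_sd <- function(trace, basalWindow) {
  sel <- times(trace) >= basalWindow[1] & times(trace) < basalWindow[2]
  stats::mad(values(trace)[sel])
}

check_dynamic_range <- function(trace, basalMean, nh4clMean, basalWindow) {
  tol <- 5 * basal_robust_sd(trace, basalWindow)
  if (nh4clMean - basalMean <= tol)
    stop("degenerate trace: NH4Cl plateau does not exceed basal ",
         "fluorescence (flat or inverted trace; nothing to normalize)")
}

#' Normalize a pHluorin trace to a 0-1 scale
#'
#' Rescales the trace so the basal-window mean maps to 0 and the
#' post-NH4Cl window mean maps to 1:
#' \code{(value(t) - basal) / (nh4cl - basal)}. The basal window defaults
#' to everything before \code{tStim}; the NH4Cl window defaults to 30 s
#' starting 10 s after \code{tNH4Cl}, skipping the mixing transient.
#'
#' @param trace a \linkS4class{TimeSeriesTrace}.
#' @param basalWindow,nh4clWindow numeric(2) time windows (s), each
#'   containing at least 3 samples; \code{NULL} uses the annotations.
#' @return A unitless \linkS4class{TimeSeriesTrace}.
#' @examples
#' g <- genExoTrace(stimRiseFraction = 0.5)
#' nt <- normalizeTrace(g$trace)
#' @export
normalizeTrace <- function(trace, basalWindow = NULL, nh4clWindow = NULL) {
  if (is.null(basalWindow)) {
    if (is.na(stimTime(trace)))
      stop("no tStim annotation and no basalWindow given")
    basalWindow <- c(min(times(trace)), stimTime(trace))
  }
  if (is.null(nh4clWindow)) {
    if (is.na(nh4clTime(trace)))
      stop("no tNH4Cl annotation and no nh4clWindow given")
    nh4clWindow <- nh4clTime(trace) + c(10, 40)
  }
  basal <- window_mean(trace, basalWindow, what = "basal window")
  nh4cl <- window_mean(trace, nh4clWindow, what = "NH4Cl window")
  check_dynamic_range(trace, basal, nh4cl, basalWindow)
  TimeSeriesTrace((times(trace)), (values(trace) - basal) / (nh4cl - basal),
                  tStim = stimTime(trace), tNH4Cl = nh4clTime(trace),
                  tBaf = bafTime(trace),
                  id = paste0(traceId(trace), "-normalized"))
}

#' Percent stimulated exocytosis from a pHluorin trace
#'
#' Computes
#' \code{100 * (stim_mean - basal_mean) / (nh4cl_mean - basal_mean)}:
#' the averaged stimulated fluorescence rise as a percentage of the full
#' dequenchable pool revealed by NH4Cl. The stimulated window defaults to
#' the final 60 s before NH4Cl addition (the plateau of the stimulated
#' response); negative results are clipped to 0 and flagged, results over
#' 100 are retained and flagged.
#'
#' @param trace a \linkS4class{TimeSeriesTrace} with tStim/tNH4Cl
#'   annotations (or explicit windows).
#' @param basalWindow,stimWindow,nh4clWindow numeric(2) windows (s);
#'   \code{NULL} uses the defaults derived from the annotations.
#' @return An \linkS4class{ExoResult}.
#' @examples
#' g <- genExoTrace(stimRiseFraction = 0.25)
#' pctExocytosis(percentExocytosis(g$trace))  # 25
#' @export
percentExocytosis <- function(trace, basalWindow = NULL, stimWindow = NULL,
                              nh4clWindow = NULL) {
  w <- default_windows(trace, basalWindow, stimWindow, nh4clWindow)
  basal <- window_mean(trace, w$basal, what = "basal window")
  stim <- window_mean(trace, w$stim, what = "stimulated window")
  nh4cl <- window_mean(trace, w$nh4cl, what = "NH4Cl window")
  check_dynamic_range(trace, basal, nh4cl, w$basal)
  pct <- 100 * (stim - basal) / (nh4cl - basal)
  fl <- character()
  if (pct < 0) {
    fl <- "clipped_negative"
    pct <- 0
  } else if (pct > 100) fl <- "over_100"
  new("ExoResult", pctExocytosis = pct, basalMean = basal, stimMean = stim,
      nh4clMean = nh4cl, windows = w, flags = fl)
}

#' Spontaneous (unstimulated) release
#'
#' Applies the percent-exocytosis normalization with a pre-stimulus drift
#' window substituted for the stimulated window: the basal reference is
#' the mean over the first \code{subWindow} seconds of the pre-stimulus
#' epoch and the drift readout is the mean over its last \code{subWindow}
#' seconds, both scaled by the NH4Cl dynamic range. Requires a
#' pre-stimulus epoch of at least 60 s.
#'
#' @param trace a \linkS4class{TimeSeriesTrace}.
#' @param preStimWindow numeric(2) pre-stimulus window (s); defaults to
#'   everything before \code{tStim}.
#' @param nh4clWindow numeric(2); defaults as in
#'   \code{\link{percentExocytosis}}.
#' @param subWindow seconds used for the basal and drift sub-windows.
#' @return numeric(1), spontaneous release in percent.
#' @export
spontaneousRelease <- function(trace, preStimWindow = NULL,
                               nh4clWindow = NULL, subWindow = 20) {
  if (is.null(preStimWindow)) {
    if (is.na(stimTime(trace)))
      stop("no tStim annotation and no preStimWindow given")
    preStimWindow <- c(min(times(trace)), stimTime(trace))
  }
  if (diff(preStimWindow) < 60)
    stop("pre-stimulus epoch must span at least 60 s")
  if (is.null(nh4clWindow)) {
    if (is.na(nh4clTime(trace)))
      stop("no tNH4Cl annotation and no nh4clWindow given")
    nh4clWindow <- nh4clTime(trace) + c(10, 40)
  }
  basal <- window_mean(trace, c(preStimWindow[1],
                                preStimWindow[1] + subWindow),
                       what = "basal sub-window")
  drift <- window_mean(trace, c(preStimWindow[2] - subWindow,
                                preStimWindow[2]),
                       what = "drift sub-window")
  nh4cl <- window_mean(trace, nh4clWindow, what = "NH4Cl window")
  check_dynamic_range(trace, basal, nh4cl,
                      c(preStimWindow[1], preStimWindow[1] + subWindow))
  100 * (drift - basal) / (nh4cl - basal)
}
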