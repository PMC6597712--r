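#' @import methods
NULL

#' Annotated fluorescence time course
#'
#' Container for a single-cell or field-averaged fluorescence trace with
#' optional epoch annotations: stimulation time, NH4Cl (dequench) addition
#' time and bafilomycin pre-treatment time. Times are in seconds, values in
#' arbitrary fluorescence units.
#'
#' @slot times numeric, strictly increasing sample times (s).
#' @slot values numeric, fluorescence values (finite).
#' @slot tStim numeric(1), stimulation time (s) or \code{NA}.
#' @slot tNH4Cl numeric(1), NH4Cl addition time (s) or \code{NA}.
#' @slot tBaf numeric(1), bafilomycin addition time (s) or \code{NA}.
#' @slot id character(1), free-text identifier.
#' @exportClass TimeSeriesTrace
setClass("TimeSeriesTrace",
  representation(times = "numeric", values = "numeric",
                 tStim = "numeric", tNH4Cl = "numeric", tBaf = "numeric",
                 id = "character"),
  prototype(tStim = NA_real_, tNH4Cl = NA_real_, tBaf = NA_real_,
            id = "trace"))

setValidity("TimeSeriesTrace", function(object) {
  msg <- NULL
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all values must be finite")
  if (!is.na(object@tStim) && !is.na(object@tNH4Cl) &&
      object@tStim >= object@tNH4Cl)
    msg <- c(msg, "tStim must precede tNH4Cl")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TimeSeriesTrace
#'
#' @param times sample times in seconds, strictly increasing.
#' @param values fluorescence values (a.u.), finite, same length as times.
#' @param tStim,tNH4Cl,tBaf optional epoch annotations (s).
#' @param id identifier string.
#' @return A \linkS4class{TimeSeriesTrace}.
#' @examples
#' tr <- TimeSeriesTrace(0:10, rep(100, 11), tStim = 2)
#' @export
TimeSeriesTrace <- function(times, values, tStim = NA_real_,
                            tNH4Cl = NA_real_, tBaf = NA_real_,
                            id = "trace") {
  new("TimeSeriesTrace", times = as.numeric(times),
      values = as.numeric(values), tStim = as.numeric(tStim),
      tNH4Cl = as.numeric(tNH4Cl), tBaf = as.numeric(tBaf), id = id)
}

#' TIRF movie stack
#'
#' Frame stack of TIRF (or TIRF-like) imaging with acquisition metadata.
#' The first array dimension indexes frames.
#'
#' @slot frames 3-D numeric array (frame, row, col).
#' @slot frameInterval numeric(1), seconds between frames.
#' @slot pixelSize numeric(1), pixel edge length in nm.
#' @exportClass TirfMovie
setClass("TirfMovie",
  representation(frames = "array", frameInterval = "numeric",
                 pixelSize = "numeric"))

setValidity("TirfMovie", function(object) {
  msg <- NULL
  if (length(dim(object@frames)) != 3)
    msg <- c(msg, "frames must be a 3-D array (frame, row, col)")
  else if (dim(object@frames)[1] < 2)
    msg <- c(msg, "movie must contain at least 2 frames")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TirfMovie
#' @param frames 3-D array (frame, row, col) of intensities.
#' @param frameInterval seconds between frames.
#' @param pixelSize pixel size in nm.
#' @return A \linkS4class{TirfMovie}.
#' @export
TirfMovie <- function(frames, frameInterval = 1, pixelSize = 100) {
  new("TirfMovie", frames = frames, frameInterval = frameInterval,
      pixelSize = pixelSize)
}

#' Detected exocytic event list
#'
#' Events detected in a TIRF movie, with time (s), position (0-based pixel
#' row/col) and amplitude, plus a snapshot of the detection parameters.
#'
#' @slot events data.frame with columns t, frame, row, col, amplitude.
#' @slot params list, detection parameter snapshot.
#' @exportClass EventList
setClass("EventList",
  representation(events = "data.frame", params = "list"),
  prototype(params = list()))

setValidity("EventList", function(object) {
  need <- c("t", "frame", "row", "col", "amplitude")
  if (!all(need %in% names(object@events)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Construct an EventList
#' @param events data.frame with columns t, frame, row, col, amplitude.
#' @param params list of detection parameters.
#' @return An \linkS4class{EventList}.
#' @export
EventList <- function(events = data.frame(t = numeric(), frame = integer(),
                                          row = numeric(), col = numeric(),
                                          amplitude = numeric()),
                      params = list()) {
  new("EventList", events = events, params = params)
}

#' Two-channel still image with cell mask
#'
#' Substrate for shell fractions, Manders overlap, line scans and puncta
#' counting. Channels are background-subtracted nonnegative intensities;
#' negative input pixels are clipped to zero with a warning.
#'
#' @slot channelR,channelG numeric matrices of equal dimension.
#' @slot cellMask logical matrix, same dimension, at least one TRUE pixel.
#' @slot pixelSize numeric(1), nm per pixel.
#' @exportClass MaskedImagePair
setClass("MaskedImagePair",
  representation(channelR = "matrix", channelG = "matrix",
                 cellMask = "matrix", pixelSize = "numeric"))

setValidity("MaskedImagePair", function(object) {
  msg <- NULL
  d <- dim(object@channelR)
  if (!identical(d, dim(object@channelG)) ||
      !identical(d, dim(object@cellMask)))
    msg <- c(msg, "channels and mask must share dimensions")
  if (!is.logical(object@cellMask)) msg <- c(msg, "cellMask must be logical")
  else if (!any(object@cellMask)) msg <- c(msg, "cellMask must be nonempty")
  if (any(!is.finite(object@channelR)) || any(!is.finite(object@channelG)))
    msg <- c(msg, "channel intensities must be finite")
  if (any(object@channelR < 0) || any(object@channelG < 0))
    msg <- c(msg, "channel intensities must be nonnegative")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MaskedImagePair
#'
#' Negative pixel values (e.g. from background subtraction) are clipped to
#' zero with a warning.
#'
#' @param channelR,channelG numeric intensity matrices, same dimensions.
#' @param cellMask logical matrix; defaults to all-TRUE.
#' @param pixelSize nm per pixel.
#' @return A \linkS4class{MaskedImagePair}.
#' @export
MaskedImagePair <- function(channelR, channelG, cellMask = NULL,
                            pixelSize = 100) {
  if (is.null(cellMask))
    cellMask <- matrix(TRUE, nrow(channelR), ncol(channelR))
  if (any(channelR < 0) || any(channelG < 0)) {
    warning("negative intensities clipped to 0")
    channelR[channelR < 0] <- 0
    channelG[channelG < 0] <- 0
  }
  new("MaskedImagePair", channelR = channelR, channelG = channelG,
      cellMask = cellMask, pixelSize = pixelSize)
}

#' Per-residue NMR quantities
#'
#' Table of per-residue amide and carbon chemical shifts and/or peak
#' intensities, aligned to a 1-based protein sequence. Missing values are
#' \code{NA} (prolines have no amide entries). Shifts outside physical
#' ranges (H 5-12 ppm, N 100-140 ppm, C 10-80 ppm) raise a warning.
#'
#' @slot data data.frame with columns residue, aa and any of H, N, CA, CB,
#'   intensity.
#' @slot sequence character(1), one-letter sequence or "".
#' @exportClass ResidueTable
setClass("ResidueTable",
  representation(data = "data.frame", sequence = "character"),
  prototype(sequence = ""))

setValidity("ResidueTable", function(object) {
  msg <- NULL
  d <- object@data
  if (!all(c("residue", "aa") %in% names(d)))
    msg <- c(msg, "data must have columns residue and aa")
  else {
    if (anyDuplicated(d$residue)) msg <- c(msg, "residue numbers must be unique")
    if (nzchar(object@sequence) &&
        any(d$residue < 1 | d$residue > nchar(object@sequence)))
      msg <- c(msg, "residue numbers must lie within the sequence length")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a ResidueTable
#'
#' @param data data.frame with columns residue, aa and any subset of
#'   H, N, CA, CB, intensity (ppm for shifts, a.u. for intensities).
#' @param sequence optional one-letter protein sequence the numbering
#'   refers to.
#' @return A \linkS4class{ResidueTable}.
#' @export
ResidueTable <- function(data, sequence = "") {
  data$residue <- as.integer(data$residue)
  obj <- new("ResidueTable", data = data, sequence = sequence)
  rngs <- list(H = c(5, 12), N = c(100, 140), CA = c(10, 80), CB = c(10, 80))
  for (col in intersect(names(rngs), names(data))) {
    v <- data[[col]]
    bad <- !is.na(v) & (v < rngs[[col]][1] | v > rngs[[col]][2])
    if (any(bad))
      warning(sprintf("%d %s shifts outside physical range", sum(bad), col))
  }
  if ("aa" %in% names(data)) {
    pro <- !is.na(data$aa) & data$aa == "P"
    for (col in intersect(c("H", "N"), names(data)))
      if (any(pro & !is.na(data[[col]])))
        warning("prolines should not carry amide entries")
  }
  obj
}

#' Blot lane densitometry table
#'
#' Per-lane band densities for standards (known concentration) and unknowns
#' (cell-lysate lanes with known cell equivalents and loaded volume), plus
#' three nonspecific-band densities per lane used as loading controls.
#'
#' @slot lanes data.frame with columns lane, role, band_density,
#'   load1, load2, load3, known_conc, cell_equivalents, loaded_volume_ml.
#' @exportClass DensitometryTable
setClass("DensitometryTable", representation(lanes = "data.frame"))

setValidity("DensitometryTable", function(object) {
  d <- object@lanes
  msg <- NULL
  need <- c("lane", "role", "band_density", "load1", "load2", "load3")
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("lanes must have columns:", paste(need, collapse = ", ")))
  else {
    if (!all(d$role %in% c("standard", "unknown")))
      msg <- c(msg, "role must be 'standard' or 'unknown'")
    if (any(d$band_density < 0)) msg <- c(msg, "densities must be >= 0")
    sc <- d$known_conc[d$role == "standard"]
    if (length(unique(sc[!is.na(sc)])) < 3)
      msg <- c(msg, "standards must span >= 3 distinct concentrations")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a DensitometryTable
#' @param lanes data.frame of lane measurements (see class docs).
#' @return A \linkS4class{DensitometryTable}.
#' @export
DensitometryTable <- function(lanes) {
  for (col in c("known_conc", "cell_equivalents", "loaded_volume_ml"))
    if (!col %in% names(lanes)) lanes[[col]] <- NA_real_
  new("DensitometryTable", lanes = lanes)
}

#' Linear density-to-concentration calibration
#'
#' @slot slope numeric(1), density units per ug/ml (> 0).
#' @slot intercept numeric(1), density units.
#' @slot rSquared numeric(1).
#' @slot range numeric(2), concentration range spanned by the standards.
#' @exportClass CalibrationFit
setClass("CalibrationFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", range = "numeric"))

setValidity("CalibrationFit", function(object) {
  if (object@slope <= 0) "slope must be > 0" else TRUE
})

#' Percent-exocytosis result
#'
#' @slot pctExocytosis numeric(1), percent.
#' @slot basalMean,stimMean,nh4clMean numeric(1), window means (a.u.).
#' @slot windows list of the window definitions used (s).
#' @slot flags character, quality flags ("clipped_negative", "over_100").
#' @exportClass ExoResult
setClass("ExoResult",
  representation(pctExocytosis = "numeric", basalMean = "numeric",
                 stimMean = "numeric", nh4clMean = "numeric",
                 windows = "list", flags = "character"),
  prototype(flags = character()))

#' Membrane-proximal shell fraction result
#'
#' @slot shellFraction numeric(1) in [0, 1].
#' @slot shellWidth numeric(1), nm.
#' @slot shellPixelCount,maskPixelCount integer(1).
#' @slot flags character.
#' @exportClass ShellResult
setClass("ShellResult",
  representation(shellFraction = "numeric", shellWidth = "numeric",
                 shellPixelCount = "integer", maskPixelCount = "integer",
                 flags = "character"),
  prototype(flags = character()))

setValidity("ShellResult", function(object) {
  if (object@shellFraction < -1e-12 || object@shellFraction > 1 + 1e-12)
    "shellFraction must lie in [0, 1]" else TRUE
})

#' Residue-resolved profile
#'
#' A per-residue quantity: amide CSD or secondary carbon shift (ppm), or a
#' lipid/free intensity ratio (unitless).
#'
#' @slot residue integer residue indices.
#' @slot value numeric profile values.
#' @slot quantity character(1), what the values are.
#' @slot excluded integer, residues excluded (e.g. free intensity at floor).
#' @slot flags character.
#' @exportClass ResidueProfile
setClass("ResidueProfile",
  representation(residue = "integer", value = "numeric",
                 quantity = "character", excluded = "integer",
                 flags = "character"),
  prototype(excluded = integer(), flags = character()))
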