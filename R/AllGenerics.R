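#' @name accessors
#' @title Accessors for asynquant data classes
#' @description Slot accessors for the S4 containers. Use these rather than
#'   \code{@} access.
#' @param x an asynquant object.
NULL

#' @rdname accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))
#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("stimTime", function(x) standardGeneric("stimTime"))
#' @rdname accessors
#' @export
setGeneric("nh4clTime", function(x) standardGeneric("nh4clTime"))
#' @rdname accessors
#' @export
setGeneric("bafTime", function(x) standardGeneric("bafTime"))
#' @rdname accessors
#' @export
setGeneric("traceId", function(x) standardGeneric("traceId"))
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("channelR", function(x) standardGeneric("channelR"))
#' @rdname accessors
#' @export
setGeneric("channelG", function(x) standardGeneric("channelG"))
#' @rdname accessors
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))
#' @rdname accessors
#' @export
setGeneric("residueData", function(x) standardGeneric("residueData"))
#' @rdname accessors
#' @export
setGeneric("residueSequence", function(x) standardGeneric("residueSequence"))
#' @rdname accessors
#' @export
setGeneric("laneData", function(x) standardGeneric("laneData"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("calibrationRange", function(x) standardGeneric("calibrationRange"))
#' @rdname accessors
#' @export
setGeneric("pctExocytosis", function(x) standardGeneric("pctExocytosis"))
#' @rdname accessors
#' @export
setGeneric("shellFraction", function(x) standardGeneric("shellFraction"))
#' @rdname accessors
#' @export
setGeneric("flags", function(x) standardGeneric("flags"))

setMethod("times", "TimeSeriesTrace", function(x) x@times)
setMethod("values", "TimeSeriesTrace", function(x) x@values)
setMethod("stimTime", "TimeSeriesTrace", function(x) x@tStim)
setMethod("nh4clTime", "TimeSeriesTrace", function(x) x@tNH4Cl)
setMethod("bafTime", "TimeSeriesTrace", function(x) x@tBaf)
setMethod("traceId", "TimeSeriesTrace", function(x) x@id)

setMethod("frames", "TirfMovie", function(x) x@frames)
setMethod("frameInterval", "TirfMovie", function(x) x@frameInterval)
setMethod("pixelSize", "TirfMovie", function(x) x@pixelSize)
setMethod("pixelSize", "MaskedImagePair", function(x) x@pixelSize)

setMethod("events", "EventList", function(x) x@events)
setMethod("nEvents", "EventList", function(x) nrow(x@events))

setMethod("channelR", "MaskedImagePair", function(x) x@channelR)
setMethod("channelG", "MaskedImagePair", function(x) x@channelG)
setMethod("cellMask", "MaskedImagePair", function(x) x@cellMask)

setMethod("residueData", "ResidueTable", function(x) x@data)
setMethod("residueSequence", "ResidueTable", function(x) x@sequence)

setMethod("laneData", "DensitometryTable", function(x) x@lanes)

#' @rdname accessors
#' @param object a CalibrationFit.
#' @param ... unused.
#' @export
setMethod("coef", "CalibrationFit",
          function(object, ...) c(intercept = object@intercept,
                                  slope = object@slope))
setMethod("rSquared", "CalibrationFit", function(x) x@rSquared)
setMethod("calibrationRange", "CalibrationFit", function(x) x@range)

setMethod("pctExocytosis", "ExoResult", function(x) x@pctExocytosis)
setMethod("flags", "ExoResult", function(x) x@flags)
setMethod("shellFraction", "ShellResult", function(x) x@shellFraction)
setMethod("flags", "ShellResult", function(x) x@flags)
setMethod("flags", "ResidueProfile", function(x) x@flags)

#' Coerce a ResidueProfile to a data.frame
#' @param x a \linkS4class{ResidueProfile}.
#' @param ... unused.
#' @return data.frame with columns residue and value.
#' @export
setMethod("as.data.frame", "ResidueProfile", function(x, ...) {
  data.frame(residue = x@residue, value = x@value)
})

setMethod("show", "TimeSeriesTrace", function(object) {
  cat(sprintf("TimeSeriesTrace '%s': %d samples, t = [%g, %g] s\n",
              object@id, length(object@times),
              min(object@times), max(object@times)))
  ann <- c(tStim = object@tStim, tNH4Cl = object@tNH4Cl, tBaf = object@tBaf)
  ann <- ann[!is.na(ann)]
  if (length(ann))
    cat("  annotations:", paste(names(ann), ann, sep = " = ",
                                collapse = ", "), "\n")
})

setMethod("show", "TirfMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("TirfMovie: %d frames of %d x %d px (%g s/frame, %g nm/px)\n",
              d[1], d[2], d[3], object@frameInterval, object@pixelSize))
})

setMethod("show", "EventList", function(object) {
  cat(sprintf("EventList: %d events\n", nrow(object@events)))
  if (nrow(object@events)) print(utils::head(object@events, 5))
})

setMethod("show", "MaskedImagePair", function(object) {
  cat(sprintf("MaskedImagePair: %d x %d px, %d mask px (%g nm/px)\n",
              nrow(object@channelR), ncol(object@channelR),
              sum(object@cellMask), object@pixelSize))
})

setMethod("show", "ResidueTable", function(object) {
  cols <- setdiff(names(object@data), c("residue", "aa"))
  cat(sprintf("ResidueTable: %d residues; columns: %s\n",
              nrow(object@data), paste(cols, collapse = ", ")))
})

setMethod("show", "DensitometryTable", function(object) {
  d <- object@lanes
  cat(sprintf("DensitometryTable: %d standards, %d unknowns\n",
              sum(d$role == "standard"), sum(d$role == "unknown")))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit: density = %.4g * conc + %.4g (R^2 = %.4f, range %g-%g ug/ml)\n",
    object@slope, object@intercept, object@rSquared,
    object@range[1], object@range[2]))
})

setMethod("show", "ExoResult", function(object) {
  cat(sprintf("ExoResult: %.2f%% exocytosis (basal %.3g, stim %.3g, NH4Cl %.3g)\n",
              object@pctExocytosis, object@basalMean, object@stimMean,
              object@nh4clMean))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ShellResult", function(object) {
  cat(sprintf("ShellResult: fraction %.4f (shell %g nm, %d/%d px)\n",
              object@shellFraction, object@shellWidth,
              object@shellPixelCount, object@maskPixelCount))
})

setMethod("show", "ResidueProfile", function(object) {
  cat(sprintf("ResidueProfile [%s]: %d residues", object@quantity,
              length(object@residue)))
  if (length(object@excluded))
    cat(sprintf(" (%d excluded)", length(object@excluded)))
  cat("\n")
})
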