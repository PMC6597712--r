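#' Generator configuration
#'
#' Common configuration for the synthetic-data generators. A fixed seed
#' makes every generator bit-identical across runs; \code{noiseSd = 0}
#' produces the noiseless model exactly. Size parameters specific to one
#' generator can be passed through \code{...} and are stored alongside.
#'
#' @param seed integer RNG seed.
#' @param noiseSd nonnegative Gaussian noise SD (a.u.; generators document
#'   the scale it applies on).
#' @param ... further per-generator size parameters (e.g. nFrames,
#'   imageShape, pixelSizeNm, nResidues, nLanes, nEvents).
#' @return A list of class \code{"GenConfig"}.
#' @examples
#' cfg <- genConfig(seed = 1, noiseSd = 0.5)
#' @export
genConfig <- function(seed = 1L, noiseSd = 0, ...) {
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  structure(list(seed = as.integer(seed), noiseSd = noiseSd, ...),
            class = "GenConfig")
}
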