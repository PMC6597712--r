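samples_baseline_shifts <- function(n, aa) {
  # smooth, deterministic baseline amide shifts typical of a disordered
  # protein; carbons sit at the residue-type random-coil value
  rc <- random_coil_values()
  i <- seq_len(n)
  list(H = 8.25 + 0.15 * sin(i / 6) + 0.05 * cos(i / 2.3),
       N = 119 + 4 * sin(i / 9 + 1) + 1.5 * cos(i / 3.1),
       CA = rc$CA[match(aa, rc$aa)],
       CB = rc$CB[match(aa, rc$aa)])
}

gen_sequence <- function(nResidues) {
  asyn <- asynSequence()
  if (nResidues <= nchar(asyn)) substr(asyn, 1, nResidues)
  else paste(rep(strsplit(asyn, "")[[1]],
                 length.out = nResidues), collapse = "")
}

#' Generate paired wild-type and mutant chemical-shift tables
#'
#' The mutant amide shifts equal the wild-type shifts plus a Gaussian bump
#' centered at \code{perturbSite} (emulating the local chemical-shift
#' perturbation a point mutation causes in the micelle-bound state); the
#' mutant carbon shifts are additionally offset everywhere by
#' \code{carbonOffset}, emulating a referencing discrepancy between
#' spectra. Prolines carry no amide entries.
#'
#' @param nResidues protein length (uses the alpha-synuclein sequence for
#'   lengths up to 140).
#' @param perturbSite residue index of the perturbation center.
#' @param perturbWidth Gaussian width of the perturbation (residues).
#' @param perturbMagnitude amide-proton perturbation amplitude (ppm); the
#'   nitrogen perturbation is 5x this, matching the larger 15N shift range.
#' @param carbonOffset global CA/CB offset of the mutant table (ppm).
#' @param cfg a \code{\link{genConfig}}; \code{noiseSd} is in ppm, applied
#'   to the mutant measurements (the nitrogen noise is 5x).
#' @return list(wt, mut = \linkS4class{ResidueTable},
#'   truth = list(perturbSite, perturbWidth, carbonOffset)).
#' @export
genShiftTables <- function(nResidues = 140, perturbSite = 70,
                           perturbWidth = 5, perturbMagnitude = 0.1,
                           carbonOffset = 0, cfg = genConfig()) {
  seqc <- gen_sequence(nResidues)
  aa <- strsplit(seqc, "")[[1]]
  base <- samples_baseline_shifts(nResidues, aa)
  i <- seq_len(nResidues)
  pro <- aa == "P"
  mk <- function(H, N, CA, CB) {
    H[pro] <- NA; N[pro] <- NA
    ResidueTable(data.frame(residue = i, aa = aa, H = H, N = N,
                            CA = CA, CB = CB), sequence = seqc)
  }
  bump <- exp(-(i - perturbSite)^2 / (2 * perturbWidth^2))
  with_seed(cfg$seed, {
    wt <- mk(base$H, base$N, base$CA, base$CB)
    noise <- function(scale = 1)
      if (cfg$noiseSd > 0) stats::rnorm(nResidues, 0, scale * cfg$noiseSd)
      else 0
    mut <- mk(base$H + perturbMagnitude * bump + noise(),
              base$N + 5 * perturbMagnitude * bump + noise(5),
              base$CA + carbonOffset + noise(),
              base$CB + carbonOffset + noise())
    list(wt = wt, mut = mut,
         truth = list(perturbSite = perturbSite,
                      perturbWidth = perturbWidth,
                      carbonOffset = carbonOffset))
  })
}

#' Generate paired lipid and lipid-free peak-intensity tables
#'
#' Emulates a vesicle-binding experiment in which residues bound to slowly
#' tumbling SUVs lose NMR intensity: the lipid/free intensity ratio sits
#' near \code{boundFreeFraction} for residues N-terminal to
#' \code{boundaryResidue} and transitions logistically to
#' \code{unboundFreeFraction} C-terminal to it (the V70P-like release
#' profile when the two differ, a flat profile when they are equal).
#'
#' @param boundaryResidue transition midpoint (residue index).
#' @param boundFreeFraction free fraction on the bound (N-terminal) side.
#' @param unboundFreeFraction free fraction on the released side.
#' @param transitionWidth logistic width (residues).
#' @param nResidues protein length.
#' @param baseIntensity mean lipid-free peak intensity (a.u.).
#' @param cfg a \code{\link{genConfig}}; \code{noiseSd} is relative to
#'   \code{baseIntensity}.
#' @return list(lipid, free = \linkS4class{ResidueTable},
#'   truth = list(boundaryResidue, boundFreeFraction,
#'   unboundFreeFraction)).
#' @export
genBindingProfile <- function(boundaryResidue = 70, boundFreeFraction = 0.2,
                              unboundFreeFraction = 1.0,
                              transitionWidth = 2, nResidues = 140,
                              baseIntensity = 1000, cfg = genConfig()) {
  stopifnot(boundFreeFraction >= 0, boundFreeFraction <= 1,
            unboundFreeFraction >= 0, unboundFreeFraction <= 1)
  seqc <- gen_sequence(nResidues)
  aa <- strsplit(seqc, "")[[1]]
  i <- seq_len(nResidues)
  ratio <- boundFreeFraction +
    (unboundFreeFraction - boundFreeFraction) /
      (1 + exp(-(i - boundaryResidue) / transitionWidth))
  with_seed(cfg$seed, {
    free_int <- baseIntensity * (1 + 0.1 * sin(i / 5))
    noise <- function() if (cfg$noiseSd > 0)
      stats::rnorm(nResidues, 0, cfg$noiseSd * baseIntensity) else 0
    lipid_int <- pmax(free_int * ratio + noise(), 0)
    pro <- aa == "P"
    free_int[pro] <- NA
    lipid_int[pro] <- NA
    mk <- function(v) ResidueTable(data.frame(residue = i, aa = aa,
                                              intensity = v),
                                   sequence = seqc)
    list(lipid = mk(lipid_int), free = mk(free_int),
         truth = list(boundaryResidue = boundaryResidue,
                      boundFreeFraction = boundFreeFraction,
                      unboundFreeFraction = unboundFreeFraction))
  })
}

#' Generate a synthetic western-blot densitometry table
#'
#' Band density is linear in concentration, scaled per lane by a loading
#' factor (log-normal with coefficient of variation \code{loadingCv});
#' three nonspecific-band densities per lane encode the loading factor, as
#' in a loading-control normalization. Defaults use the five standard
#' concentrations 2, 3.5, 5, 6.5 and 8 ug/ml.
#'
#' @param standardConcs standard concentrations (ug/ml).
#' @param unknownConcs true unknown-lane concentrations (ug/ml).
#' @param slope density units per ug/ml.
#' @param loadingCv coefficient of variation of the per-lane loading
#'   factor (0 = equal loading).
#' @param loadingBases densities of the three nonspecific bands at unit
#'   loading.
#' @param cellEquivalents cell equivalents per unknown lane (default
#'   7.5e6 cells/ml x 25 ul).
#' @param loadedVolumeMl loaded volume per lane (ml).
#' @param cfg a \code{\link{genConfig}}; \code{noiseSd} is in density
#'   units, applied to specific and nonspecific bands.
#' @return list(table = \linkS4class{DensitometryTable},
#'   truth = list(trueLaneConcentration, slope, loadingFactors)).
#' @export
genBlot <- function(standardConcs = c(2, 3.5, 5, 6.5, 8),
                    unknownConcs = c(3, 6), slope = 1000, loadingCv = 0,
                    loadingBases = c(400, 500, 600),
                    cellEquivalents = 7.5e6 * 0.025,
                    loadedVolumeMl = 0.025, cfg = genConfig()) {
  concs <- c(standardConcs, unknownConcs)
  n <- length(concs)
  role <- c(rep("standard", length(standardConcs)),
            rep("unknown", length(unknownConcs)))
  with_seed(cfg$seed, {
    lf <- if (loadingCv > 0)
      exp(stats::rnorm(n, -loadingCv^2 / 2, loadingCv)) else rep(1, n)
    noise <- function(k) if (cfg$noiseSd > 0)
      stats::rnorm(k, 0, cfg$noiseSd) else rep(0, k)
    band <- pmax(slope * concs * lf + noise(n), 0)
    loads <- sapply(loadingBases, function(b) pmax(b * lf + noise(n), 0))
    lanes <- data.frame(
      lane = paste0("L", seq_len(n)), role = role, band_density = band,
      load1 = loads[, 1], load2 = loads[, 2], load3 = loads[, 3],
      known_conc = ifelse(role == "standard", concs, NA_real_),
      cell_equivalents = ifelse(role == "unknown", cellEquivalents,
                                NA_real_),
      loaded_volume_ml = ifelse(role == "unknown", loadedVolumeMl,
                                NA_real_))
    list(table = DensitometryTable(lanes),
         truth = list(trueLaneConcentration = unknownConcs, slope = slope,
                      loadingFactors = lf))
  })
}
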