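# average residue masses (Da) and the mass of water
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

#' Human alpha-synuclein sequence
#'
#' The 140-residue human alpha-synuclein sequence (UniProt P37840),
#' packaged so mass and extinction-coefficient calculations need no
#' network access.
#'
#' @return character(1) one-letter sequence.
#' @examples
#' nchar(asynSequence())  # 140
#' @export
asynSequence <- function() {
  paste0("MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVA",
         "EKTKEQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGKNEEGAPQEGI",
         "LEDMPVDPDNEAYEMPSEEGYQDYEPEA")
}

check_sequence <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(aa, names(AA_MASS))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  aa
}

#' Protein molecular weight
#'
#' Average (not monoisotopic) molecular weight: the sum of the free
#' amino-acid masses minus (n - 1) waters of condensation, computed here
#' as the sum of dehydrated residue masses plus one water.
#'
#' @param sequence one-letter protein sequence.
#' @return numeric(1), Da.
#' @examples
#' molecularWeight("G")  # 75.07
#' @export
molecularWeight <- function(sequence = asynSequence()) {
  aa <- check_sequence(sequence)
  sum(AA_MASS[aa]) + WATER_MASS
}

#' Molar extinction coefficient at 280 nm
#'
#' \code{5500 * nTrp + 1490 * nTyr + 125 * nCystine}; cystines (oxidized
#' disulfides) default to 0 for a reduced protein. A zero coefficient
#' (no aromatic residues) raises a warning because A280 quantification is
#' then impossible.
#'
#' @param sequence one-letter protein sequence.
#' @param nCystine number of disulfide bonds.
#' @return numeric(1), 1/(M cm).
#' @examples
#' extinctionCoefficient(asynSequence())  # 5960
#' @export
extinctionCoefficient <- function(sequence = asynSequence(),
                                  nCystine = 0) {
  aa <- check_sequence(sequence)
  eps <- 5500 * sum(aa == "W") + 1490 * sum(aa == "Y") + 125 * nCystine
  if (eps == 0)
    warning("no aromatic residues: A280 quantification is impossible")
  eps
}

#' Loading-control normalization of blot lanes
#'
#' Scales each lane's specific-band density by the grand mean of the
#' per-lane loading means divided by that lane's loading mean (the
#' average of its three nonspecific bands). Correction factors deviating
#' from 1 by more than 0.25 are flagged.
#'
#' @param table a \linkS4class{DensitometryTable}.
#' @return A \linkS4class{DensitometryTable} whose lanes gain columns
#'   \code{loading_factor} (lane loading mean / grand mean) and
#'   \code{loading_flagged}.
#' @export
normalizeLoading <- function(table) {
  d <- laneData(table)
  loads <- as.matrix(d[, c("load1", "load2", "load3")])
  if (any(loads <= 0)) stop("zero or negative loading density")
  lane_mean <- rowMeans(loads)
  grand <- mean(lane_mean)
  factor <- lane_mean / grand
  d$band_density <- d$band_density / factor
  d$loading_factor <- factor
  d$loading_flagged <- abs(factor - 1) > 0.25
  DensitometryTable(d)
}

#' Fit the band-density calibration curve
#'
#' Ordinary least-squares line of band density versus standard
#' concentration (free intercept by default; set
#' \code{throughOrigin = TRUE} for a zero-background blot).
#'
#' @param table a \linkS4class{DensitometryTable}; only standard lanes
#'   are used.
#' @param throughOrigin force a zero intercept.
#' @return A \linkS4class{CalibrationFit}.
#' @export
fitCalibration <- function(table, throughOrigin = FALSE) {
  d <- laneData(table)
  s <- d[d$role == "standard" & !is.na(d$known_conc), ]
  if (length(unique(s$known_conc)) < 3)
    stop("need >= 3 distinct standard concentrations")
  fit <- if (throughOrigin)
    stats::lm(band_density ~ known_conc + 0, data = s)
  else stats::lm(band_density ~ known_conc, data = s)
  cf <- stats::coef(fit)
  slope <- unname(cf["known_conc"])
  intercept <- if (throughOrigin) 0 else unname(cf["(Intercept)"])
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate calibration: nonpositive slope")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((s$band_density - mean(s$band_density))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  new("CalibrationFit", slope = slope, intercept = intercept,
      rSquared = r2, range = range(s$known_conc))
}

#' Interpolate lysate concentration from the calibration
#'
#' \code{conc = (density - intercept) / slope}, floored at 0 with a flag;
#' densities outside the fitted standard range are flagged as
#' extrapolation.
#'
#' @param fit a \linkS4class{CalibrationFit}.
#' @param bandDensity numeric vector of (loading-normalized) band
#'   densities.
#' @return numeric vector of concentrations (ug/ml) with attributes
#'   \code{"extrapolated"} and \code{"clipped"} (logical vectors).
#' @export
interpolateConcentration <- function(fit, bandDensity) {
  cf <- coef(fit)
  conc <- (bandDensity - cf["intercept"]) / cf["slope"]
  rng <- calibrationRange(fit)
  extrap <- conc < rng[1] | conc > rng[2]
  clipped <- conc < 0
  conc <- pmax(unname(conc), 0)
  attr(conc, "extrapolated") <- unname(extrap)
  attr(conc, "clipped") <- unname(clipped)
  conc
}

#' Amount of protein per cell
#'
#' Divides the protein mass in a lane (lysate concentration times loaded
#' volume) by the number of cell equivalents loaded.
#'
#' @param lysateConc lysate concentration (ug/ml).
#' @param loadedVolumeMl loaded volume per lane (ml).
#' @param cellEquivalents cell equivalents in the lane.
#' @return numeric, pg per cell.
#' @examples
#' perCellAmount(4, 0.025, 1.875e5)  # 0.533 pg/cell
#' @export
perCellAmount <- function(lysateConc, loadedVolumeMl, cellEquivalents) {
  if (any(loadedVolumeMl <= 0)) stop("loaded volume must be positive")
  if (any(cellEquivalents <= 0)) stop("cell equivalents must be positive")
  lysateConc * loadedVolumeMl * 1e6 / cellEquivalents
}

#' Intracellular concentration from per-cell amount
#'
#' Converts a per-cell protein amount to a volumetric mass concentration
#' (pg/um^3 is numerically g/ml, reported as ug/ml) and, via the
#' sequence-derived molecular weight, to a molar concentration. The
#' default cell volume is 2627 um^3 (mean RBL-2H3 cell volume).
#'
#' @param amountPgPerCell protein amount (pg/cell).
#' @param cellVolumeUm3 mean cell volume (um^3).
#' @param sequence protein sequence for the molar conversion.
#' @return list(ugPerMl, uM, uMRounded).
#' @examples
#' # 130 ug/ml of alpha-synuclein is 9 uM
#' cellularConcentration(130e-6 * 2627)$uMRounded
#' @export
cellularConcentration <- function(amountPgPerCell, cellVolumeUm3 = 2627,
                                  sequence = asynSequence()) {
  if (cellVolumeUm3 <= 0) stop("cell volume must be positive")
  check_sequence(sequence)
  ug_per_ml <- amountPgPerCell / cellVolumeUm3 * 1e6
  um <- ug_per_ml * 1000 / molecularWeight(sequence)
  list(ugPerMl = ug_per_ml, uM = um, uMRounded = round(um))
}

#' Full densitometry-to-concentration chain for unknown lanes
#'
#' Convenience wrapper: loading normalization, calibration fit on the
#' standards, interpolation of each unknown lane, per-cell amount and
#' intracellular concentration.
#'
#' @param table a \linkS4class{DensitometryTable}.
#' @param cellVolumeUm3 mean cell volume (um^3).
#' @param sequence protein sequence.
#' @param normalize apply loading normalization first.
#' @return data.frame, one row per unknown lane: lane, lysate_conc_ug_ml,
#'   pg_per_cell, cellular_ug_ml, cellular_uM.
#' @export
blotConcentrationChain <- function(table, cellVolumeUm3 = 2627,
                                   sequence = asynSequence(),
                                   normalize = TRUE) {
  if (normalize) table <- normalizeLoading(table)
  fit <- fitCalibration(table)
  d <- laneData(table)
  u <- d[d$role == "unknown", ]
  conc <- as.numeric(interpolateConcentration(fit, u$band_density))
  pg <- perCellAmount(conc, u$loaded_volume_ml, u$cell_equivalents)
  cc <- cellularConcentration(pg, cellVolumeUm3, sequence)
  data.frame(lane = u$lane, lysate_conc_ug_ml = conc, pg_per_cell = pg,
             cellular_ug_ml = cc$ugPerMl, cellular_uM = cc$uM)
}
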