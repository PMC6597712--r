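#' Random-coil carbon shift reference table
#'
#' Loads the packaged random-coil CA/CB chemical-shift table (one row per
#' amino acid, ppm) with optional nearest-neighbor and temperature
#' correction columns defaulting to 0. The packaged file contains
#' representative literature-style random-coil values; supply your own
#' table via \code{path} to use a specific published coefficient set.
#'
#' @param path CSV file with columns aa, CA, CB and optionally
#'   neighborCA, neighborCB, tempCoefCA, tempCoefCB (ppm/K).
#' @return data.frame covering all 20 canonical residues.
#' @export
randomCoilTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "random_coil_shifts_synthetic.csv",
                        package = "asynquant", mustWork = TRUE)
  rc <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("neighborCA", "neighborCB", "tempCoefCA", "tempCoefCB"))
    if (!col %in% names(rc)) rc[[col]] <- 0
  if (!all(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]] %in% rc$aa))
    stop("random-coil table must cover all 20 residues")
  rc
}

random_coil_values <- function() randomCoilTable()

join_residues <- function(a, b, cols) {
  da <- residueData(a)
  db <- residueData(b)
  common <- intersect(da$residue, db$residue)
  m <- merge(da[da$residue %in% common, c("residue", "aa", cols)],
             db[db$residue %in% common, c("residue", cols)],
             by = "residue", suffixes = c(".a", ".b"))
  m[order(m$residue), ]
}

#' Amide chemical shift deviation profile
#'
#' Weighted amide 1H/15N chemical-shift difference between a mutant (or
#' perturbed-state) table and a reference table:
#' \code{sqrt(0.5 * (dHN^2 + dN^2 / 25))} per residue, with the nitrogen
#' difference down-weighted by its larger shift range. Residues missing an
#' amide entry in either table (e.g. prolines) are skipped. The default
#' residue range 1-102 covers the membrane-interacting N-terminal region.
#'
#' @param mut,wt \linkS4class{ResidueTable} objects sharing numbering,
#'   with H and N columns.
#' @param residueRange numeric(2) inclusive residue range.
#' @return A \linkS4class{ResidueProfile} (ppm).
#' @examples
#' g <- genShiftTables(perturbSite = 70)
#' p <- amideCSD(g$mut, g$wt)
#' @export
amideCSD <- function(mut, wt, residueRange = c(1, 102)) {
  m <- join_residues(mut, wt, c("H", "N"))
  m <- m[m$residue >= residueRange[1] & m$residue <= residueRange[2], ]
  ok <- stats::complete.cases(m[, c("H.a", "H.b", "N.a", "N.b")])
  m <- m[ok, ]
  if (nrow(m) == 0) stop("no common residues with amide shifts")
  csd <- sqrt(0.5 * ((m$H.a - m$H.b)^2 + (m$N.a - m$N.b)^2 / 25))
  new("ResidueProfile", residue = m$residue, value = csd,
      quantity = "amide_csd_ppm")
}

#' Secondary carbon chemical shift profile
#'
#' Difference between the observed CA or CB shift and the sequence- and
#' temperature-corrected random-coil shift. Positive CA values indicate
#' helical structure.
#'
#' @param table a \linkS4class{ResidueTable} with the requested nucleus.
#' @param rc random-coil table from \code{\link{randomCoilTable}}.
#' @param temperature sample temperature (K); the correction is
#'   \code{tempCoef * (temperature - 298)}.
#' @param nucleus "CA" or "CB".
#' @return A \linkS4class{ResidueProfile} (ppm).
#' @export
secondaryShift <- function(table, rc = randomCoilTable(),
                           temperature = 298, nucleus = c("CA", "CB")) {
  nucleus <- match.arg(nucleus)
  d <- residueData(table)
  if (!nucleus %in% names(d) || all(is.na(d[[nucleus]])))
    stop("no ", nucleus, " shifts in table")
  d <- d[!is.na(d[[nucleus]]), ]
  miss <- setdiff(unique(d$aa), rc$aa)
  if (length(miss))
    stop("residue type(s) absent from the random-coil table: ",
         paste(miss, collapse = ", "))
  j <- match(d$aa, rc$aa)
  coil <- rc[[nucleus]][j] + rc[[paste0("neighbor", nucleus)]][j] +
    rc[[paste0("tempCoef", nucleus)]][j] * (temperature - 298)
  keep <- !is.na(coil)
  if (!any(keep)) stop("no residues with random-coil ", nucleus, " values")
  new("ResidueProfile", residue = d$residue[keep],
      value = d[[nucleus]][keep] - coil[keep],
      quantity = paste0("secondary_", nucleus, "_ppm"))
}

#' Re-reference the carbon dimension of a mutant table
#'
#' Estimates the carbon referencing offset between a mutant and reference
#' spectrum as the signed mean difference \code{mean(wt - mut)} over CA
#' and CB shifts in a C-terminal window unaffected by the mutation
#' (default residues 111-130), and applies it to all carbon columns of the
#' mutant table. Amide columns are untouched; the post-correction mean
#' difference over the window is zero to rounding.
#'
#' @param mut,wt \linkS4class{ResidueTable} objects.
#' @param window numeric(2) inclusive residue window used for the fit.
#' @param minResidues minimum number of carbon-bearing residues required.
#' @return list(offset = ppm, corrected = the offset-corrected mutant
#'   \linkS4class{ResidueTable}).
#' @examples
#' g <- genShiftTables(carbonOffset = 0.3)
#' rereferenceCarbon(g$mut, g$wt)$offset  # ~ -0.3
#' @export
rereferenceCarbon <- function(mut, wt, window = c(111, 130),
                              minResidues = 5) {
  m <- join_residues(mut, wt, c("CA", "CB"))
  m <- m[m$residue >= window[1] & m$residue <= window[2], ]
  diffs <- c(m$CA.b - m$CA.a, m$CB.b - m$CB.a)
  diffs <- diffs[!is.na(diffs)]
  n_res <- sum(!is.na(m$CA.a - m$CA.b) | !is.na(m$CB.a - m$CB.b))
  if (n_res < minResidues)
    stop("insufficient overlap: ", n_res,
         " carbon-bearing residues in the window (need >= ", minResidues, ")")
  offset <- mean(diffs)
  d <- residueData(mut)
  for (col in intersect(c("CA", "CB"), names(d)))
    d[[col]] <- d[[col]] + offset
  list(offset = offset,
       corrected = ResidueTable(d, sequence = residueSequence(mut)))
}

#' Lipid/free peak-intensity ratio profile
#'
#' Per-residue ratio of peak intensity with lipid vesicles present to the
#' matched lipid-free intensity: a measure of the fraction of the protein
#' population in which that residue is not bound to the vesicle surface
#' (bound residues broaden beyond detection). Residues whose free
#' intensity is at or below \code{floor} are excluded and listed; ratios
#' above 1.1 are flagged.
#'
#' @param lipid,free \linkS4class{ResidueTable} objects with intensity
#'   columns.
#' @param floor minimum usable free intensity (a.u.).
#' @return A \linkS4class{ResidueProfile} (unitless), with excluded
#'   residues in the \code{excluded} slot.
#' @export
intensityRatioProfile <- function(lipid, free, floor = 0) {
  m <- join_residues(lipid, free, "intensity")
  names(m)[match(c("intensity.a", "intensity.b"), names(m))] <-
    c("lipid", "free")
  m <- m[!is.na(m$lipid) & !is.na(m$free), ]
  excl <- m$residue[m$free <= floor]
  m <- m[m$free > floor, ]
  if (nrow(m) == 0) stop("all residues excluded by the intensity floor")
  ratio <- m$lipid / m$free
  fl <- if (any(ratio > 1.1)) "ratio_over_1.1" else character()
  new("ResidueProfile", residue = m$residue, value = ratio,
      quantity = "intensity_ratio", excluded = as.integer(excl),
      flags = fl)
}

#' Fit the membrane-release boundary of an intensity-ratio profile
#'
#' Fits a four-parameter logistic to the ratio profile and returns the
#' transition midpoint: the residue at which the protein releases from
#' the membrane surface (e.g. the mutation site in a V70P-like profile).
#'
#' @param profile a \linkS4class{ResidueProfile} from
#'   \code{\link{intensityRatioProfile}}.
#' @return list(midpoint, width, low, high) of the fitted logistic.
#' @export
fitBindingBoundary <- function(profile) {
  df <- as.data.frame(profile)
  if (diff(range(df$value)) < 1e-6)
    stop("profile is flat; no transition to fit")
  start <- list(low = min(df$value), high = max(df$value),
                mid = df$residue[which.min(abs(df$value -
                  (min(df$value) + max(df$value)) / 2))],
                width = 2)
  fit <- minpack.lm::nlsLM(
    value ~ low + (high - low) / (1 + exp(-(residue - mid) / width)),
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(midpoint = unname(cf["mid"]), width = unname(cf["width"]),
       low = unname(cf["low"]), high = unname(cf["high"]))
}

#' Summarize a residue profile over named regions
#'
#' Mean and SD of the profile over named residue ranges, e.g. the helix-1
#' / helix-2 / C-terminal regions of membrane-bound alpha-synuclein. The
#' default boundaries (helix-1 = 3-37, helix-2 = 45-92, C-terminal =
#' 103-140) are configurable conventions.
#'
#' @param profile a \linkS4class{ResidueProfile}.
#' @param regions named list of numeric(2) inclusive residue ranges.
#' @return data.frame with columns region, from, to, n, mean, sd.
#' @export
regionSummary <- function(profile,
                          regions = list(helix1 = c(3, 37),
                                         helix2 = c(45, 92),
                                         cterm = c(103, 140))) {
  df <- as.data.frame(profile)
  out <- lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    v <- df$value[df$residue >= r[1] & df$residue <= r[2]]
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("empty region: ", nm)
    data.frame(region = nm, from = r[1], to = r[2], n = length(v),
               mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  do.call(rbind, out)
}
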