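#' Read and write traces as CSV
#'
#' Traces are stored as headered CSV with columns \code{time_s} and
#' \code{value}; epoch annotations travel as \code{#} comment lines
#' (\code{# t_stim=20}) at the top of the file.
#'
#' @param trace a \linkS4class{TimeSeriesTrace}.
#' @param path file path.
#' @return \code{readTrace} returns a \linkS4class{TimeSeriesTrace};
#'   \code{writeTrace} returns \code{path} invisibly.
#' @export
writeTrace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ann <- c(t_stim = stimTime(trace), t_nh4cl = nh4clTime(trace),
           t_baf = bafTime(trace))
  writeLines(sprintf("# id=%s", traceId(trace)), con)
  for (nm in names(ann)[!is.na(ann)])
    writeLines(sprintf("# %s=%g", nm, ann[[nm]]), con)
  utils::write.csv(data.frame(time_s = times(trace),
                              value = values(trace)),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_ann <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(paste0("^# ", key, "="), "", ln[1]))
    else NA_real_
  }
  id_ln <- grep("^# id=", hdr, value = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  TimeSeriesTrace(df$time_s, df$value, tStim = get_ann("t_stim"),
                  tNH4Cl = get_ann("t_nh4cl"), tBaf = get_ann("t_baf"),
                  id = if (length(id_ln)) sub("^# id=", "", id_ln[1])
                       else "trace")
}

#' Read and write residue tables as CSV
#'
#' Headered CSV with columns residue, aa and any of H, N, CA, CB,
#' intensity.
#'
#' @param table a \linkS4class{ResidueTable}.
#' @param path file path.
#' @param sequence optional sequence to attach on read.
#' @return \code{readResidueTable} returns a \linkS4class{ResidueTable}.
#' @export
writeResidueTable <- function(table, path) {
  utils::write.csv(residueData(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResidueTable
#' @export
readResidueTable <- function(path, sequence = "") {
  ResidueTable(utils::read.csv(path, stringsAsFactors = FALSE),
               sequence = sequence)
}

#' Read and write densitometry tables as CSV
#'
#' @param table a \linkS4class{DensitometryTable}.
#' @param path file path.
#' @return \code{readDensitometryTable} returns a
#'   \linkS4class{DensitometryTable}.
#' @export
writeDensitometryTable <- function(table, path) {
  utils::write.csv(laneData(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDensitometryTable
#' @export
readDensitometryTable <- function(path) {
  DensitometryTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write and read event lists as CSV
#'
#' @param events an \linkS4class{EventList}.
#' @param path file path.
#' @return \code{readEventList} returns an \linkS4class{EventList}.
#' @export
writeEventList <- function(events, path) {
  utils::write.csv(events(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventList
#' @export
readEventList <- function(path) {
  EventList(utils::read.csv(path, stringsAsFactors = FALSE))
}

TIFF_MAX <- 65535

# acquisition metadata travels in a small key=value text sidecar next to
# the TIFF (this tiff build does not round-trip description tags)
write_meta <- function(path, ...) {
  kv <- c(...)
  writeLines(sprintf("%s=%g", names(kv), kv), paste0(path, ".meta"))
}

read_meta <- function(path, key, default) {
  meta <- paste0(path, ".meta")
  if (!file.exists(meta)) return(default)
  ln <- grep(paste0("^", key, "="), readLines(meta), value = TRUE)
  if (length(ln)) as.numeric(sub(paste0("^", key, "="), "", ln[1]))
  else default
}

#' Write and read TIRF movies as multi-page 16-bit TIFF
#'
#' Intensities are stored as 16-bit samples; values must lie in
#' [0, 65535] and are rounded to integers on write. The frame interval
#' and pixel size travel in a \code{<path>.meta} text sidecar.
#'
#' @param movie a \linkS4class{TirfMovie}.
#' @param path file path.
#' @return \code{readTirfMovie} returns a \linkS4class{TirfMovie}.
#' @export
writeTirfMovie <- function(movie, path) {
  a <- frames(movie)
  if (min(a) < 0 || max(a) > TIFF_MAX)
    stop("intensities must lie in [0, 65535] for 16-bit TIFF")
  pages <- lapply(seq_len(dim(a)[1]),
                  function(f) round(a[f, , ]) / TIFF_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  write_meta(path, frame_interval_s = frameInterval(movie),
             pixel_size_nm = pixelSize(movie))
  invisible(path)
}

#' @rdname writeTirfMovie
#' @export
readTirfMovie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(0, c(length(pages), dim(pages[[1]])))
  for (f in seq_along(pages)) a[f, , ] <- round(pages[[f]] * TIFF_MAX)
  TirfMovie(a, frameInterval = read_meta(path, "frame_interval_s", 1),
            pixelSize = read_meta(path, "pixel_size_nm", 100))
}

#' Write and read masked image pairs as multi-page 16-bit TIFF
#'
#' Three pages: channel R, channel G and the cell mask (0/1). Intensities
#' must lie in [0, 65535] and are rounded on write.
#'
#' @param img a \linkS4class{MaskedImagePair}.
#' @param path file path.
#' @return \code{readImagePair} returns a \linkS4class{MaskedImagePair}.
#' @export
writeImagePair <- function(img, path) {
  chs <- list(channelR(img), channelG(img))
  if (min(sapply(chs, min)) < 0 || max(sapply(chs, max)) > TIFF_MAX)
    stop("intensities must lie in [0, 65535] for 16-bit TIFF")
  pages <- c(lapply(chs, function(m) round(m) / TIFF_MAX),
             list(cellMask(img) * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  write_meta(path, pixel_size_nm = pixelSize(img))
  invisible(path)
}

#' @rdname writeImagePair
#' @export
readImagePair <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3) stop("expected 3 pages (R, G, mask)")
  MaskedImagePair(channelR = round(pages[[1]] * TIFF_MAX),
                  channelG = round(pages[[2]] * TIFF_MAX),
                  cellMask = round(pages[[3]] * TIFF_MAX) > 0,
                  pixelSize = read_meta(path, "pixel_size_nm", 100))
}
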