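## Multi-page TIFF, CSV track-table and JSON configuration plumbing.

#' Read / write multi-page TIFF stacks
#'
#' Volumes and stacks are stored as one 32-bit page per plane, page index
#' along the third axis. TIFF samples live on a normalized [0, 1] scale
#' (2^32 levels); data outside that range are rescaled linearly on write
#' and the original range is recorded in a \code{<path>.range.json}
#' sidecar, which \code{readTiffArray} uses to restore the values (relative
#' quantization error ~2e-10). Data already inside [0, 1] are stored as-is
#' with no sidecar.
#'
#' @param path file path.
#' @return \code{readTiffArray}: a 3D array (x, y, plane); a single-page
#'   file yields a third extent of 1. Pixel rows of each TIFF page map to
#'   the first (x) axis.
#' @export
readTiffArray <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels
    p
  })
  arr <- simplify2array(pages)
  side <- paste0(path, ".range.json")
  if (file.exists(side)) {
    rng <- jsonlite::read_json(side, simplifyVector = TRUE)
    arr <- arr * (rng$hi - rng$lo) + rng$lo
  }
  arr
}

#' @param arr 3D (or 2D) numeric array to write.
#' @rdname readTiffArray
#' @export
writeTiffArray <- function(arr, path) {
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  side <- paste0(path, ".range.json")
  lo <- min(arr); hi <- max(arr)
  if (lo < 0 || hi > 1) {
    if (hi == lo) hi <- lo + 1
    jsonlite::write_json(list(lo = lo, hi = hi), side, auto_unbox = TRUE,
                         digits = NA)
    arr <- (arr - lo) / (hi - lo)
  } else if (file.exists(side)) {
    unlink(side)                       # stale sidecar from a previous write
  }
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read an oblique stack plus geometry
#'
#' @param path TIFF path.
#' @param geometry a \code{\link{ScanGeometry}}, or NULL to read it from the
#'   JSON sidecar \code{<path>.json} written by \code{writeObliqueStack}.
#' @return an \code{\link{ObliqueStack}}.
#' @export
readObliqueStack <- function(path, geometry = NULL) {
  if (is.null(geometry)) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("readObliqueStack: no geometry given and no sidecar at ", side)
    geometry <- geometryFromJson(side)
  }
  ObliqueStack(readTiffArray(path), geometry)
}

#' @param stack an \code{\link{ObliqueStack}}.
#' @rdname readObliqueStack
#' @export
writeObliqueStack <- function(stack, path) {
  writeTiffArray(stack@frames, path)
  geometryToJson(stack@geometry, paste0(path, ".json"))
  invisible(path)
}

#' Scan geometry as JSON
#'
#' @param geometry a \code{\link{ScanGeometry}}.
#' @param path JSON file path.
#' @export
geometryToJson <- function(geometry, path) {
  jsonlite::write_json(list(theta = geometry@theta, ystep = geometry@ystep,
                            pixel_size = geometry@pixelSize,
                            fill = geometry@fillValue),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geometryToJson
#' @export
geometryFromJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("theta", "ystep", "pixel_size"))
    if (is.null(j[[f]]))
      stop("geometryFromJson: field '", f, "' missing in ", path)
  ScanGeometry(j$theta, j$ystep, j$pixel_size, j$fill %||% 0)
}

#' Read a single-particle track table
#'
#' Accepts either the native minimal schema (columns \code{track},
#' \code{frame}, \code{x}, \code{y}) or TrackMate-style exports
#' (\code{TRACK_ID}, \code{FRAME}, \code{POSITION_X}, \code{POSITION_Y};
#' the non-numeric secondary header rows TrackMate emits are skipped).
#' Positions are expected in um.
#'
#' @param path CSV path.
#' @param dt frame interval in seconds.
#' @return a \code{\link{TrackSet}}.
#' @export
readTrackTable <- function(path, dt) {
  df <- read.csv(path, check.names = TRUE)
  map <- c(track = "TRACK_ID", frame = "FRAME", x = "POSITION_X",
           y = "POSITION_Y")
  if (all(map %in% names(df))) {
    df <- df[, map]
    names(df) <- names(map)
  } else if (!all(c("track", "frame", "x", "y") %in% names(df))) {
    stop("readTrackTable: ", path, " has neither the native columns ",
         "(track, frame, x, y) nor TrackMate columns (",
         paste(map, collapse = ", "), ")")
  }
  df <- df[c("track", "frame", "x", "y")]
  for (cn in names(df)) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  bad <- !stats::complete.cases(df)
  if (any(bad)) {
    df <- df[!bad, , drop = FALSE]   # TrackMate unit/label header rows
  }
  if (!nrow(df)) stop("readTrackTable: no numeric rows in ", path)
  TrackSet(df, dt = dt)
}

#' @param trackSet a \code{\link{TrackSet}}.
#' @rdname readTrackTable
#' @export
writeTrackTable <- function(trackSet, path) {
  write.csv(trackSet@tracks, path, row.names = FALSE)
  invisible(path)
}
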