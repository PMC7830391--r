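# File interchange: MetaImage volumes, JSON configs, CSV tables.

#' Write a volume as MetaImage (MHD + RAW)
#'
#' Plain ITK MetaImage: a text `.mhd` header next to a little-endian
#' float64 `.raw` payload.  Works for 2D and 3D arrays; voxel spacing is
#' recorded when a geometry is supplied.
#'
#' @param vol numeric array (matrix or 3D array).
#' @param path output path ending in `.mhd`.
#' @param spacing voxel spacing in mm per axis (default 1).
#' @return `path`, invisibly.
#' @export
write_mhd <- function(vol, path, spacing = NULL) {
  d <- dim(vol)
  if (is.null(d)) d <- length(vol)
  if (is.null(spacing)) spacing <- rep(1, length(d))
  raw_path <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
  if (identical(raw_path, path)) stop("'path' must end in .mhd")
  hdr <- c("ObjectType = Image",
           sprintf("NDims = %d", length(d)),
           sprintf("DimSize = %s", paste(d, collapse = " ")),
           sprintf("ElementSpacing = %s",
                   paste(signif(spacing, 12), collapse = " ")),
           "ElementType = MET_DOUBLE",
           "ElementByteOrderMSB = False",
           sprintf("ElementDataFile = %s", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage volume written by [write_mhd()]
#'
#' Supports uncompressed MET_DOUBLE / MET_FLOAT payloads.
#'
#' @param path path to the `.mhd` header.
#' @return numeric array with a `spacing` attribute.
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  field <- function(key) {
    hit <- grep(sprintf("^%s\\s*=", key), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub("^[^=]*=", "", hit[1]))
  }
  d <- as.integer(strsplit(field("DimSize"), "\\s+")[[1]])
  type <- field("ElementType")
  size <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 stop("unsupported ElementType: ", type))
  msb <- identical(tolower(field("ElementByteOrderMSB")), "true")
  raw_path <- file.path(dirname(path), field("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = prod(d), size = size,
               endian = if (msb) "big" else "little")
  out <- array(v, dim = d)
  sp <- field("ElementSpacing")
  attr(out, "spacing") <- if (is.null(sp)) rep(1, length(d))
                          else as.numeric(strsplit(sp, "\\s+")[[1]])
  out
}

#' Serialise a scan geometry to JSON
#'
#' @param geom a [scan_geometry()].
#' @param path output path; `NULL` returns the JSON string.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_geometry_json <- function(geom, path = NULL) {
  stopifnot(inherits(geom, "scan_geometry"))
  js <- jsonlite::toJSON(unclass(geom), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a scan geometry from JSON
#'
#' Accepts either an explicit `angles` array or a
#' `{span_degrees, n_views, start}` object in its place.
#'
#' @param path path to a JSON file from [write_geometry_json()].
#' @return a [scan_geometry()].
#' @export
read_geometry_json <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  angles <- cfg$angles
  if (is.list(angles) && !is.null(angles$n_views))
    angles <- make_angles(angles$span_degrees, angles$n_views,
                          if (is.null(angles$start)) 0 else angles$start)
  scan_geometry(beam_mode = cfg$beam_mode, angles = angles,
                volume_shape = cfg$volume_shape,
                voxel_size = cfg$voxel_size,
                detector_pixel_counts = cfg$detector_pixel_counts,
                detector_pixel_pitch = cfg$detector_pixel_pitch,
                source_to_origin = if (is.null(cfg$source_to_origin) ||
                                       is.na(cfg$source_to_origin)) NULL
                                   else cfg$source_to_origin,
                source_to_detector = if (is.null(cfg$source_to_detector) ||
                                         is.na(cfg$source_to_detector)) NULL
                                     else cfg$source_to_detector)
}

#' Write a per-iteration reconstruction trace as CSV
#'
#' @param result an [awpcsd()] result.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(result, path) {
  stopifnot(inherits(result, "awpcsd_result"))
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}

#' Write tuning results as JSON + CSV score matrix
#'
#' Emits `<stem>.json` with the best configuration and diagnostics and
#' `<stem>_scores.csv` with the accumulated per-configuration scores
#' (rows = first search dimension, columns = second).
#'
#' @param result an [aco_tune_result][aco_tune()].
#' @param stem output path stem (no extension).
#' @export
write_tune_result <- function(result, stem) {
  stopifnot(inherits(result, "aco_tune_result"))
  meta <- list(best_config = result$best_config,
               stop_reason = result$stop_reason,
               n_iterations = result$n_iterations,
               n_generations = result$n_generations)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             paste0(stem, ".json"))
  utils::write.csv(as.data.frame(result$accumulated_scores),
                   paste0(stem, "_scores.csv"))
  invisible(stem)
}
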