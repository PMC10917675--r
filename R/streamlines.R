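#' Streamline sets in world millimetre space
#'
#' A `streamline_set` holds an ordered collection of polylines, each an
#' n x 3 matrix of world-mm points — the "connectome" being filtered. All
#' package geometry runs in world mm; the on-disk voxel-space conventions of
#' TRK files are resolved at load time.
#'
#' @param streamlines list of n x 3 numeric matrices, each with >= 2 rows and
#'   finite coordinates.
#' @param space_tag free-text tag naming the coordinate space (e.g. a template
#'   identifier).
#' @return object of class `streamline_set` with fields `streamlines`,
#'   `space_tag`.
#' @export
streamline_set <- function(streamlines, space_tag = "world-mm") {
  stopifnot(is.list(streamlines))
  streamlines <- lapply(seq_along(streamlines), function(i) {
    p <- streamlines[[i]]
    if (is.null(dim(p))) p <- matrix(p, ncol = 3L, byrow = TRUE)
    storage.mode(p) <- "double"
    if (ncol(p) != 3L || nrow(p) < 2L)
      stop("streamline ", i, " must be an n x 3 matrix with n >= 2")
    if (!all(is.finite(p)))
      stop("streamline ", i, " contains non-finite coordinates")
    p
  })
  structure(list(streamlines = streamlines, space_tag = space_tag),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, 0L)
  cat(sprintf("<streamline_set> %d streamlines, %d points total, space=%s\n",
              length(np), sum(np), x$space_tag))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Subset a streamline set by index
#' @param set a [streamline_set()].
#' @param idx integer or logical index into the streamlines.
#' @return a [streamline_set()] with the selected streamlines.
#' @export
subset_streamlines <- function(set, idx) {
  streamline_set(set$streamlines[idx], set$space_tag)
}

#' Select one hemisphere's streamlines
#'
#' Splits by the sign of each streamline's mean world x coordinate
#' (x < 0 is left of the template midline).
#'
#' @param set a [streamline_set()].
#' @param hemisphere `"left"` or `"right"`.
#' @return a [streamline_set()].
#' @export
hemisphere_streamlines <- function(set, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  side <- vapply(set$streamlines, function(p) mean(p[, 1]), 0)
  subset_streamlines(set, if (hemisphere == "left") side < 0 else side >= 0)
}

#' Read streamlines from TRK or TCK files
#'
#' Dispatches on the file extension. Points are returned in world mm
#' regardless of the on-disk convention: TCK stores scanner/world mm
#' directly; TRK stores voxel-mm coordinates which are converted through the
#' header's voxel-to-RAS matrix (an all-zero matrix — an unspecified space —
#' is an error, never a silent guess).
#'
#' @param path path to a `.trk` or `.tck` file.
#' @return a [streamline_set()].
#' @export
load_streamlines <- function(path) {
  if (!file.exists(path)) stop("no such streamline file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = read_trk(path),
         tck = read_tck(path),
         stop("unknown streamline format '.", ext, "' (expect .trk or .tck)"))
}

#' Write streamlines to TRK or TCK files
#'
#' @param set a [streamline_set()] in world mm.
#' @param path output path ending in `.trk` or `.tck`.
#' @param affine for TRK output, the voxel-to-world affine and grid to declare
#'   in the header (identity spacing by default; TRK requires one).
#' @param dim for TRK output, the grid dimensions to declare.
#' @return `path`, invisibly.
#' @export
save_streamlines <- function(set, path, affine = diag(4), dim = c(1L, 1L, 1L)) {
  stopifnot(inherits(set, "streamline_set"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = write_trk(set, path, affine, dim),
         tck = write_tck(set, path),
         stop("unknown streamline format '.", ext, "' (expect .trk or .tck)"))
  invisible(path)
}

## ---- TRK (TrackVis) ------------------------------------------------------
## 1000-byte little-endian header; track data as float32. Points on disk are
## in "voxel-mm": continuous voxel index scaled by voxel size, with the voxel
## centre at (index + 0.5) * voxel_size. World mm = M %*% (p / voxel_size - 0.5)
## where M is the header's vox_to_ras matrix.

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6)[1:5])
  if (magic != "TRACK") stop("'", path, "' is not a TRK file")
  dim3 <- readBin(con, "integer", 3, size = 2, endian = "little")
  voxsz <- readBin(con, "double", 3, size = 4, endian = "little")
  origin <- readBin(con, "double", 3, size = 4, endian = "little")
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))           # scalar names
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))           # property names
  vox2ras <- matrix(readBin(con, "double", 16, size = 4, endian = "little"),
                    4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444))           # reserved
  invisible(readBin(con, "raw", 4))             # voxel_order
  invisible(readBin(con, "raw", 4))             # pad2
  invisible(readBin(con, "raw", 24))            # image_orientation_patient
  invisible(readBin(con, "raw", 2))             # pad1
  invisible(readBin(con, "raw", 6))             # invert/swap flags
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000L)
    stop("'", path, "': unsupported TRK header size ", hdr_size)
  if (version >= 2L && all(vox2ras == 0))
    stop("'", path, "': TRK header declares no voxel-to-RAS transform; ",
         "coordinate space is unknown")
  if (version < 2L) vox2ras <- diag(4)          # legacy: voxmm == world
  if (any(voxsz <= 0)) voxsz <- c(1, 1, 1)
  tracks <- list()
  repeat {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(np) == 0L) break
    vals <- readBin(con, "double", np * (3L + n_scalars), size = 4,
                    endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)
    if (n_props > 0)
      invisible(readBin(con, "double", n_props, size = 4, endian = "little"))
    p <- m[, 1:3, drop = FALSE]
    vox <- sweep(p, 2, voxsz, "/") - 0.5
    tracks[[length(tracks) + 1L]] <- voxel_to_world(vox, vox2ras)
  }
  if (n_count > 0 && length(tracks) != n_count)
    warning("TRK '", path, "': header count ", n_count, " != tracks read ",
            length(tracks))
  streamline_set(tracks, space_tag = "world-mm")
}

write_trk <- function(set, path, affine = diag(4), dim = c(1L, 1L, 1L)) {
  affine <- check_affine(affine)
  voxsz <- voxel_sizes(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  # zero-padding to the fixed field width is intentional
  suppressWarnings(writeChar("TRACK", con, nchars = 6, eos = NULL))
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxsz), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")      # origin
  writeBin(0L, con, size = 2, endian = "little")              # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")              # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  suppressWarnings(writeChar("RAS", con, nchars = 4, eos = NULL)) # voxel_order
  writeBin(raw(4), con)                                       # pad2
  writeBin(numeric(6), con, size = 4, endian = "little")      # orientation
  writeBin(raw(2), con)                                       # pad1
  writeBin(raw(6), con)                                       # invert/swap
  writeBin(length(set$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")              # version
  writeBin(1000L, con, size = 4, endian = "little")           # hdr_size
  for (p in set$streamlines) {
    vox <- world_to_voxel(p, affine) + 0.5
    voxmm <- sweep(vox, 2, voxsz, "*")
    writeBin(nrow(p), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

## ---- TCK (MRtrix) --------------------------------------------------------
## Text header terminated by END, then float32 triplets in scanner/world mm;
## streamlines separated by a NaN triplet, file terminated by an Inf triplet.

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!grepl("^mrtrix tracks", first)) stop("'", path, "' is not a TCK file")
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("'", path, "': TCK header missing END")
    if (line == "END") break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) {
      key <- trimws(kv[2]); val <- trimws(kv[3])
      if (key == "file") offset <- as.integer(sub("^\\.\\s+", "", val))
      if (key == "datatype") datatype <- val
    }
  }
  if (is.na(offset)) stop("'", path, "': TCK header has no file offset")
  if (!datatype %in% c("Float32LE", "Float32BE"))
    stop("'", path, "': unsupported TCK datatype ", datatype)
  endian <- if (datatype == "Float32LE") "little" else "big"
  seek(con, offset)
  vals <- readBin(con, "double", n = file.size(path), size = 4, endian = endian)
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  tracks <- list()
  start <- 1L
  for (r in seq_len(nrow(m))) {
    if (!all(is.finite(m[r, ]))) {
      if (r > start) tracks[[length(tracks) + 1L]] <- m[start:(r - 1L), ,
                                                        drop = FALSE]
      start <- r + 1L
      if (all(is.infinite(m[r, ]))) break
    }
  }
  streamline_set(tracks, space_tag = "world-mm")
}

write_tck <- function(set, path) {
  n <- length(set$streamlines)
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", n),
           "file: . OFFSET",
           "END")
  # two-pass offset: header length once OFFSET is substituted
  guess <- sum(nchar(hdr)) + length(hdr)          # with newlines
  offset <- guess
  repeat {
    hdr2 <- sub("OFFSET", as.character(offset), hdr, fixed = TRUE)
    len <- sum(nchar(hdr2)) + length(hdr2)
    if (len == offset) break
    offset <- len
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr2, con, sep = "\n")
  sep <- rep(NaN, 3)
  for (p in set$streamlines) {
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
    writeBin(sep, con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}
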