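# TrackVis .trk streamline file I/O.
#
# The .trk format stores a 1000-byte little-endian header followed by, per
# streamline, an int32 point count and float32 (x, y, z) triples in "voxmm"
# coordinates: continuous voxel index (corner-of-first-voxel origin) times
# voxel size. Internally the package keeps streamlines in world mm, so the
# writer converts through the grid affine and the reader converts back.

trk_header_template <- function(grid_shape, voxel_size, affine, n_count) {
  list(grid_shape = as.integer(grid_shape),
       voxel_size = as.numeric(voxel_size),
       affine = affine, n_count = as.integer(n_count))
}

world_to_voxmm <- function(points, affine, voxel_size) {
  vox <- world_to_voxel(points, affine)            # centers at integers
  sweep(vox + 0.5, 2L, voxel_size, `*`)            # corner-origin voxmm
}

voxmm_to_world <- function(points, affine, voxel_size) {
  vox <- sweep(points, 2L, voxel_size, `/`) - 0.5
  voxel_to_world(vox, affine)
}

#' Write streamlines as TrackVis .trk
#'
#' @param streams a `streamline_set` (world-mm points).
#' @param path output path.
#' @param grid_shape integer length-3 voxel counts of the reference grid.
#' @param affine 4x4 voxel-to-world transform of the reference grid.
#' @return invisibly, `path`.
#' @export
write_trk <- function(streams, path, grid_shape, affine = make_affine(0.4)) {
  stopifnot(inherits(streams, "streamline_set"))
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5L, eos = NULL)
  writeBin(raw(1L), con)                                       # id_string[6]
  writeBin(as.integer(grid_shape), con, size = 2L, endian = "little")   # dim[3]
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")   # voxel_size[3]
  writeBin(rep(0, 3), con, size = 4L, endian = "little")       # origin[3]
  writeBin(0L, con, size = 2L, endian = "little")              # n_scalars
  writeBin(raw(200L), con)                                     # scalar_name
  writeBin(0L, con, size = 2L, endian = "little")              # n_properties
  writeBin(raw(200L), con)                                     # property_name
  writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")  # vox_to_ras, row-major
  writeBin(raw(444L), con)                                     # reserved
  writeChar("RAS", con, nchars = 3L, eos = NULL)               # voxel_order[4]
  writeBin(raw(1L), con)
  writeBin(raw(4L), con)                                       # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4L, endian = "little")  # image_orientation_patient
  writeBin(raw(2L), con)                                       # pad1
  writeBin(raw(6L), con)                                       # invert/swap flags
  writeBin(length(streams$streamlines), con, size = 4L, endian = "little")  # n_count
  writeBin(2L, con, size = 4L, endian = "little")              # version
  writeBin(1000L, con, size = 4L, endian = "little")           # hdr_size
  for (pts in streams$streamlines) {
    vm <- world_to_voxmm(pts, affine, voxel_size)
    writeBin(nrow(vm), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(vm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a TrackVis .trk file
#'
#' @param path input path.
#' @param affine optional 4x4 voxel-to-world transform overriding the
#'   header's `vox_to_ras` (needed for files written by tools that leave it
#'   zeroed).
#' @return an object of class `streamline_set` (world-mm points; the `side`
#'   labels are not stored in .trk and come back as `NA`).
#' @export
read_trk <- function(path, affine = NULL) {
  if (file.size(path) < 1000L) {
    stop_bad("malformed .trk file: header truncated at %d bytes", file.size(path))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readChar(con, 5L, useBytes = TRUE)
  if (!identical(id, "TRACK")) stop_bad("malformed .trk header: id_string is not 'TRACK'")
  readBin(con, "raw", 1L)
  grid_shape <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")    # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  v2r <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) stop_bad("malformed .trk header: hdr_size = %d", hdr_size)
  if (is.null(affine)) {
    if (all(v2r == 0)) stop_bad("malformed .trk header: vox_to_ras is zero; supply `affine`")
    affine <- v2r
  }
  streamlines <- list()
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    vals <- readBin(con, "numeric", npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_props > 0L) readBin(con, "numeric", n_props, size = 4L, endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    streamlines[[length(streamlines) + 1L]] <-
      voxmm_to_world(m, affine, voxel_size)
  }
  if (n_count > 0L && length(streamlines) != n_count) {
    stop_bad("malformed .trk body: header n_count = %d but %d streamlines read",
             n_count, length(streamlines))
  }
  structure(list(streamlines = streamlines,
                 side = rep(NA_character_, length(streamlines)),
                 n_discarded_short = NA_integer_, n_no_start = NA_integer_,
                 counts_by_side = NULL),
            class = "streamline_set")
}
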