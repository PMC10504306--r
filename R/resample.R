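# Grid resampling: trilinear interpolation for signal/scalar volumes,
# nearest-neighbor for label volumes. Stands in for the spatial
# normalization step that brings native-resolution acquisitions onto the
# 0.4 mm isotropic common grid.

#' Resample a volume onto an isotropic target grid
#'
#' The target grid covers the source field of view (voxel-edge to
#' voxel-edge) at `target_voxel` mm isotropic, sharing the source origin
#' corner. Scalar and 4-D multi-volume arrays are interpolated trilinearly;
#' label volumes use nearest-neighbor lookup. When the source already sits
#' on the requested grid the input is returned unchanged.
#'
#' @param volume 3-D or 4-D array.
#' @param source_affine 4x4 voxel-to-world transform of `volume` (must be
#'   invertible).
#' @param target_voxel target isotropic voxel size, mm (default 0.4).
#' @param method `"trilinear"` or `"nearest"`.
#' @return list with `data` (resampled array) and `affine` (target 4x4).
#' @export
resample_to_grid <- function(volume, source_affine, target_voxel = 0.4,
                             method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (abs(det(source_affine)) < 1e-12) stop_bad("singular source affine")
  dims <- dim(volume)
  is4d <- length(dims) == 4L
  grid_shape <- dims[1:3]
  src_vox <- sqrt(colSums(source_affine[1:3, 1:3]^2))
  if (all(abs(src_vox - target_voxel) < 1e-12)) {
    return(list(data = volume, affine = source_affine))
  }
  tgt <- target_grid(grid_shape, source_affine, target_voxel)
  tgt_shape <- tgt$shape
  tgt_affine <- tgt$affine
  tgt_vox <- as.matrix(expand.grid(0:(tgt_shape[1] - 1L), 0:(tgt_shape[2] - 1L),
                                   0:(tgt_shape[3] - 1L)))
  tgt_world <- voxel_to_world(tgt_vox, tgt_affine)
  src_cont <- world_to_voxel(tgt_world, source_affine)
  interp_one <- function(vol3d) {
    if (method == "nearest") {
      vox <- floor(src_cont + 0.5)
      vox[, 1] <- pmin(pmax(vox[, 1], 0), grid_shape[1] - 1L)
      vox[, 2] <- pmin(pmax(vox[, 2], 0), grid_shape[2] - 1L)
      vox[, 3] <- pmin(pmax(vox[, 3], 0), grid_shape[3] - 1L)
      out <- vol3d[voxel_linear_index(vox, grid_shape)]
    } else {
      out <- trilinear(vol3d, src_cont, grid_shape)
    }
    array(out, tgt_shape)
  }
  if (is4d) {
    out <- array(0, c(tgt_shape, dims[4]))
    for (v in seq_len(dims[4])) out[, , , v] <- interp_one(volume[, , , v])
  } else {
    out <- interp_one(volume)
  }
  list(data = out, affine = tgt_affine)
}

#' Target grid covering a source field of view
#'
#' The isotropic grid (voxel-edge to voxel-edge) that [resample_to_grid()]
#' resamples onto, exposed so callers can precompute the common-grid shape
#' and affine of a native-resolution acquisition.
#'
#' @param source_shape integer length-3 voxel counts of the source grid.
#' @param source_affine 4x4 voxel-to-world transform of the source grid.
#' @param target_voxel target isotropic voxel size, mm.
#' @return list with `shape` (integer length-3) and `affine` (4x4).
#' @export
target_grid <- function(source_shape, source_affine, target_voxel = 0.4) {
  corners <- as.matrix(expand.grid(c(-0.5, source_shape[1] - 0.5),
                                   c(-0.5, source_shape[2] - 0.5),
                                   c(-0.5, source_shape[3] - 0.5)))
  world <- voxel_to_world(corners, source_affine)
  lo <- apply(world, 2L, min)
  hi <- apply(world, 2L, max)
  shape <- pmax(1L, as.integer(ceiling((hi - lo) / target_voxel)))
  list(shape = shape, affine = make_affine(target_voxel, origin = lo + target_voxel / 2))
}

# Vectorized trilinear interpolation at continuous 0-based voxel coords;
# coordinates are clamped to the valid cube (edge padding).
trilinear <- function(vol, cont, grid_shape) {
  cx <- pmin(pmax(cont[, 1], 0), grid_shape[1] - 1)
  cy <- pmin(pmax(cont[, 2], 0), grid_shape[2] - 1)
  cz <- pmin(pmax(cont[, 3], 0), grid_shape[3] - 1)
  x0 <- pmax(pmin(floor(cx), grid_shape[1] - 2L), 0); x1 <- x0 + 1
  y0 <- pmax(pmin(floor(cy), grid_shape[2] - 2L), 0); y1 <- y0 + 1
  z0 <- pmax(pmin(floor(cz), grid_shape[3] - 2L), 0); z1 <- z0 + 1
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  idx <- function(i, j, k) voxel_linear_index(cbind(i, j, k), grid_shape)
  vol[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    vol[idx(x1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
    vol[idx(x0, y1, z0)] * (1 - fx) * fy * (1 - fz) +
    vol[idx(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
    vol[idx(x1, y1, z0)] * fx * fy * (1 - fz) +
    vol[idx(x1, y0, z1)] * fx * (1 - fy) * fz +
    vol[idx(x0, y1, z1)] * (1 - fx) * fy * fz +
    vol[idx(x1, y1, z1)] * fx * fy * fz
}
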