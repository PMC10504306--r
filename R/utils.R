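# Shared geometry and RNG helpers.
#
# Conventions used throughout the package:
#  * voxel indices are 0-based, voxel centers sit at integer indices, and a
#    voxel owns the half-open cube [i - 0.5, i + 0.5) along each axis;
#  * world coordinates are millimetres, obtained from voxel indices through a
#    4x4 NIfTI-style affine;
#  * symmetric tensors are stored as 6 components in the order
#    (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).

#' Build a diagonal voxel-to-world affine
#'
#' @param voxel_size numeric length-1 or length-3 voxel edge length, mm.
#' @param origin world coordinate of voxel (0, 0, 0), mm.
#' @return a 4x4 matrix mapping homogeneous 0-based voxel indices to world mm.
#' @export
make_affine <- function(voxel_size, origin = c(0, 0, 0)) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  stopifnot(all(voxel_size > 0), length(origin) == 3L)
  aff <- diag(c(voxel_size, 1))
  aff[1:3, 4] <- origin
  aff
}

#' Convert world-mm points to continuous 0-based voxel coordinates
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param affine 4x4 voxel-to-world transform.
#' @return n x 3 matrix of continuous voxel coordinates.
#' @export
world_to_voxel <- function(points, affine) {
  points <- to_points_matrix(points)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(points) + inv[1:3, 4])
}

#' Convert 0-based voxel coordinates to world mm
#'
#' @param voxels n x 3 matrix of (possibly continuous) voxel coordinates.
#' @param affine 4x4 voxel-to-world transform.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(voxels, affine) {
  voxels <- to_points_matrix(voxels)
  t(affine[1:3, 1:3] %*% t(voxels) + affine[1:3, 4])
}

to_points_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 3L)
  x
}

# Voxel (0-based integer triplet) owning each world point; half-open ownership.
owning_voxel <- function(points, affine) {
  floor(world_to_voxel(points, affine) + 0.5)
}

# TRUE for voxel triplets inside a grid of the given shape.
voxel_in_grid <- function(vox, grid_shape) {
  vox[, 1] >= 0 & vox[, 1] < grid_shape[1] &
    vox[, 2] >= 0 & vox[, 2] < grid_shape[2] &
    vox[, 3] >= 0 & vox[, 3] < grid_shape[3]
}

# 1-based linear index into a column-major array for 0-based voxel triplets.
voxel_linear_index <- function(vox, grid_shape) {
  as.integer(vox[, 1] + grid_shape[1] * (vox[, 2] + grid_shape[2] * vox[, 3])) + 1L
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive per-unit child seeds from a master seed, reproducibly.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)
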