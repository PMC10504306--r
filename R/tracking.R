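# Seed placement and deterministic FACT streamline tractography with the
# protocol thresholds: track while FA > 0.15, stop at turning angles above
# 60 degrees, discard fibers shorter than 2 mm.

#' Tracking parameters
#'
#' Defaults are the nerve-tracking protocol values: FA threshold 0.15,
#' angle threshold 60 degrees, minimum retained fiber length 2 mm, and an
#' integration step of 0.2 mm (half the 0.4 mm common-grid voxel).
#'
#' @param fa_threshold stop when the containing voxel's FA falls below this.
#' @param angle_threshold maximum turning angle between successive steps,
#'   degrees.
#' @param min_length fibers with total path length below this (mm) are
#'   discarded.
#' @param step_size integration step, mm.
#' @param max_steps cap on steps per half-track.
#' @return an object of class `track_params`.
#' @export
track_params <- function(fa_threshold = 0.15, angle_threshold = 60,
                         min_length = 2.0, step_size = 0.2, max_steps = 2000L) {
  stopifnot(fa_threshold > 0, fa_threshold < 1,
            angle_threshold > 0, angle_threshold < 180,
            min_length > 0, step_size > 0, max_steps >= 1)
  structure(list(fa_threshold = fa_threshold, angle_threshold = angle_threshold,
                 min_length = min_length, step_size = step_size,
                 max_steps = as.integer(max_steps)),
            class = "track_params")
}

#' Expand spherical seed regions into seed points
#'
#' Each sphere contributes one seed per voxel whose center lies within
#' `diameter / 2` of the sphere center (density 1); higher densities add
#' uniformly jittered copies inside each seed voxel (seeded RNG).
#'
#' @param centers k x 3 matrix of sphere centers, world mm.
#' @param side character vector of side labels, one per center.
#' @param grid_shape integer length-3 voxel counts.
#' @param affine 4x4 voxel-to-world transform.
#' @param diameter sphere diameter, mm (default 5, the protocol value).
#' @param density seeds per seed voxel.
#' @param seed RNG seed used when `density > 1`.
#' @return an object of class `seed_set`: `points` (n x 3 world mm),
#'   `side` (length n), `diameter`, `centers`.
#' @export
make_seeds <- function(centers, side, grid_shape, affine = make_affine(0.4),
                       diameter = 5, density = 1L, seed = NULL) {
  centers <- to_points_matrix(centers)
  stopifnot(diameter > 0, density >= 1L, length(side) == nrow(centers))
  vox_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  all_pts <- list(); all_side <- list()
  for (k in seq_len(nrow(centers))) {
    ctr <- centers[k, ]
    r <- diameter / 2
    lo <- pmax(floor(world_to_voxel(ctr - r - vox_size, affine) + 0.5), 0)
    hi <- pmin(floor(world_to_voxel(ctr + r + vox_size, affine) + 0.5), grid_shape - 1L)
    if (any(lo > hi)) stop_bad("seed sphere %d lies fully outside the grid", k)
    cand <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    ctrs <- voxel_to_world(cand, affine)
    inside <- rowSums((ctrs - matrix(ctr, nrow(ctrs), 3L, byrow = TRUE))^2) <= r^2
    if (!any(inside)) stop_bad("seed sphere %d contains no voxel center inside the grid", k)
    pts <- ctrs[inside, , drop = FALSE]
    if (density > 1L) {
      extra <- with_seed(seed, {
        reps <- pts[rep(seq_len(nrow(pts)), density - 1L), , drop = FALSE]
        jit <- matrix(stats::runif(length(reps), -0.5, 0.5), ncol = 3L)
        reps + jit %*% diag(vox_size)
      })
      pts <- rbind(pts, extra)
    }
    all_pts[[k]] <- pts
    all_side[[k]] <- rep(side[k], nrow(pts))
  }
  structure(list(points = do.call(rbind, all_pts),
                 side = unlist(all_side),
                 diameter = diameter, centers = centers),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("Seed set: %d points from %d spheres (%g mm diameter)\n",
              nrow(x$points), nrow(x$centers), x$diameter))
  invisible(x)
}

#' Track one streamline from a seed point
#'
#' FACT integration (nearest-voxel principal-eigenvector directions,
#' sign-aligned step to step). The two half-tracks launched along +e1 and
#' -e1 of the seed voxel are concatenated. Returns `NULL` when the seed
#' voxel's FA is below threshold. No length filter is applied here.
#'
#' @param seed_point world-mm coordinate (length 3).
#' @param eigs an `eigen_system`.
#' @param fa FA volume (3-D array).
#' @param params a `track_params`.
#' @param affine 4x4 voxel-to-world transform.
#' @return n x 3 matrix of world-mm points, or `NULL`.
#' @export
track_streamline <- function(seed_point, eigs, fa, params,
                             affine = make_affine(0.4)) {
  res <- track_batch(matrix(seed_point, 1L, 3L), eigs, fa, params, affine)
  if (nrow(res[[1L]]) == 0L) NULL else res[[1L]]
}

track_batch <- function(seed_pts, eigs, fa, params, affine) {
  grid_shape <- dim(fa)
  vox <- world_to_voxel(seed_pts, affine)
  if (any(!voxel_in_grid(floor(vox + 0.5), grid_shape))) {
    stop_bad("seed point outside the grid")
  }
  e1 <- eigs$vectors[, , , , 1L, drop = FALSE]      # c(grid, 3, 1)
  inv <- solve(affine)[1:3, , drop = FALSE]
  track_streamlines_cpp(seed_pts, as.numeric(e1), as.numeric(fa),
                        as.integer(grid_shape), inv,
                        params$fa_threshold, params$angle_threshold,
                        params$step_size, params$max_steps)
}

streamline_length <- function(points) {
  if (is.null(points) || nrow(points) < 2L) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Track from every seed and apply the length filter
#'
#' Runs [track_streamline()] for each seed point and discards streamlines
#' whose total path length is below `params$min_length` (strictly less than;
#' a fiber of exactly the threshold length is retained).
#'
#' @param seeds a `seed_set`.
#' @param eigs an `eigen_system`.
#' @param fa FA volume.
#' @param params a `track_params`.
#' @param affine 4x4 voxel-to-world transform.
#' @return an object of class `streamline_set`: `streamlines` (list of n x 3
#'   matrices), `side` (label per streamline), and QC attributes
#'   `n_discarded_short`, `n_no_start`, `counts_by_side`.
#' @export
track_all <- function(seeds, eigs, fa, params = track_params(),
                      affine = make_affine(0.4)) {
  stopifnot(inherits(seeds, "seed_set"), inherits(params, "track_params"))
  raw <- track_batch(seeds$points, eigs, fa, params, affine)
  lens <- vapply(raw, streamline_length, 0)
  started <- vapply(raw, nrow, 0L) > 0L
  keep <- started & lens >= params$min_length
  sl <- raw[keep]
  side <- seeds$side[keep]
  structure(list(streamlines = sl, side = side,
                 n_discarded_short = sum(started & !keep),
                 n_no_start = sum(!started),
                 counts_by_side = table(factor(side, levels = unique(seeds$side)))),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  lens <- vapply(x$streamlines, streamline_length, 0)
  cat(sprintf("Streamline set: %d fibers (%d short discarded, %d seeds below FA threshold)\n",
              length(x$streamlines), x$n_discarded_short, x$n_no_start))
  if (length(lens)) {
    cat(sprintf("  length %.1f-%.1f mm, median %.1f mm\n",
                min(lens), max(lens), stats::median(lens)))
  }
  invisible(x)
}
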