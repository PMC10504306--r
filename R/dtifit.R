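# Log-linear least-squares diffusion tensor fit, eigendecomposition and the
# four scalar indexes (FA, MD, AD, RD).

#' Fit the diffusion tensor per voxel
#'
#' Ordinary (unweighted) log-linear least squares: for each voxel the model
#' ln S_i = ln s0 - b_i g_i' D g_i is solved for the 7 unknowns
#' (ln s0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) with a single pseudo-inverse shared
#' across voxels. Signals are clamped to a small positive floor
#' (1e-6 x the voxel's mean b = 0 signal) before the log; the number of
#' clamped samples is recorded as a QC counter.
#'
#' @param dwi 4-D signal array `c(grid_shape, n_volumes)`.
#' @param scheme an `acquisition_scheme` with one entry per volume.
#' @param mask optional logical array; voxels outside are zero-filled.
#' @return an object of class `tensor_fit`: `tensors` (4-D, components
#'   xx, yy, zz, xy, xz, yz), `s0` (3-D), `mask`, `n_clamped`.
#' @export
fit_tensor <- function(dwi, scheme, mask = NULL) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  dims <- dim(dwi)
  stopifnot(length(dims) == 4L)
  n_vol <- dims[4]
  if (n_vol != length(scheme$bvals)) {
    stop_bad("dwi has %d volumes but scheme has %d entries", n_vol, length(scheme$bvals))
  }
  if (n_vol < 7L) stop_bad("tensor fit needs at least 7 volumes")
  X <- design_matrix(scheme)
  if (qr(X)$rank < 7L) {
    stop_bad("rank-deficient design: gradient directions are collinear; add non-coplanar directions")
  }
  grid_shape <- dims[1:3]
  n_vox <- prod(grid_shape)
  S <- matrix(dwi, n_vox, n_vol)
  keep <- if (is.null(mask)) rep(TRUE, n_vox) else as.logical(mask)
  stopifnot(length(keep) == n_vox)
  b0 <- scheme$bvals == 0
  s0_hat <- rowMeans(S[, b0, drop = FALSE])
  floor_vals <- pmax(1e-6 * s0_hat, .Machine$double.xmin)
  Sm <- S[keep, , drop = FALSE]
  fl <- floor_vals[keep]
  clamped <- Sm < fl
  n_clamped <- sum(clamped)
  Sm <- pmax(Sm, matrix(fl, nrow(Sm), n_vol))
  P <- solve(crossprod(X), t(X))              # 7 x n_vol pseudo-inverse
  coefs <- P %*% t(log(Sm))                   # 7 x n_kept
  tens <- matrix(0, n_vox, 6L)
  tens[keep, ] <- t(coefs[2:7, , drop = FALSE])
  s0 <- numeric(n_vox)
  s0[keep] <- exp(coefs[1L, ])
  # all-zero (fully clamped) voxels are degenerate: flag and zero the tensor
  dead <- keep & rowSums(S >= matrix(floor_vals, n_vox, n_vol)) == 0L
  tens[dead, ] <- 0
  structure(list(tensors = array(tens, c(grid_shape, 6L)),
                 s0 = array(s0, grid_shape),
                 mask = array(keep, grid_shape),
                 n_clamped = n_clamped,
                 n_dead = sum(dead)),
            class = "tensor_fit")
}

design_matrix <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' @export
print.tensor_fit <- function(x, ...) {
  d <- dim(x$s0)
  cat(sprintf("Tensor fit: %dx%dx%d grid, %d voxels in mask, %d clamped samples\n",
              d[1], d[2], d[3], sum(x$mask), x$n_clamped))
  invisible(x)
}

#' Eigendecompose a tensor volume
#'
#' Per-voxel symmetric eigendecomposition, eigenvalues sorted descending.
#' Negative eigenvalues (a noise artefact of the unconstrained fit) are
#' clamped to zero for scalar-map purposes and counted.
#'
#' @param x a `tensor_fit` or a 4-D tensor array (xx, yy, zz, xy, xz, yz).
#' @return an object of class `eigen_system`: `values` (4-D,
#'   `c(grid_shape, 3)`, descending), `vectors` (5-D, `c(grid_shape, 3, 3)`,
#'   `[..., i, e]` = component i of eigenvector e), `n_clamped_negative`.
#' @export
eigendecompose <- function(x) {
  tens <- if (inherits(x, "tensor_fit")) x$tensors else x
  dims <- dim(tens)
  stopifnot(length(dims) == 4L, dims[4] == 6L)
  grid_shape <- dims[1:3]
  D <- matrix(tens, prod(grid_shape), 6L)
  bad <- which(!is.finite(rowSums(D)))
  if (length(bad)) {
    vox <- arrayInd(bad[1L], grid_shape) - 1L
    stop_bad("non-finite tensor at voxel (%d, %d, %d)", vox[1], vox[2], vox[3])
  }
  res <- eig_sym_vol(D)
  n_neg <- sum(res$values < 0)
  res$values[res$values < 0] <- 0
  structure(list(values = array(res$values, c(grid_shape, 3L)),
                 vectors = array(res$vectors, c(grid_shape, 3L, 3L)),
                 n_clamped_negative = n_neg),
            class = "eigen_system")
}

#' @export
print.eigen_system <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Eigen system: %dx%dx%d grid, %d negative eigenvalues clamped\n",
              d[1], d[2], d[3], x$n_clamped_negative))
  invisible(x)
}

#' Scalar indexes from eigenvalue triples
#'
#' The standard definitions: MD = (l1 + l2 + l3)/3, AD = l1,
#' RD = (l2 + l3)/2, FA = sqrt(3/2) * sqrt(sum (l_i - MD)^2) / sqrt(sum l_i^2),
#' with FA defined as 0 where all eigenvalues vanish.
#'
#' @param l1,l2,l3 eigenvalue vectors, descending, mm^2/s.
#' @return list of vectors `fa`, `md`, `ad`, `rd`.
#' @export
tensor_indices <- function(l1, l2, l3) {
  md <- (l1 + l2 + l3) / 3
  ssq <- l1^2 + l2^2 + l3^2
  dev <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  fa <- ifelse(ssq > 0, sqrt(1.5 * dev / ssq), 0)
  list(fa = pmin(fa, 1), md = md, ad = l1, rd = (l2 + l3) / 2)
}

#' Derive FA, MD, AD and RD volumes from an eigen system
#'
#' @param eigs an `eigen_system` (eigenvalues already non-negative).
#' @return an object of class `scalar_maps` with 3-D arrays `fa`, `md`,
#'   `ad`, `rd`.
#' @export
scalar_maps <- function(eigs) {
  stopifnot(inherits(eigs, "eigen_system"))
  v <- eigs$values
  grid_shape <- dim(v)[1:3]
  if (any(v < 0)) stop_bad("negative eigenvalues reached scalar_maps; clamp first")
  ix <- tensor_indices(as.vector(v[, , , 1L]), as.vector(v[, , , 2L]),
                       as.vector(v[, , , 3L]))
  structure(lapply(ix, array, dim = grid_shape), class = "scalar_maps")
}

#' @export
print.scalar_maps <- function(x, ...) {
  cat(sprintf("Scalar maps: FA in [%.3f, %.3f], MD in [%.3g, %.3g] mm^2/s\n",
              min(x$fa), max(x$fa), min(x$md), max(x$md)))
  invisible(x)
}
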