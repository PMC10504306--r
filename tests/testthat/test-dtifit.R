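test_that("noiseless signals invert exactly to the generating tensors", {
  np <- noiseless_phantom()
  rel <- abs(np$fit$tensors - np$field$tensors) / max(abs(np$field$tensors))
  expect_lt(max(rel), 1e-6)
  expect_equal(np$fit$n_clamped, 0L)
  # isotropic voxel recovers the isotropic triple
  bg <- which(!(np$field$masks$left | np$field$masks$right))[1L]
  lam <- matrix(np$eigs$values, prod(np$grid_shape), 3L)[bg, ]
  expect_equal(lam, rep(1e-3, 3), tolerance = 1e-9)
})

test_that("tensor fit agrees with an independent per-voxel regression", {
  np <- noiseless_phantom()
  # independent oracle: lm() on the log-signal of individual voxels
  g <- np$scheme$bvecs
  b <- np$scheme$bvals
  X <- cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  n_vox <- prod(np$grid_shape)
  S <- matrix(np$dwi, n_vox, length(b))
  fitted <- matrix(np$fit$tensors, n_vox, 6L)
  set.seed(42)
  vox <- sample(which(np$field$masks$left | np$field$masks$right), 50)
  vox <- c(vox, sample(n_vox, 50))
  for (v in vox) {
    ref <- unname(coef(lm(log(S[v, ]) ~ X))[-1L])
    expect_equal(fitted[v, ], ref, tolerance = 1e-6)
  }
})

test_that("degenerate voxels are clamped, flagged and zeroed", {
  sch <- default_scheme()
  dims <- c(2L, 2L, 2L, 21L)
  tis <- tissue_model(sigma = 0)
  tens <- array(rep(c(1e-3, 1e-3, 1e-3, 0, 0, 0), each = 8), c(2, 2, 2, 6))
  dwi <- simulate_dwi(tens, sch, tis)
  dwi[1, 1, 1, ] <- 0                     # dead voxel
  fit <- fit_tensor(dwi, sch)
  expect_gt(fit$n_clamped, 0L)
  expect_equal(fit$n_dead, 1L)
  expect_equal(max(abs(fit$tensors[1, 1, 1, ])), 0)
  # a collinear scheme (all directions in one plane) is refused
  flat <- acquisition_scheme(c(0, rep(1000, 6)),
                             rbind(0, cbind(cos(1:6), sin(1:6), 0)))
  dwi7 <- array(100, c(2, 2, 2, 7))
  expect_error(fit_tensor(dwi7, flat), "collinear")
})

test_that("eigendecomposition sorts, clamps and matches base eigen", {
  tens <- random_tensors(100, seed = 9)
  eigs <- eigendecompose(array(tens, c(100, 1, 1, 6)))
  vals <- matrix(eigs$values, 100, 3)
  vecs <- array(eigs$vectors, c(100, 3, 3))
  for (i in 1:100) {
    D <- matrix(c(tens[i, 1], tens[i, 4], tens[i, 5],
                  tens[i, 4], tens[i, 2], tens[i, 6],
                  tens[i, 5], tens[i, 6], tens[i, 3]), 3, 3)
    ref <- eigen(D, symmetric = TRUE)
    expect_equal(vals[i, ], ref$values, tolerance = 1e-10)
    # eigenvectors match up to sign
    for (e in 1:3) {
      expect_equal(abs(sum(vecs[i, , e] * ref$vectors[, e])), 1, tolerance = 1e-8)
    }
  }
  expect_true(all(diff(t(vals)) <= 1e-15))           # descending order

  # rotation invariance of the eigenvalues
  lam <- c(1.7e-3, 0.3e-3, 0.3e-3)
  q <- qr.Q(qr(matrix(c(1, 2, 3, 0, 1, 4, 5, 6, 0), 3)))
  D <- q %*% diag(lam) %*% t(q)
  e2 <- eigendecompose(array(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
                             c(1, 1, 1, 6)))
  expect_equal(as.vector(e2$values), lam, tolerance = 1e-12)

  # a slightly negative eigenvalue is clamped and counted
  neg <- eigendecompose(array(c(1e-3, 5e-4, -1e-6, 0, 0, 0), c(1, 1, 1, 6)))
  expect_equal(neg$n_clamped_negative, 1L)
  expect_equal(min(neg$values), 0)

  bad <- array(c(NaN, 1, 1, 0, 0, 0), c(1, 1, 1, 6))
  expect_error(eigendecompose(bad), "voxel")
})

test_that("scalar indexes follow the standard definitions", {
  # isotropic
  iso <- tensor_indices(1e-3, 1e-3, 1e-3)
  expect_equal(iso$fa, 0)
  expect_equal(iso$md, 1e-3)
  expect_equal(iso$ad, 1e-3)
  expect_equal(iso$rd, 1e-3)
  # prolate nerve-like tensor (frozen closed-form values)
  pro <- tensor_indices(1.7e-3, 0.3e-3, 0.3e-3)
  expect_equal(pro$fa, 0.7990222, tolerance = 1e-6)
  expect_equal(pro$md, 0.7666667e-3, tolerance = 1e-6)
  expect_equal(pro$ad, 1.7e-3)
  expect_equal(pro$rd, 0.3e-3)
  # stick limit
  expect_equal(tensor_indices(1e-3, 0, 0)$fa, 1)
})

test_that("scalar maps match an independently coded formula on random triples", {
  set.seed(13)
  lam <- matrix(sort(runif(300, 0, 2e-3), decreasing = TRUE), 100, 3)
  lam <- t(apply(lam, 1, sort, decreasing = TRUE))
  eigs <- structure(list(values = array(lam, c(100, 1, 1, 3)),
                         vectors = array(rep(diag(3), each = 100), c(100, 1, 1, 3, 3)),
                         n_clamped_negative = 0L),
                    class = "eigen_system")
  sm <- scalar_maps(eigs)
  for (i in 1:100) {
    l <- lam[i, ]
    md_ref <- sum(l) / 3
    fa_ref <- sqrt(3 / 2) * sqrt(sum((l - md_ref)^2)) / sqrt(sum(l^2))
    expect_equal(sm$fa[i, 1, 1], fa_ref, tolerance = 1e-12)
    expect_equal(sm$md[i, 1, 1], md_ref, tolerance = 1e-12)
    expect_equal(sm$ad[i, 1, 1], l[1], tolerance = 1e-12)
    expect_equal(sm$rd[i, 1, 1], (l[2] + l[3]) / 2, tolerance = 1e-12)
  }
})

test_that("scalar-map invariants hold volume-wide", {
  np <- noiseless_phantom()
  sm <- np$scal
  expect_true(all(sm$fa >= 0 & sm$fa <= 1))
  # MD identity to 1e-12 relative
  expect_lt(max(abs(sm$md - (sm$ad + 2 * sm$rd) / 3)) / max(sm$md), 1e-12)
  # FA = 0 iff isotropic (background voxels here)
  iso_vox <- !(np$field$masks$left | np$field$masks$right)
  expect_lt(max(sm$fa[iso_vox]), 1e-6)
  expect_gt(min(sm$fa[!iso_vox]), 0.2)
  # with AD fixed, FA strictly decreases in RD on (0, AD]
  rd_grid <- seq(0.05e-3, 1.2e-3, length.out = 25)
  fa_grid <- tensor_indices(rep(1.2e-3, 25), rd_grid, rd_grid)$fa
  expect_true(all(diff(fa_grid) < 0))
})
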