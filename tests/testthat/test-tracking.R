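test_that("seed expansion matches a brute-force enumeration of voxel centers", {
  gs <- c(32L, 32L, 32L)
  aff <- make_affine(0.4)
  ctr <- c(6.4, 6.4, 6.4)
  seeds <- make_seeds(matrix(ctr, 1), "left", gs, aff, diameter = 5)
  # oracle: every voxel center in the grid within 2.5 mm
  all_vox <- as.matrix(expand.grid(0:31, 0:31, 0:31)) * 0.4
  n_ref <- sum(rowSums(sweep(all_vox, 2, ctr)^2) <= 2.5^2)
  expect_equal(nrow(seeds$points), n_ref)
  expect_gt(n_ref, 500)   # a 5 mm sphere holds many 0.4 mm voxels

  # sub-voxel sphere centered exactly on a voxel center -> single seed
  tiny <- make_seeds(matrix(c(4, 4, 4), 1), "left", gs, aff, diameter = 0.2)
  expect_equal(nrow(tiny$points), 1L)
  expect_equal(as.vector(tiny$points), c(4, 4, 4))

  # mirrored centers give mirrored, equally sized seed sets
  extent <- (gs[1] - 1) * 0.4
  m1 <- make_seeds(matrix(c(4.0, 6, 6), 1), "left", gs, aff)
  m2 <- make_seeds(matrix(c(extent - 4.0, 6, 6), 1), "right", gs, aff)
  expect_equal(nrow(m1$points), nrow(m2$points))
  expect_equal(sort(extent - m1$points[, 1]), sort(m2$points[, 1]), tolerance = 1e-9)

  expect_error(make_seeds(matrix(c(100, 100, 100), 1), "left", gs, aff),
               "outside the grid")
})

test_that("sub-threshold seeds start nothing and straight fields track to the mask edge", {
  gs <- c(50L, 16L, 16L)
  aff <- make_affine(0.4)
  # high-FA slab for voxels i in [10, 39], uniform +x field
  f <- synthetic_eigs(gs,
                      function(i, j, k) cbind(1, 0 * i, 0 * i),
                      function(i, j, k) ifelse(i >= 10 & i <= 39, 0.8, 0.05))
  params <- track_params()
  seed <- c(25 * 0.4, 3.2, 3.2)   # inside the slab
  sl <- track_streamline(seed, f$eigs, f$fa, params, aff)
  expect_false(is.null(sl))
  # straight line: constant y, z
  expect_lt(max(abs(sl[, 2] - 3.2)), 1e-9)
  expect_lt(max(abs(sl[, 3] - 3.2)), 1e-9)
  # length equals twice the seed-to-boundary distance within one step per side
  len <- sum(sqrt(rowSums(diff(sl)^2)))
  d_left <- 25 * 0.4 - (10 - 0.5) * 0.4
  d_right <- (39 + 0.5) * 0.4 - 25 * 0.4
  expect_lt(abs(len - (d_left + d_right)), 2 * params$step_size + 1e-9)
  # steps are uniform at step_size
  expect_equal(sqrt(rowSums(diff(sl)^2)),
               rep(params$step_size, nrow(sl) - 1L), tolerance = 1e-9)

  # seed voxel below the FA threshold -> no streamline
  low <- track_streamline(c(2 * 0.4, 3.2, 3.2), f$eigs, f$fa, params, aff)
  expect_null(low)
})

test_that("the angle threshold stops at a 61 degree bend but passes 59 degrees", {
  gs <- c(60L, 60L, 16L)
  aff <- make_affine(0.4)
  run_bend <- function(theta_deg) {
    th <- theta_deg * pi / 180
    f <- synthetic_eigs(gs,
                        function(i, j, k) {
                          bent <- i >= 30
                          cbind(ifelse(bent, cos(th), 1), ifelse(bent, sin(th), 0), 0)
                        },
                        function(i, j, k) 0.9)
    # launch inside the straight region, heading +x
    sl <- track_streamline(c(10 * 0.4, 30 * 0.4, 3.2), f$eigs, f$fa,
                           track_params(max_steps = 500L), aff)
    sl
  }
  stopped <- run_bend(61)
  passed <- run_bend(59)
  # the 61-degree track cannot continue beyond the bend: no point much past x of the bend
  expect_lt(max(stopped[, 1]), 30 * 0.4 + 2 * 0.2 + 1e-9)
  # the 59-degree track turns and keeps going well beyond
  expect_gt(sum(sqrt(rowSums(diff(passed)^2))),
            sum(sqrt(rowSums(diff(stopped)^2))) + 2)
  # turning angles in the retained 59-degree track never exceed 60 degrees
  steps <- diff(passed)
  steps <- steps / sqrt(rowSums(steps^2))
  cosang <- rowSums(steps[-nrow(steps), ] * steps[-1L, ])
  expect_gte(min(cosang), cos(60 * pi / 180) - 1e-9)
})

test_that("the length filter discards strictly below the threshold", {
  np <- noiseless_phantom()
  lens <- vapply(np$streams$streamlines, facialdti:::streamline_length, 0)
  expect_true(all(lens >= 2.0))
  # re-filter the same raw tracks at a higher threshold: boundary is 'less than'
  l1 <- lens[1]
  raw <- facialdti:::track_batch(np$seeds$points, np$eigs, np$scal$fa,
                                 np$params, np$affine)
  raw_lens <- vapply(raw, facialdti:::streamline_length, 0)
  keep_at <- function(thr) sum(raw_lens[raw_lens > 0] >= thr)
  expect_equal(length(np$streams$streamlines), keep_at(2.0))
  expect_lt(keep_at(l1 + 0.1), keep_at(l1))   # raising above an attained length drops it
  # an all-isotropic volume tracks nothing
  f <- synthetic_eigs(c(12L, 12L, 12L), function(i, j, k) cbind(1, 0 * i, 0 * i),
                      function(i, j, k) 0 * i)
  seeds <- make_seeds(matrix(c(2, 2, 2), 1), "left", c(12L, 12L, 12L),
                      np$affine, diameter = 2)
  st <- track_all(seeds, f$eigs, f$fa, np$params, np$affine)
  expect_equal(length(st$streamlines), 0L)
  expect_warning(voxelize_streamlines(st, c(12L, 12L, 12L), np$affine), "empty")
})

test_that("retained streamlines respect the FA, angle and length invariants", {
  np <- noiseless_phantom()
  fa_of <- function(pts) {
    vox <- floor(facialdti::world_to_voxel(pts, np$affine) + 0.5)
    np$scal$fa[cbind(vox[, 1] + 1L, vox[, 2] + 1L, vox[, 3] + 1L)]
  }
  for (sl in np$streams$streamlines[seq(1, length(np$streams$streamlines), by = 7)]) {
    expect_gte(sum(sqrt(rowSums(diff(sl)^2))), np$params$min_length)
    fa_vals <- fa_of(sl)
    expect_true(all(fa_vals[-c(1L, length(fa_vals))] >= np$params$fa_threshold))
    steps <- diff(sl)
    steps <- steps / sqrt(rowSums(steps^2))
    if (nrow(steps) > 1) {
      cosang <- rowSums(steps[-nrow(steps), ] * steps[-1L, ])
      expect_gte(min(cosang), cos(np$params$angle_threshold * pi / 180) - 1e-9)
    }
  }
})

test_that("flipping every principal eigenvector leaves tracks identical up to reversal", {
  np <- noiseless_phantom()
  flipped <- np$eigs
  flipped$vectors[, , , , 1L] <- -flipped$vectors[, , , , 1L]
  sub <- make_seeds(np$seeds$centers[c(1, 3), , drop = FALSE], c("left", "right"),
                    np$grid_shape, np$affine, diameter = 1.2)
  a <- track_all(sub, np$eigs, np$scal$fa, np$params, np$affine)
  b <- track_all(sub, flipped, np$scal$fa, np$params, np$affine)
  expect_equal(length(a$streamlines), length(b$streamlines))
  for (i in seq_along(a$streamlines)) {
    rev_b <- b$streamlines[[i]][nrow(b$streamlines[[i]]):1, , drop = FALSE]
    expect_equal(a$streamlines[[i]], rev_b, tolerance = 1e-9)
  }
})

test_that("seeded tracking visits nearly every tube voxel", {
  np <- noiseless_phantom()
  lab <- voxelize_streamlines(np$streams, np$grid_shape, np$affine)
  for (side in c("left", "right")) {
    tube <- np$field$masks[[side]]
    frac <- sum(lab[[side]] & tube) / sum(tube)
    expect_gte(frac, 0.95)
  }
})
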