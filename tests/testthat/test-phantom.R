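test_that("left and right centerlines are mirror images with a safe margin", {
  gs <- c(64L, 64L, 64L)
  aff <- make_affine(0.4)
  left <- make_centerline("left", gs, aff)
  right <- make_centerline("right", gs, aff)
  mid <- (gs[1] - 1) * 0.4 / 2
  mirrored_x <- 2 * mid - left$centerline[, 1]
  expect_equal(mirrored_x, right$centerline[, 1], tolerance = 1e-9)
  expect_equal(left$centerline[, 2:3], right$centerline[, 2:3], tolerance = 1e-9)
  # all points at least 2 voxels (0.8 mm) from every grid face
  extent <- (gs - 1L) * 0.4
  for (cl in list(left$centerline, right$centerline)) {
    expect_true(all(cl >= 0.8 - 1e-9))
    expect_true(all(sweep(cl, 2, extent) <= -0.8 + 1e-9))
  }
  expect_error(make_centerline("left", c(4L, 4L, 4L), aff), "too small")
})

test_that("tensor field places cylindrical tensors along the tube and isotropic background", {
  gs <- c(30L, 12L, 12L)
  aff <- make_affine(0.4)
  # straight tube along +x through the grid middle
  geom <- structure(list(centerline = cbind(seq(1, 10.6, length.out = 5), 2.2, 2.2),
                         tube_radius = 0.8, side = "left"),
                    class = "nerve_geometry")
  tis <- tissue_model(ad_true = 1.7e-3, rd_true = 0.3e-3, sigma = 0)
  field <- build_tensor_field(geom, tis, gs, aff)
  mask <- field$masks$left
  expect_gt(sum(mask), 50)
  tens <- matrix(field$tensors, prod(gs), 6L)
  inside <- which(mask)
  # principal axis along x: Dxx = ad, Dyy = Dzz = rd, off-diagonals 0
  expect_equal(tens[inside, 1], rep(1.7e-3, length(inside)), tolerance = 1e-12)
  expect_equal(tens[inside, 2], rep(0.3e-3, length(inside)), tolerance = 1e-12)
  expect_equal(max(abs(tens[inside, 4:6])), 0)
  eigs <- eigendecompose(field$tensors)
  e1 <- matrix(eigs$vectors[, , , , 1L], prod(gs), 3L)
  expect_equal(abs(e1[inside, 1]), rep(1, length(inside)), tolerance = 1e-9)
  # outside the tube: isotropic triple
  outside <- which(!mask)
  expect_equal(tens[outside, 1], rep(1e-3, length(outside)), tolerance = 1e-12)
  expect_equal(max(abs(tens[outside, 4:6])), 0)
  # closed-form FA of the tube tensor
  ix <- tensor_indices(1.7e-3, 0.3e-3, 0.3e-3)
  expect_equal(ix$fa, 0.799, tolerance = 5e-4)
})

test_that("DWI simulation follows the monoexponential model and is reproducible", {
  tis <- tissue_model(sigma = 0, s0 = 500)
  # single-voxel tensor volume, diagonal (1.7, 0.3, 0.3)e-3
  tens <- array(c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0), c(1, 1, 1, 6))
  sch <- acquisition_scheme(c(0, rep(1000, 6)),
                            rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                  c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                                  c(0, 1, 1) / sqrt(2)))
  S <- simulate_dwi(tens, sch, tis)
  expect_equal(S[1, 1, 1, 1], 500)                        # b = 0 -> s0
  expect_equal(S[1, 1, 1, 2] / 500, exp(-1.7), tolerance = 1e-12)
  bad <- sch; bad$bvals[2] <- -10
  expect_error(simulate_dwi(tens, bad, tis), "negative b")

  noisy <- tissue_model(sigma = 10)
  big <- array(rep(c(1e-3, 1e-3, 1e-3, 0, 0, 0), each = 1000), c(10, 10, 10, 6))
  s1 <- simulate_dwi(big, sch, noisy, seed = 7)
  s2 <- simulate_dwi(big, sch, noisy, seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_dwi(big, sch, noisy, seed = 8)
  expect_false(identical(s1, s3))
})

test_that("Rician noise inflates the mean background magnitude", {
  # Rician bias: E|S + noise| > S, clearest at low SNR; test on >= 1e4 voxels
  tis <- tissue_model(sigma = 100, s0 = 1000)
  tens <- array(rep(c(1e-3, 1e-3, 1e-3, 0, 0, 0), each = 30^3), c(30, 30, 30, 6))
  sch <- default_scheme()
  S <- simulate_dwi(tens, sch, tis, seed = 11)
  noiseless <- 1000 * exp(-1)            # any b=1000 direction of an isotropic voxel
  expect_gt(mean(S[, , , 2]), noiseless)
})

test_that("cohort generation applies effects exactly and follows the laterality split", {
  tis <- tissue_model()
  # zero between-subject variance: all subjects identical, effect ratios exact
  spec <- cohort_spec(3, "patient", affected_side = "left",
                      rd_effect = 1.128, ad_effect = 1.0,
                      between_subject_sd = 0, seed = 5)
  m <- simulate_index_cohort(spec, tis)
  expect_equal(nrow(m), 6L)
  left <- m[m$side == "left", ]
  right <- m[m$side == "right", ]
  expect_equal(left$rd / right$rd, rep(1.128, 3), tolerance = 1e-12)
  expect_equal(left$ad / right$ad, rep(1, 3), tolerance = 1e-12)
  expect_equal(unique(left$role), "affected")

  healthy <- cohort_spec(4, "healthy", between_subject_sd = 0, seed = 5)
  mh <- simulate_index_cohort(healthy, tis)
  expect_equal(length(unique(mh$ad)), 1L)
  expect_equal(length(unique(mh$rd)), 1L)

  split <- facialdti:::assign_affected_sides(cohort_spec(19, "patient", seed = 1))
  expect_equal(sum(split == "right"), 13L)
  expect_equal(sum(split == "left"), 6L)

  expect_error(cohort_spec(1, "patient"), "n_subjects")
  expect_error(cohort_spec(5, "healthy", rd_effect = 1.2), "healthy cohorts")
})

test_that("healthy truth masks are exact mirror images and cohorts are byte-deterministic", {
  gs <- c(36L, 36L, 36L)
  aff <- make_affine(0.4)
  tis <- tissue_model()
  spec <- cohort_spec(2, "healthy", between_subject_sd = 0, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- generate_cohort(spec, default_scheme(), tis, gs, aff,
                        geometry_args = list(tract_length = 10), out_dir = d1)
  c2 <- generate_cohort(spec, default_scheme(), tis, gs, aff,
                        geometry_args = list(tract_length = 10), out_dir = d2)
  s <- c1$subjects[[1L]]
  ml <- s$truth_masks$left
  mr <- s$truth_masks$right
  expect_equal(sum(ml), sum(mr))
  expect_identical(ml[gs[1]:1, , ], mr)       # voxel mirror across midsagittal plane
  expect_false(any(ml & mr))
  # identical (spec, seed) -> identical bytes on disk
  f1 <- file.path(d1, "H01", "dwi.nii.gz")
  f2 <- file.path(d2, "H01", "dwi.nii.gz")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_equal(nrow(c1$manifest), 2L)
  expect_named(c1$manifest, c("subject_id", "group", "affected_side", "ad_left",
                              "rd_left", "ad_right", "rd_right", "seed"))
})
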