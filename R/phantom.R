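# Synthetic bilateral nerve phantom: geometry, tissue model, DWI simulation
# and cohort generation with known ground truth.
#
# The phantom emulates the statistical structure of a bilateral
# intratemporal-nerve study: thin curved tubes placed mirror-symmetrically
# about the midsagittal plane of a common isotropic grid, a cylindrically
# symmetric tensor inside the tube (principal axis along the local tangent),
# isotropic background elsewhere, monoexponential diffusion signal and
# Rician magnitude noise. Patients carry a unilateral radial-diffusivity
# increase with axial diffusivity unchanged -- the demyelination signature.

#' Tissue model for the nerve phantom
#'
#' Diffusivities are in mm^2/s. Defaults follow healthy-side facial-nerve
#' values (AD 1.20e-3, RD 0.78e-3); background is isotropic soft tissue;
#' noise defaults to SNR 30 on the b = 0 signal.
#'
#' @param ad_true axial diffusivity (largest eigenvalue), mm^2/s.
#' @param rd_true radial diffusivity (the two equal small eigenvalues), mm^2/s.
#' @param iso_background isotropic background diffusivity, mm^2/s.
#' @param s0 non-diffusion-weighted signal, arbitrary units.
#' @param sigma Rician noise scale (SD of each Gaussian channel), same units
#'   as `s0`.
#' @return an object of class `tissue_model`.
#' @export
tissue_model <- function(ad_true = 1.20e-3, rd_true = 0.78e-3,
                         iso_background = 1.0e-3, s0 = 1000,
                         sigma = s0 / 30) {
  if (!(ad_true >= rd_true && rd_true > 0)) {
    stop_bad("tissue model requires ad_true >= rd_true > 0 (got %g, %g)", ad_true, rd_true)
  }
  if (iso_background <= 0) stop_bad("iso_background must be > 0")
  if (s0 <= 0) stop_bad("s0 must be > 0")
  if (sigma < 0) stop_bad("sigma must be >= 0")
  structure(list(ad_true = ad_true, rd_true = rd_true,
                 iso_background = iso_background, s0 = s0, sigma = sigma),
            class = "tissue_model")
}

#' Cohort specification
#'
#' Defines one simulated group. Healthy cohorts are bilaterally symmetric
#' (no affected side, unit effects). Patient cohorts apply a multiplicative
#' radial-diffusivity effect (default 0.00088/0.00078, the affected/healthy
#' ratio of the facial-nerve group means) to the affected side only, with
#' axial diffusivity unchanged. `affected_side = "split"` reproduces the
#' 13 right / 6 left laterality proportion of the clinical cohort.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param group `"healthy"` or `"patient"`.
#' @param affected_side `"left"`, `"right"`, `"none"`, or `"split"`.
#' @param rd_effect multiplicative factor on radial diffusivity, affected side.
#' @param ad_effect multiplicative factor on axial diffusivity, affected side.
#' @param between_subject_sd relative SD of per-subject, per-side tissue
#'   parameters (log-normal jitter).
#' @param between_side_correlation correlation of the left and right log
#'   jitters within a subject. A shared subject-level component (anatomy,
#'   physiology common to both nerves) makes paired left-right differences
#'   tighter than the marginal spread; the default 0.6 is calibrated to the
#'   published facial-nerve tables, whose paired t statistics imply
#'   correlations of roughly 0.5-0.75 between sides.
#' @param seed integer RNG seed for the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, group = c("healthy", "patient"),
                        affected_side = NULL, rd_effect = NULL,
                        ad_effect = NULL, between_subject_sd = 0.08,
                        between_side_correlation = 0.6, seed = 1L) {
  group <- match.arg(group)
  if (group == "healthy") {
    affected_side <- affected_side %||% "none"
    rd_effect <- rd_effect %||% 1
    ad_effect <- ad_effect %||% 1
  } else {
    affected_side <- affected_side %||% "split"
    rd_effect <- rd_effect %||% (0.00088 / 0.00078)
    ad_effect <- ad_effect %||% 1
  }
  problems <- character()
  if (!(is.numeric(n_subjects) && n_subjects >= 2)) {
    problems <- c(problems, "n_subjects must be >= 2")
  }
  if (!affected_side %in% c("left", "right", "none", "split")) {
    problems <- c(problems, "affected_side must be left, right, none or split")
  }
  if (!(rd_effect > 0)) problems <- c(problems, "rd_effect must be > 0")
  if (!(ad_effect > 0)) problems <- c(problems, "ad_effect must be > 0")
  if (between_subject_sd < 0) problems <- c(problems, "between_subject_sd must be >= 0")
  if (between_side_correlation < 0 || between_side_correlation > 1) {
    problems <- c(problems, "between_side_correlation must be in [0, 1]")
  }
  if (group == "healthy" &&
      (affected_side != "none" || rd_effect != 1 || ad_effect != 1)) {
    problems <- c(problems,
                  "healthy cohorts must have affected_side = none and unit effects")
  }
  if (length(problems)) {
    stop_bad("invalid cohort spec: %s", paste(problems, collapse = "; "))
  }
  structure(list(n_subjects = as.integer(n_subjects), group = group,
                 affected_side = affected_side, rd_effect = rd_effect,
                 ad_effect = ad_effect, between_subject_sd = between_subject_sd,
                 between_side_correlation = between_side_correlation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d %s subjects, affected side %s, RD effect %.4g, AD effect %.4g\n",
              x$n_subjects, x$group, x$affected_side, x$rd_effect, x$ad_effect))
  invisible(x)
}

#' Nerve centerline geometry
#'
#' A gently curved circular arc running mostly along z at a fixed lateral
#' offset from the grid midsagittal plane; the left and right curves are
#' exact mirror images across that plane. The arc stands in for the mastoid
#' segment of the intratemporal nerve course.
#'
#' @param side `"left"` or `"right"`.
#' @param grid_shape integer length-3 voxel counts.
#' @param affine 4x4 voxel-to-world transform (must be axis-aligned diagonal).
#' @param tube_radius nerve tube radius, mm.
#' @param tract_length arc length, mm; default fits the grid (at least 10 mm).
#' @param arc_radius radius of curvature, mm (large = gentle bend).
#' @param lateral_frac lateral offset of the nerve from the midsagittal
#'   plane, as a fraction of the grid x extent.
#' @param n_points number of control points returned.
#' @return an object of class `nerve_geometry` with fields `centerline`
#'   (n x 3 world mm), `tube_radius`, `side`.
#' @export
make_centerline <- function(side = c("left", "right"), grid_shape,
                            affine = make_affine(0.4), tube_radius = 0.8,
                            tract_length = NULL, arc_radius = 20,
                            lateral_frac = 0.24, n_points = 41L) {
  side <- match.arg(side)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, tube_radius > 0)
  vox <- diag(affine)[1:3]
  if (any(abs(affine[1:3, 1:3] - diag(vox)) > 1e-12)) {
    stop_bad("phantom geometry requires an axis-aligned diagonal affine")
  }
  origin <- affine[1:3, 4]
  extent <- (grid_shape - 1L) * vox               # center-to-center extents, mm
  margin <- 2 * vox + tube_radius                 # >= 2 voxels + tube wall
  usable_z <- extent[3] - 2 * margin[3]
  min_len <- 10
  if (is.null(tract_length)) tract_length <- min(14, 0.8 * usable_z)
  if (tract_length < min_len || usable_z < tract_length) {
    stop_bad(paste0(
      "grid too small for the nerve tube: z extent must be at least %.1f mm ",
      "(%.0f voxels at %.2g mm) to hold a %.0f mm tube with a 2-voxel margin; got %.1f mm"),
      min_len + 2 * margin[3], ceiling((min_len + 2 * margin[3]) / vox[3]) + 1,
      vox[3], min_len, extent[3])
  }
  mid <- origin + extent / 2                      # midsagittal mirror plane at mid[1]
  offset <- lateral_frac * extent[1]
  x_c <- if (side == "right") mid[1] + offset else mid[1] - offset
  if (x_c - tube_radius < origin[1] + margin[1] ||
      x_c + tube_radius > origin[1] + extent[1] - margin[1]) {
    stop_bad("grid too small in x: lateral offset %.1f mm leaves no margin", offset)
  }
  theta_max <- tract_length / (2 * arc_radius)
  theta <- seq(-theta_max, theta_max, length.out = n_points)
  bulge <- arc_radius * (1 - cos(theta))
  centerline <- cbind(
    x = rep(x_c, n_points),
    y = mid[2] + bulge - max(bulge) / 2,
    z = mid[3] + arc_radius * sin(theta)
  )
  structure(list(centerline = centerline, tube_radius = tube_radius, side = side),
            class = "nerve_geometry")
}

# Dense resampling of the centerline polyline with unit tangents; the
# workhorse behind voxel membership and tensor orientation.
sample_centerline <- function(geometry, spacing = 0.1) {
  cl <- geometry$centerline
  seg <- diff(cl)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) stop_bad("centerline has repeated consecutive points")
  pts <- list(); tans <- list()
  for (i in seq_len(nrow(seg))) {
    n_sub <- max(1L, ceiling(seg_len[i] / spacing))
    frac <- seq(0, 1, length.out = n_sub + 1L)[-(n_sub + 1L)]
    pts[[i]] <- cbind(cl[i, 1] + frac * seg[i, 1],
                      cl[i, 2] + frac * seg[i, 2],
                      cl[i, 3] + frac * seg[i, 3])
    tans[[i]] <- matrix(seg[i, ] / seg_len[i], nrow = n_sub, ncol = 3L, byrow = TRUE)
  }
  last_tan <- tans[[length(tans)]][1L, , drop = FALSE]
  pts[[length(pts) + 1L]] <- cl[nrow(cl), , drop = FALSE]
  tans[[length(tans) + 1L]] <- last_tan
  list(points = do.call(rbind, pts), tangents = do.call(rbind, tans))
}

#' Tube membership of a nerve geometry on a grid
#'
#' Linear indices of voxels whose center lies within `tube_radius` of the
#' centerline (no subvoxel partial-volume mixing), plus the unit tangent at
#' the nearest centerline sample per voxel.
#'
#' @param geometry a `nerve_geometry`.
#' @param grid_shape integer length-3 voxel counts.
#' @param affine 4x4 voxel-to-world transform.
#' @return list with `index` (1-based linear voxel indices) and `tangent`
#'   (matching n x 3 unit vectors).
#' @export
tube_geometry <- function(geometry, grid_shape, affine) {
  samp <- sample_centerline(geometry)
  vox <- diag(affine)[1:3]
  r <- geometry$tube_radius
  lo <- owning_voxel(matrix(apply(samp$points, 2, min) - r - max(vox), ncol = 3), affine)
  hi <- owning_voxel(matrix(apply(samp$points, 2, max) + r + max(vox), ncol = 3), affine)
  lo <- pmax(as.numeric(lo), 0)
  hi <- pmin(as.numeric(hi), grid_shape - 1L)
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  centers <- voxel_to_world(cand, affine)
  # nearest centerline sample per candidate voxel center
  d2 <- outer(rowSums(centers^2), rep(1, nrow(samp$points))) +
    outer(rep(1, nrow(centers)), rowSums(samp$points^2)) -
    2 * centers %*% t(samp$points)
  nearest <- max.col(-d2, ties.method = "first")
  mind2 <- d2[cbind(seq_len(nrow(d2)), nearest)]
  inside <- mind2 <= r^2 + 1e-12
  list(
    index = voxel_linear_index(cand[inside, , drop = FALSE], grid_shape),
    tangent = samp$tangents[nearest[inside], , drop = FALSE]
  )
}

#' Build the ground-truth tensor field for one nerve geometry
#'
#' Voxels whose center lies within `tube_radius` of the centerline receive a
#' cylindrically symmetric tensor with principal axis along the local
#' centerline tangent and eigenvalues (ad, rd, rd); all other voxels receive
#' an isotropic background tensor.
#'
#' @param geometry a `nerve_geometry` (or list of them, fused into one field).
#' @param tissue a `tissue_model`; per-side overrides via `ad`, `rd`.
#' @param grid_shape integer length-3 voxel counts.
#' @param affine 4x4 voxel-to-world transform.
#' @param ad,rd optional vectors (recycled over geometries) overriding the
#'   tissue model's diffusivities per geometry.
#' @param tubes optional precomputed list of [tube_geometry()] results, one
#'   per geometry; geometry is identical across a cohort's subjects, so
#'   callers generating many subjects can compute it once.
#' @return list with `tensors` (4-D array `c(grid_shape, 6)`, component order
#'   xx, yy, zz, xy, xz, yz), `masks` (list of logical arrays, one per
#'   geometry, named by side).
#' @export
build_tensor_field <- function(geometry, tissue, grid_shape,
                               affine = make_affine(0.4), ad = NULL, rd = NULL,
                               tubes = NULL) {
  if (inherits(geometry, "nerve_geometry")) geometry <- list(geometry)
  n_geo <- length(geometry)
  ad <- rep_len(ad %||% tissue$ad_true, n_geo)
  rd <- rep_len(rd %||% tissue$rd_true, n_geo)
  n_vox <- prod(grid_shape)
  tens <- matrix(0, n_vox, 6L)
  tens[, 1:3] <- tissue$iso_background
  masks <- list()
  for (g in seq_len(n_geo)) {
    if (any(rd[g] <= 0) || ad[g] < rd[g]) {
      stop_bad("tube diffusivities must satisfy ad >= rd > 0")
    }
    tg <- if (!is.null(tubes)) tubes[[g]] else {
      tube_geometry(geometry[[g]], grid_shape, affine)
    }
    t1 <- tg$tangent[, 1]; t2 <- tg$tangent[, 2]; t3 <- tg$tangent[, 3]
    dl <- ad[g] - rd[g]
    tens[tg$index, ] <- cbind(dl * t1 * t1 + rd[g],
                              dl * t2 * t2 + rd[g],
                              dl * t3 * t3 + rd[g],
                              dl * t1 * t2, dl * t1 * t3, dl * t2 * t3)
    m <- array(FALSE, grid_shape)
    m[tg$index] <- TRUE
    masks[[geometry[[g]]$side]] <- m
  }
  list(tensors = array(tens, c(grid_shape, 6L)), masks = masks)
}

#' Simulate diffusion-weighted signal from a tensor field
#'
#' Noiseless signal follows the monoexponential tensor model
#' S = s0 exp(-b g' D g); Rician noise replaces S with
#' sqrt((S + n1)^2 + n2^2), n1 and n2 independent zero-mean Gaussians of SD
#' `sigma`. Fully reproducible from `seed`.
#'
#' @param tensors 4-D tensor array `c(grid_shape, 6)` (xx, yy, zz, xy, xz, yz).
#' @param scheme an `acquisition_scheme`.
#' @param tissue a `tissue_model` (supplies `s0` and `sigma`).
#' @param seed RNG seed; `NULL` leaves the caller's RNG stream in charge.
#' @return 4-D array `c(grid_shape, n_volumes)` of non-negative signals.
#' @export
simulate_dwi <- function(tensors, scheme, tissue, seed = NULL) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  dims <- dim(tensors)
  stopifnot(length(dims) == 4L, dims[4] == 6L)
  if (any(scheme$bvals < 0)) stop_bad("negative b-value")
  n_vox <- prod(dims[1:3])
  D <- matrix(tensors, n_vox, 6L)
  n_vol <- length(scheme$bvals)
  S <- matrix(tissue$s0, n_vox, n_vol)
  for (v in seq_len(n_vol)) {
    b <- scheme$bvals[v]
    if (b == 0) next
    g <- scheme$bvecs[v, ]
    quad <- D[, 1] * g[1]^2 + D[, 2] * g[2]^2 + D[, 3] * g[3]^2 +
      2 * (D[, 4] * g[1] * g[2] + D[, 5] * g[1] * g[3] + D[, 6] * g[2] * g[3])
    S[, v] <- tissue$s0 * exp(-b * quad)
  }
  if (tissue$sigma > 0) {
    S <- with_seed(seed, {
      n1 <- matrix(stats::rnorm(length(S), 0, tissue$sigma), n_vox, n_vol)
      n2 <- matrix(stats::rnorm(length(S), 0, tissue$sigma), n_vox, n_vol)
      sqrt((S + n1)^2 + n2^2)
    })
  }
  array(S, c(dims[1:3], n_vol))
}

# Per-subject, per-side realized tissue parameters. The log jitter of each
# diffusivity splits into a subject-shared component (variance fraction
# `between_side_correlation`) plus an independent per-side component, so the
# marginal relative SD stays `between_subject_sd` while left-right paired
# differences are tighter -- matching the within-subject correlation implied
# by the published paired statistics. Affected-side multiplicative effects
# are applied last.
draw_subject_params <- function(spec, tissue, affected_side) {
  sd_shared <- spec$between_subject_sd * sqrt(spec$between_side_correlation)
  sd_side <- spec$between_subject_sd * sqrt(1 - spec$between_side_correlation)
  shared <- stats::rnorm(2L, 0, sd_shared)    # (ad, rd) subject components
  p <- list()
  for (side in c("left", "right")) {
    ad <- tissue$ad_true * exp(shared[1L] + stats::rnorm(1L, 0, sd_side))
    rd <- tissue$rd_true * exp(shared[2L] + stats::rnorm(1L, 0, sd_side))
    if (side == affected_side) {
      ad <- ad * spec$ad_effect
      rd <- rd * spec$rd_effect
    }
    rd <- min(rd, ad)   # jitter cannot cross the cylindrical constraint
    p[[side]] <- c(ad = ad, rd = rd)
  }
  p
}

# Deterministic affected-side assignment honouring the 13/19 right proportion.
assign_affected_sides <- function(spec) {
  if (spec$group == "healthy") return(rep("none", spec$n_subjects))
  if (spec$affected_side %in% c("left", "right")) {
    return(rep(spec$affected_side, spec$n_subjects))
  }
  n_right <- round(spec$n_subjects * 13 / 19)
  c(rep("right", n_right), rep("left", spec$n_subjects - n_right))
}

#' Generate one phantom subject
#'
#' @param params list with elements `left` and `right`, each `c(ad =, rd =)`.
#' @param tubes precomputed per-side tube geometry (see [generate_cohort()]);
#'   computed from `geometry` if `NULL`.
#' @param geometry list of two `nerve_geometry` objects (left, right).
#' @param tissue,scheme,grid_shape,affine,seed as in [generate_cohort()].
#' @return an object of class `phantom_subject` with fields `dwi`, `affine`,
#'   `truth_tensors`, `truth_masks`, `truth_params`, `seed`.
#' @export
generate_subject <- function(params, geometry, tissue, scheme,
                             grid_shape, affine = make_affine(0.4), seed = NULL,
                             tubes = NULL) {
  field <- build_tensor_field(geometry, tissue, grid_shape, affine,
                              ad = c(params$left["ad"], params$right["ad"]),
                              rd = c(params$left["rd"], params$right["rd"]),
                              tubes = tubes)
  dwi <- simulate_dwi(field$tensors, scheme, tissue, seed = seed)
  if (min(dwi) < 0) stop_bad("negative simulated signal")  # cannot happen; guard
  structure(list(dwi = dwi, affine = affine,
                 truth_tensors = field$tensors,
                 truth_masks = field$masks,
                 truth_params = params, seed = seed),
            class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  d <- dim(x$dwi)
  cat(sprintf("Phantom subject: %dx%dx%d grid, %d volumes, %d+%d nerve voxels\n",
              d[1], d[2], d[3], d[4],
              sum(x$truth_masks$left), sum(x$truth_masks$right)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject, per-side tissue parameters, applies the affected-side
#' effects, simulates each subject's DWI and returns the subjects (optionally
#' writing them to disk as NIfTI + FSL gradient tables) together with a
#' manifest table of realized ground-truth parameters.
#'
#' @param spec a `cohort_spec`.
#' @param scheme an `acquisition_scheme`.
#' @param tissue a `tissue_model`.
#' @param grid_shape integer length-3 voxel counts (default 64^3).
#' @param affine 4x4 voxel-to-world transform (default 0.4 mm isotropic).
#' @param geometry_args list of overrides passed to [make_centerline()].
#' @param out_dir if non-`NULL`, per-subject NIfTI volumes, gradient tables,
#'   truth masks and `manifest.csv` are written under it.
#' @param keep_volumes if `FALSE`, subject volumes are dropped after writing
#'   (requires `out_dir`); the manifest is always returned.
#' @return list with `subjects` (list of `phantom_subject`, or `NULL` ids if
#'   dropped), `manifest` (data.frame), `geometry`, `scheme`.
#' @export
generate_cohort <- function(spec, scheme = default_scheme(),
                            tissue = tissue_model(),
                            grid_shape = c(64L, 64L, 64L),
                            affine = make_affine(0.4),
                            geometry_args = list(), out_dir = NULL,
                            keep_volumes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!keep_volumes && is.null(out_dir)) {
    stop_bad("keep_volumes = FALSE requires out_dir")
  }
  geometry <- lapply(c("left", "right"), function(s) {
    do.call(make_centerline,
            c(list(side = s, grid_shape = grid_shape, affine = affine),
              geometry_args))
  })
  names(geometry) <- c("left", "right")
  tubes <- lapply(geometry, tube_geometry, grid_shape = grid_shape, affine = affine)
  sides <- assign_affected_sides(spec)
  seeds <- derive_seeds(spec$seed, spec$n_subjects + 1L)
  params <- with_seed(seeds[spec$n_subjects + 1L], {
    lapply(seq_len(spec$n_subjects), function(i) {
      draw_subject_params(spec, tissue, sides[i])
    })
  })
  subjects <- vector("list", spec$n_subjects)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(spec$n_subjects)) {
    subj <- generate_subject(params[[i]], geometry, tissue, scheme,
                             grid_shape, affine, seed = seeds[i], tubes = tubes)
    if (!is.null(out_dir)) write_subject(subj, scheme, out_dir, subject_tag(spec, i))
    subjects[[i]] <- if (keep_volumes) subj else NULL
  }
  manifest <- data.frame(
    subject_id = vapply(seq_len(spec$n_subjects), function(i) subject_tag(spec, i), ""),
    group = spec$group,
    affected_side = sides,
    ad_left = vapply(params, function(p) p$left[["ad"]], 0),
    rd_left = vapply(params, function(p) p$left[["rd"]], 0),
    ad_right = vapply(params, function(p) p$right[["ad"]], 0),
    rd_right = vapply(params, function(p) p$right[["rd"]], 0),
    seed = seeds[seq_len(spec$n_subjects)],
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(subjects = subjects, manifest = manifest, geometry = geometry, scheme = scheme)
}

subject_tag <- function(spec, i) {
  sprintf("%s%02d", if (spec$group == "healthy") "H" else "P", i)
}

write_subject <- function(subj, scheme, out_dir, tag) {
  dir.create(file.path(out_dir, tag), recursive = TRUE, showWarnings = FALSE)
  write_nifti(subj$dwi, subj$affine, file.path(out_dir, tag, "dwi.nii.gz"))
  write_bvalbvec(scheme, file.path(out_dir, tag, "bvals"),
                 file.path(out_dir, tag, "bvecs"))
  for (side in names(subj$truth_masks)) {
    write_nifti(subj$truth_masks[[side]] * 1L, subj$affine,
                file.path(out_dir, tag, sprintf("truth_mask_%s.nii.gz", side)),
                datatype = "uint8")
  }
  invisible(NULL)
}

#' Measurement-level cohort simulator
#'
#' Draws per-subject, per-side ground-truth diffusivities with the same
#' jitter and effect model as the imaging phantom, but returns the scalar
#' indexes computed analytically from the eigenvalue triple (ad, rd, rd)
#' instead of simulating, fitting and tracking images. This is the fast
#' null/power oracle for the statistics layer.
#'
#' @param spec a `cohort_spec`.
#' @param tissue a `tissue_model`.
#' @param seed optional override of `spec$seed`.
#' @return a measurements data.frame (columns `subject_id`, `group`, `mpm`,
#'   `side`, `role`, `fa`, `md`, `ad`, `rd`) as consumed by [build_tables()].
#' @export
simulate_index_cohort <- function(spec, tissue = tissue_model(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  sides <- assign_affected_sides(spec)
  seed <- seed %||% spec$seed
  params <- with_seed(seed, {
    lapply(seq_len(spec$n_subjects), function(i) {
      draw_subject_params(spec, tissue, sides[i])
    })
  })
  rows <- list()
  for (i in seq_len(spec$n_subjects)) {
    for (side in c("left", "right")) {
      p <- params[[i]][[side]]
      ix <- tensor_indices(p[["ad"]], p[["rd"]], p[["rd"]])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_tag(spec, i), group = spec$group, mpm = "truth",
        side = side,
        role = side_role(spec$group, side, sides[i]),
        fa = ix$fa, md = ix$md, ad = ix$ad, rd = ix$rd,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

side_role <- function(group, side, affected_side) {
  if (group == "healthy" || affected_side == "none") return(side)
  if (side == affected_side) "affected" else "healthy_side"
}
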