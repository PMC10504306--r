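# Shared fixtures, built once per session and cached.

.fx <- new.env(parent = emptyenv())

# Noiseless bilateral phantom on a 48^3 grid at 0.4 mm, with tensor fit,
# eigensystem, scalar maps, protocol seeds and tracked streamlines.
noiseless_phantom <- function() {
  if (is.null(.fx$np)) {
    gs <- c(48L, 48L, 48L)
    aff <- make_affine(0.4)
    tis <- tissue_model(sigma = 0)
    geom <- lapply(c(left = "left", right = "right"), function(s) {
      make_centerline(s, gs, aff)
    })
    field <- build_tensor_field(geom, tis, gs, aff)
    scheme <- default_scheme()
    dwi <- simulate_dwi(field$tensors, scheme, tis)
    fit <- fit_tensor(dwi, scheme)
    eigs <- eigendecompose(fit)
    scal <- scalar_maps(eigs)
    sc <- seed_centers_from_geometry(geom, c(0.35, 0.65))
    seeds <- make_seeds(sc$centers, sc$side, gs, aff)
    params <- track_params()
    streams <- track_all(seeds, eigs, scal$fa, params, aff)
    .fx$np <- list(grid_shape = gs, affine = aff, tissue = tis, geom = geom,
                   field = field, scheme = scheme, dwi = dwi, fit = fit,
                   eigs = eigs, scal = scal, seeds = seeds, params = params,
                   streams = streams)
  }
  .fx$np
}

# Internal helper re-exported for tests.
seed_centers_from_geometry <- facialdti:::seed_centers_from_geometry

# Hand-built eigen system: uniform principal direction `e1_fun(i, j, k)`
# (0-based voxel indices, vectorized), FA given by `fa_fun`.
synthetic_eigs <- function(grid_shape, e1_fun, fa_fun) {
  n <- prod(grid_shape)
  idx <- as.matrix(expand.grid(i = 0:(grid_shape[1] - 1L),
                               j = 0:(grid_shape[2] - 1L),
                               k = 0:(grid_shape[3] - 1L)))
  e1 <- e1_fun(idx[, 1], idx[, 2], idx[, 3])
  e1 <- e1 / sqrt(rowSums(e1^2))
  # complete an orthonormal frame (directions are axial; e2/e3 arbitrary)
  ref <- cbind(ifelse(abs(e1[, 1]) < 0.9, 1, 0),
               ifelse(abs(e1[, 1]) < 0.9, 0, 1), 0)
  e2 <- cbind(e1[, 2] * ref[, 3] - e1[, 3] * ref[, 2],
              e1[, 3] * ref[, 1] - e1[, 1] * ref[, 3],
              e1[, 1] * ref[, 2] - e1[, 2] * ref[, 1])
  e2 <- e2 / sqrt(rowSums(e2^2))
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vectors <- array(cbind(e1, e2, e3), c(grid_shape, 3L, 3L))
  values <- array(rep(c(1.7e-3, 0.3e-3, 0.3e-3), each = n), c(grid_shape, 3L))
  fa <- array(fa_fun(idx[, 1], idx[, 2], idx[, 3]), grid_shape)
  list(eigs = structure(list(values = values, vectors = vectors,
                             n_clamped_negative = 0L),
                        class = "eigen_system"),
       fa = fa)
}

# Random symmetric tensors with eigenvalues in a diffusivity-like range.
random_tensors <- function(n, seed = 1) {
  set.seed(seed)
  t(replicate(n, {
    lam <- sort(runif(3, 1e-4, 2e-3), decreasing = TRUE)
    a <- matrix(rnorm(9), 3)
    q <- qr.Q(qr(a))
    D <- q %*% diag(lam) %*% t(q)
    c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }))
}

# One patient-cohort pass through the full image-level pipeline
# (simulate -> fit -> track -> MPM -> extract -> paired tables) on a
# compact grid; returns the patient table (Table 2 analogue).
patient_replicate <- function(seed, n_subjects = 19L, grid_shape = c(44L, 44L, 44L),
                              rd_effect = NULL, ad_effect = NULL,
                              cache = NULL) {
  aff <- make_affine(0.4)
  tis <- tissue_model()
  if (is.null(cache)) cache <- patient_replicate_cache(grid_shape)
  spec <- cohort_spec(n_subjects, "patient", rd_effect = rd_effect,
                      ad_effect = ad_effect, seed = seed)
  sides <- facialdti:::assign_affected_sides(spec)
  sseeds <- facialdti:::derive_seeds(spec$seed, n_subjects + 1L)
  params <- facialdti:::with_seed(sseeds[n_subjects + 1L], {
    lapply(seq_len(n_subjects), function(i) {
      facialdti:::draw_subject_params(spec, tis, sides[i])
    })
  })
  res <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    subj <- generate_subject(params[[i]], cache$geom, tis, cache$scheme,
                             grid_shape, aff, seed = sseeds[i],
                             tubes = cache$tubes)
    fit <- fit_tensor(subj$dwi, cache$scheme)
    eigs <- eigendecompose(fit)
    scal <- scalar_maps(eigs)
    st <- track_all(cache$seeds, eigs, scal$fa, track_params(), aff)
    res[[i]] <- list(scal = scal,
                     lab = suppressWarnings(voxelize_streamlines(st, grid_shape, aff)))
  }
  mpm <- build_mpm(lapply(res, `[[`, "lab"))
  meas <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    extract_indices(res[[i]]$scal, mpm, sprintf("P%02d", i), "patient",
                    sides[i], "patient")
  }))
  build_tables(meas)$table2
}

patient_replicate_cache <- function(grid_shape = c(44L, 44L, 44L)) {
  key <- paste(grid_shape, collapse = "x")
  if (is.null(.fx$prc) || !identical(.fx$prc$key, key)) {
    aff <- make_affine(0.4)
    geom <- lapply(c(left = "left", right = "right"), function(s) {
      make_centerline(s, grid_shape, aff)
    })
    tubes <- lapply(geom, facialdti:::tube_geometry,
                    grid_shape = grid_shape, affine = aff)
    sc <- seed_centers_from_geometry(geom, c(0.35, 0.65))
    .fx$prc <- list(key = key, geom = geom, tubes = tubes,
                    scheme = default_scheme(),
                    seeds = make_seeds(sc$centers, sc$side, grid_shape, aff))
  }
  .fx$prc
}
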