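# Configuration and end-to-end orchestration:
# simulate -> fit -> track -> MPM -> extract -> stats.

#' Default pipeline configuration
#'
#' Nested list of every stage's parameters. Tracking thresholds default to
#' the nerve protocol values (FA 0.15, angle 60 degrees, minimum length
#' 2 mm, 5 mm seed spheres, 0.4 mm common grid); cohort sizes default to 18
#' healthy and 19 patient subjects.
#'
#' @param ... named overrides merged recursively into the defaults, e.g.
#'   `phantom = list(grid_shape = c(40, 40, 40))`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    phantom = list(
      n_healthy = 18L, n_patient = 19L,
      affected_side = "split",
      rd_effect = 0.00088 / 0.00078, ad_effect = 1.0,
      between_subject_sd = 0.08, between_side_correlation = 0.6,
      ad_true = 1.20e-3, rd_true = 0.78e-3, iso_background = 1.0e-3,
      s0 = 1000, snr = 30,
      grid_shape = c(64L, 64L, 64L), voxel_size = 0.4,
      native_grid = FALSE,
      native_voxel = c(1.2, 1.2, 3.0), native_shape = c(22L, 22L, 12L),
      n_dirs = 20L, bvalue = 1000,
      tube_radius = 0.8, arc_radius = 20, lateral_frac = 0.24,
      tract_length = NULL
    ),
    tracking = list(
      fa_threshold = 0.15, angle_threshold = 60, min_length = 2.0,
      step_size = 0.2, max_steps = 2000L,
      seed_diameter = 5, seeds_per_side = 2L, seed_fracs = c(0.35, 0.65),
      seed_density = 1L
    ),
    mpm = list(rule = "strict_majority"),
    stats = list(alpha = 0.05)
  )
  cfg <- modify_defaults(defaults, list(...))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

modify_defaults <- function(defaults, overrides) {
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  tr <- cfg$tracking
  stopifnot(tr$fa_threshold > 0, tr$fa_threshold < 1,
            tr$angle_threshold > 0, tr$angle_threshold < 180,
            tr$min_length > 0, tr$step_size > 0, tr$seed_diameter > 0)
  ph <- cfg$phantom
  stopifnot(ph$n_healthy >= 2, ph$n_patient >= 2, ph$voxel_size > 0,
            ph$s0 > 0, ph$snr > 0, length(ph$grid_shape) == 3L)
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' The file may specify any subset of the [pipeline_config()] fields under
#' the top-level blocks `phantom`, `tracking`, `mpm`, `stats` plus `seed`;
#' missing fields keep their defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_tissue <- function(ph) {
  tissue_model(ad_true = ph$ad_true, rd_true = ph$rd_true,
               iso_background = ph$iso_background, s0 = ph$s0,
               sigma = ph$s0 / ph$snr)
}

config_geometry_args <- function(ph) {
  list(tube_radius = ph$tube_radius, arc_radius = ph$arc_radius,
       lateral_frac = ph$lateral_frac, tract_length = ph$tract_length)
}

# Seed sphere centers: `seeds_per_side` points along each side's centerline
# at the configured arc fractions, mirroring the bilateral, symmetric
# placement of the protocol's four 5 mm spheres.
seed_centers_from_geometry <- function(geometry, fracs) {
  centers <- list(); side <- character()
  for (s in names(geometry)) {
    cl <- geometry[[s]]$centerline
    idx <- pmax(1L, pmin(nrow(cl), round(fracs * (nrow(cl) - 1L)) + 1L))
    centers[[s]] <- cl[idx, , drop = FALSE]
    side <- c(side, rep(s, length(idx)))
  }
  list(centers = do.call(rbind, centers), side = side)
}

# One subject through simulate (+ optional native-grid resampling), tensor
# fit, eigendecomposition, scalar maps, tracking and voxelization.
process_subject <- function(params, geometry, tissue, scheme, grid_shape,
                            affine, seeds, tparams, subj_seed, cfg, tubes) {
  ph <- cfg$phantom
  if (isTRUE(ph$native_grid)) {
    native_affine <- make_affine(ph$native_voxel)
    native_geom <- geometry$native
    subj <- generate_subject(params, native_geom, tissue, scheme,
                             ph$native_shape, native_affine, seed = subj_seed,
                             tubes = tubes)
    res <- resample_to_grid(subj$dwi, native_affine, ph$voxel_size)
    dwi <- res$data
    stopifnot(identical(as.integer(dim(dwi)[1:3]), as.integer(grid_shape)))
  } else {
    subj <- generate_subject(params, geometry$common, tissue, scheme,
                             grid_shape, affine, seed = subj_seed,
                             tubes = tubes)
    dwi <- subj$dwi
  }
  fit <- fit_tensor(dwi, scheme)
  eigs <- eigendecompose(fit)
  scal <- scalar_maps(eigs)
  streams <- track_all(seeds, eigs, scal$fa, tparams, affine)
  labels <- suppressWarnings(voxelize_streamlines(streams, grid_shape, affine))
  list(scalars = scal, labels = labels,
       qc = c(clamped = fit$n_clamped, negative_eigs = eigs$n_clamped_negative,
              fibers = length(streams$streamlines),
              short_discarded = streams$n_discarded_short))
}

#' Run the full analysis pipeline
#'
#' Simulates the healthy and patient cohorts, fits tensors, tracks both
#' nerves per subject, fuses the tract maps into the three group MPMs,
#' extracts MPM-based FA/MD/AD/RD per subject and side, checks normality
#' and builds the three comparison tables. Deterministic given `config$seed`.
#'
#' @param config a `pipeline_config`.
#' @param out_dir if non-`NULL`, writes `measurements.csv`,
#'   `table1.csv`-`table3.csv`, MPM label/support NIfTI volumes and a YAML
#'   run manifest under it.
#' @return list with `tables`, `measurements` (data.frame), `mpms`,
#'   `manifests` (per-cohort ground-truth tables), `ks` (normality checks),
#'   `qc`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ph <- config$phantom
  tr <- config$tracking
  tissue <- config_tissue(ph)
  scheme <- default_scheme(ph$n_dirs, ph$bvalue)
  if (isTRUE(ph$native_grid)) {
    # the common grid is the isotropic resampling target of the native FOV
    tgt <- target_grid(as.integer(ph$native_shape), make_affine(ph$native_voxel),
                       ph$voxel_size)
    grid_shape <- tgt$shape
    affine <- tgt$affine
  } else {
    affine <- make_affine(ph$voxel_size)
    grid_shape <- as.integer(ph$grid_shape)
  }
  geom_args <- config_geometry_args(ph)
  common_geom <- lapply(c(left = "left", right = "right"), function(s) {
    do.call(make_centerline,
            c(list(side = s, grid_shape = grid_shape, affine = affine), geom_args))
  })
  geometry <- list(common = common_geom)
  if (isTRUE(ph$native_grid)) {
    native_affine <- make_affine(ph$native_voxel)
    geometry$native <- lapply(c(left = "left", right = "right"), function(s) {
      do.call(make_centerline,
              c(list(side = s, grid_shape = as.integer(ph$native_shape),
                     affine = native_affine), geom_args))
    })
  }
  sim_geom <- if (isTRUE(ph$native_grid)) geometry$native else common_geom
  sim_affine <- if (isTRUE(ph$native_grid)) make_affine(ph$native_voxel) else affine
  sim_shape <- if (isTRUE(ph$native_grid)) as.integer(ph$native_shape) else grid_shape
  tubes <- lapply(sim_geom, tube_geometry, grid_shape = sim_shape, affine = sim_affine)
  sc <- seed_centers_from_geometry(common_geom, tr$seed_fracs)
  seeds <- make_seeds(sc$centers, sc$side, grid_shape, affine,
                      diameter = tr$seed_diameter, density = tr$seed_density,
                      seed = config$seed)
  tparams <- track_params(tr$fa_threshold, tr$angle_threshold, tr$min_length,
                          tr$step_size, tr$max_steps)

  cohort_seeds <- derive_seeds(config$seed, 2L)
  specs <- list(
    healthy = cohort_spec(ph$n_healthy, "healthy",
                          between_subject_sd = ph$between_subject_sd,
                          between_side_correlation = ph$between_side_correlation,
                          seed = cohort_seeds[1L]),
    patient = cohort_spec(ph$n_patient, "patient",
                          affected_side = ph$affected_side,
                          rd_effect = ph$rd_effect, ad_effect = ph$ad_effect,
                          between_subject_sd = ph$between_subject_sd,
                          between_side_correlation = ph$between_side_correlation,
                          seed = cohort_seeds[2L])
  )
  results <- list(); manifests <- list(); qc <- list()
  for (grp in names(specs)) {
    spec <- specs[[grp]]
    sides <- assign_affected_sides(spec)
    sseeds <- derive_seeds(spec$seed, spec$n_subjects + 1L)
    params <- with_seed(sseeds[spec$n_subjects + 1L], {
      lapply(seq_len(spec$n_subjects), function(i) {
        draw_subject_params(spec, tissue, sides[i])
      })
    })
    subj_res <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      subj_res[[i]] <- process_subject(params[[i]], geometry, tissue, scheme,
                                       grid_shape, affine, seeds, tparams,
                                       sseeds[i], config, tubes)
    }
    results[[grp]] <- list(spec = spec, sides = sides, subjects = subj_res)
    manifests[[grp]] <- data.frame(
      subject_id = vapply(seq_along(params), function(i) subject_tag(spec, i), ""),
      group = grp, affected_side = sides,
      ad_left = vapply(params, function(p) p$left[["ad"]], 0),
      rd_left = vapply(params, function(p) p$left[["rd"]], 0),
      ad_right = vapply(params, function(p) p$right[["ad"]], 0),
      rd_right = vapply(params, function(p) p$right[["rd"]], 0),
      seed = sseeds[seq_along(params)], stringsAsFactors = FALSE
    )
    qc[[grp]] <- Reduce(`+`, lapply(subj_res, `[[`, "qc"))
  }

  mpms <- named_mpms(lapply(results$healthy$subjects, `[[`, "labels"),
                     lapply(results$patient$subjects, `[[`, "labels"))

  extract_group <- function(grp, mpm_names) {
    res <- results[[grp]]
    rows <- list()
    for (i in seq_along(res$subjects)) {
      for (mp in mpm_names) {
        rows[[length(rows) + 1L]] <- extract_indices(
          res$subjects[[i]]$scalars, mpms[[mp]],
          subject_id = subject_tag(res$spec, i), group = grp,
          affected_side = res$sides[i], mpm_name = mp)
      }
    }
    do.call(rbind, rows)
  }
  measurements <- rbind(extract_group("healthy", c("health", "all")),
                        extract_group("patient", c("patient", "all")))

  ks <- ks_by_cell(measurements)
  tables <- build_tables(measurements, pooled_mpm = "all")

  manifest <- list(
    parameters = unclass(config),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    qc = lapply(qc, as.list),
    n_subjects = vapply(specs, `[[`, 0L, "n_subjects"),
    ks_min_p = if (nrow(ks)) min(ks$p) else NA_real_,
    warnings = if (any(is.na(measurements$fa))) "empty MPM labels present" else character()
  )
  out <- list(tables = tables, measurements = measurements, mpms = mpms,
              manifests = manifests, ks = ks, qc = qc, manifest = manifest,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, affine)
  out
}

# K-S normality check per (group, mpm, role, index) cell with n >= 5.
ks_by_cell <- function(measurements) {
  cells <- unique(measurements[, c("group", "mpm", "role")])
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    sel <- measurements$group == cells$group[r] &
      measurements$mpm == cells$mpm[r] & measurements$role == cells$role[r]
    for (ix in index_cols) {
      v <- measurements[[ix]][sel]
      v <- v[is.finite(v)]
      if (length(v) < 5L) next
      kt <- tryCatch(ks_normality(v), error = function(e) NULL)
      if (is.null(kt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = cells$group[r], mpm = cells$mpm[r], role = cells$role[r],
        index = ix, statistic = kt$statistic, p = kt$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(group = character(), mpm = character(), role = character(),
                      index = character(), statistic = numeric(), p = numeric()))
  }
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(out, out_dir, affine) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(out$measurements, file.path(out_dir, "measurements.csv"))
  for (tb in c("table1", "table2", "table3")) {
    if (!is.null(out$tables[[tb]])) {
      write_table_csv(out$tables[[tb]], file.path(out_dir, paste0(tb, ".csv")))
    }
  }
  for (mp in names(out$mpms)) {
    write_nifti(out$mpms[[mp]]$labels, affine,
                file.path(out_dir, sprintf("mpm_%s_labels.nii.gz", mp)),
                datatype = "uint8")
    write_nifti(out$mpms[[mp]]$support, affine,
                file.path(out_dir, sprintf("mpm_%s_support.nii.gz", mp)),
                datatype = "int16")
  }
  for (grp in names(out$manifests)) {
    write_table_csv(out$manifests[[grp]],
                    file.path(out_dir, sprintf("truth_%s.csv", grp)))
  }
  write_table_csv(out$ks, file.path(out_dir, "ks_normality.csv"))
  yaml::write_yaml(out$manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(out_dir)
}
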