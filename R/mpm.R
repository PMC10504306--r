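# Streamline voxelization and maximum probability map (MPM) construction by
# strict majority voting across subjects.

#' Voxelize a streamline set into per-side binary label maps
#'
#' A voxel is labeled for a side iff any retained streamline of that side
#' has a point inside it (half-open voxel ownership). With a tracking step
#' of half a voxel, point membership is a faithful rasterization.
#'
#' @param streams a `streamline_set`.
#' @param grid_shape integer length-3 voxel counts.
#' @param affine 4x4 voxel-to-world transform.
#' @param sides side labels to produce maps for.
#' @return an object of class `subject_label_map`: a named list of logical
#'   arrays, one per side.
#' @export
voxelize_streamlines <- function(streams, grid_shape, affine = make_affine(0.4),
                                 sides = c("left", "right")) {
  stopifnot(inherits(streams, "streamline_set"))
  maps <- lapply(sides, function(s) array(FALSE, grid_shape))
  names(maps) <- sides
  if (length(streams$streamlines) == 0L) {
    warning("empty streamline set: label map is all zero", call. = FALSE)
  } else {
    for (i in seq_along(streams$streamlines)) {
      s <- streams$side[i]
      if (!s %in% sides) next
      vox <- owning_voxel(streams$streamlines[[i]], affine)
      ok <- voxel_in_grid(vox, grid_shape)
      idx <- voxel_linear_index(vox[ok, , drop = FALSE], grid_shape)
      maps[[s]][idx] <- TRUE
    }
  }
  structure(maps, class = "subject_label_map")
}

#' Fuse subject label maps into a maximum probability map
#'
#' Per voxel, subjects vote for each side they visit. A side label is
#' assigned iff its vote count exceeds half the number of subjects (strict
#' majority); when both sides exceed half (possible because one subject can
#' carry both labels at a voxel), the larger count wins and an exact tie
#' falls back to background. The support volume records the winning count.
#'
#' @param maps list of `subject_label_map`, all on one grid.
#' @return an object of class `max_probability_map`: `labels` (integer
#'   array, 0 = background, 1 = left, 2 = right), `support` (integer array),
#'   `n_subjects`, `sides`.
#' @export
build_mpm <- function(maps) {
  stopifnot(length(maps) >= 1L)
  sides <- names(maps[[1L]])
  grid_shape <- dim(maps[[1L]][[1L]])
  for (m in maps) {
    if (!identical(names(m), sides)) stop_bad("subject maps carry different side labels")
    for (s in sides) {
      if (!identical(dim(m[[s]]), grid_shape)) {
        stop_bad("subject maps are on different grids: %s vs %s",
                 paste(grid_shape, collapse = "x"),
                 paste(dim(m[[s]]), collapse = "x"))
      }
    }
  }
  n <- length(maps)
  counts <- lapply(sides, function(s) {
    Reduce(`+`, lapply(maps, function(m) m[[s]] * 1L))
  })
  names(counts) <- sides
  labels <- array(0L, grid_shape)
  support <- array(0L, grid_shape)
  half <- n / 2
  stopifnot(length(sides) == 2L)
  c1 <- counts[[1L]]; c2 <- counts[[2L]]
  win1 <- c1 > half & c1 > c2
  win2 <- c2 > half & c2 > c1
  # both above half and equal -> exact tie -> background
  labels[win1] <- 1L
  labels[win2] <- 2L
  support[win1] <- c1[win1]
  support[win2] <- c2[win2]
  structure(list(labels = labels, support = support, n_subjects = n,
                 sides = sides),
            class = "max_probability_map")
}

#' @export
print.max_probability_map <- function(x, ...) {
  cat(sprintf("MPM over %d subjects: %d %s + %d %s voxels\n",
              x$n_subjects, sum(x$labels == 1L), x$sides[1],
              sum(x$labels == 2L), x$sides[2]))
  invisible(x)
}

#' Build the three named group MPMs
#'
#' The healthy-only, patient-only and pooled maps (for cohorts of 18 and 19
#' these are the 18-Health-MPM, 19-Patient-MPM and 37-All-MPM).
#'
#' @param healthy_maps,patient_maps lists of `subject_label_map`.
#' @return named list of `max_probability_map`: `health`, `patient`, `all`.
#' @export
named_mpms <- function(healthy_maps, patient_maps) {
  if (length(healthy_maps) == 0L || length(patient_maps) == 0L) {
    stop_bad("both cohorts must be non-empty to build the three group MPMs")
  }
  list(health = build_mpm(healthy_maps),
       patient = build_mpm(patient_maps),
       all = build_mpm(c(healthy_maps, patient_maps)))
}

# Linear voxel indices of one side's label in an MPM.
mpm_side_index <- function(mpm, side) {
  code <- match(side, mpm$sides)
  if (is.na(code)) stop_bad("unknown side label '%s'", side)
  which(mpm$labels == code)
}
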