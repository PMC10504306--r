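# MPM-based scalar extraction and the group statistics layer: K-S normality
# checks, paired and pooled-variance unpaired two-tailed t-tests, and the
# three comparison tables of a bilateral / affected-vs-healthy nerve study.

#' Extract MPM-based scalar indexes for one subject
#'
#' Per side label of the MPM, the arithmetic mean of each scalar map over
#' all voxels carrying that label (the subject's own maps sampled over the
#' common MPM region).
#'
#' @param scalars a `scalar_maps` for the subject.
#' @param mpm a `max_probability_map` on the same grid.
#' @param subject_id,group identifiers copied into the output.
#' @param affected_side `"left"`, `"right"` or `"none"`; determines the
#'   `role` column (`affected` / `healthy_side` for patients, the side label
#'   otherwise).
#' @param mpm_name label recorded in the `mpm` column.
#' @return a measurements data.frame with one row per side: columns
#'   `subject_id`, `group`, `mpm`, `side`, `role`, `fa`, `md`, `ad`, `rd`,
#'   `n_voxels`. Empty labels yield `NA` values with a warning.
#' @export
extract_indices <- function(scalars, mpm, subject_id, group,
                            affected_side = "none", mpm_name = "mpm") {
  stopifnot(inherits(scalars, "scalar_maps"), inherits(mpm, "max_probability_map"))
  if (!identical(dim(scalars$fa), dim(mpm$labels))) {
    stop_bad("scalar maps (%s) and MPM (%s) are on different grids",
             paste(dim(scalars$fa), collapse = "x"),
             paste(dim(mpm$labels), collapse = "x"))
  }
  rows <- lapply(mpm$sides, function(side) {
    idx <- mpm_side_index(mpm, side)
    if (length(idx) == 0L) {
      warning(sprintf("empty MPM label '%s' for subject %s", side, subject_id),
              call. = FALSE)
      vals <- c(fa = NA_real_, md = NA_real_, ad = NA_real_, rd = NA_real_)
    } else {
      vals <- c(fa = mean(scalars$fa[idx]), md = mean(scalars$md[idx]),
                ad = mean(scalars$ad[idx]), rd = mean(scalars$rd[idx]))
    }
    data.frame(subject_id = subject_id, group = group, mpm = mpm_name,
               side = side, role = side_role(group, side, affected_side),
               fa = vals[["fa"]], md = vals[["md"]], ad = vals[["ad"]],
               rd = vals[["rd"]], n_voxels = length(idx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-tailed p-value from a t statistic
#'
#' @param t t statistic.
#' @param df degrees of freedom.
#' @return two-tailed probability.
#' @export
p_from_t <- function(t, df) {
  2 * stats::pt(-abs(t), df)
}

new_ttest_result <- function(t, df, kind) {
  structure(list(t = t, df = df, p = p_from_t(t, df), kind = kind),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.3f, df = %g, two-tailed p = %.4g\n",
              x$kind, x$t, x$df, x$p))
  invisible(x)
}

#' Paired two-tailed t-test
#'
#' t = mean(d) / (sd(d) / sqrt(n)) on the differences d = x - y, df = n - 1.
#' Identical samples give t = 0, p = 1.
#'
#' @param x,y paired samples of equal length (n >= 2).
#' @return a `ttest_result` (fields `t`, `df`, `p`, `kind`).
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) {
    stop_bad("paired samples differ in length (%d vs %d)", length(x), length(y))
  }
  n <- length(x)
  if (n < 2L) stop_bad("paired t-test needs at least 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(new_ttest_result(0, n - 1L, "paired"))
    stop_bad("zero variance of non-zero paired differences")
  }
  new_ttest_result(mean(d) / (s / sqrt(n)), n - 1L, "paired")
}

#' Unpaired two-sample t-test with pooled variance
#'
#' Student's t with pooled variance and df = n1 + n2 - 2 (not Welch): the
#' convention consistent with the printed table degrees of freedom of the
#' facial-nerve comparisons (df 53 and 72).
#'
#' @param x,y independent samples (each n >= 2).
#' @return a `ttest_result`.
#' @export
unpaired_ttest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop_bad("each sample needs at least 2 observations")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(new_ttest_result(0, n1 + n2 - 2L, "unpaired-pooled"))
    stop_bad("zero pooled variance with unequal means")
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  new_ttest_result(t, n1 + n2 - 2L, "unpaired-pooled")
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests the sample against a normal distribution with the sample's own mean
#' and SD. The classical K-S p-value is reported; with estimated parameters
#' it is anti-conservative (a Lilliefors correction would be stricter), so a
#' large p here is a weak sanity check rather than proof of normality.
#'
#' @param values numeric sample, n >= 5, non-constant.
#' @return an object of class `ks_result` with `statistic` (sup-distance)
#'   and `p`.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop_bad("K-S normality check needs at least 5 values")
  s <- stats::sd(values)
  if (s == 0) stop_bad("constant sample: normality is undefined")
  kt <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values), s))
  structure(list(statistic = unname(kt$statistic), p = kt$p.value),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("K-S normality: D = %.4f, p = %.4g\n", x$statistic, x$p))
  invisible(x)
}

index_cols <- c("fa", "md", "ad", "rd")

# Wide per-subject frame (one row per subject) for one (group, mpm, role).
pivot_role <- function(measurements, grp, mpm_label, role_label) {
  m <- measurements[measurements$group == grp & measurements$mpm == mpm_label &
                      measurements$role == role_label, , drop = FALSE]
  m[order(m$subject_id), , drop = FALSE]
}

summ <- function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))

# Missing extractions (empty MPM labels) drop to complete data; cells with
# fewer than 2 usable observations report NA statistics instead of failing.
comparison_row <- function(index, mpm_label, x, y, labels, paired) {
  if (paired) {
    ok <- is.finite(x) & is.finite(y)
    x_use <- x[ok]; y_use <- y[ok]
  } else {
    x_use <- x[is.finite(x)]; y_use <- y[is.finite(y)]
  }
  tt <- if (length(x_use) >= 2L && length(y_use) >= 2L) {
    if (paired) paired_ttest(x_use, y_use) else unpaired_ttest(x_use, y_use)
  } else {
    list(t = NA_real_, df = NA_real_, p = NA_real_,
         kind = if (paired) "paired" else "unpaired-pooled")
  }
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  sd_or_na <- function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_
  data.frame(index = index, mpm = mpm_label,
             group_x = labels[1], mean_x = mean_or_na(x_use),
             sd_x = sd_or_na(x_use), n_x = length(x_use),
             group_y = labels[2], mean_y = mean_or_na(y_use),
             sd_y = sd_or_na(y_use), n_y = length(y_use),
             t = tt$t, df = tt$df, p = tt$p, kind = tt$kind,
             stringsAsFactors = FALSE)
}

paired_row <- function(index, mpm_label, x, y, labels) {
  comparison_row(index, mpm_label, x, y, labels, paired = TRUE)
}

unpaired_row <- function(index, mpm_label, x, y, labels) {
  comparison_row(index, mpm_label, x, y, labels, paired = FALSE)
}

#' Build the three group-comparison tables
#'
#' * Table 1 analogue: healthy subjects, left vs right (paired), one block
#'   per MPM the healthy measurements were extracted under.
#' * Table 2 analogue: patients, healthy side vs affected side (paired),
#'   one block per patient MPM; t is oriented healthy-side minus affected.
#' * Table 3 analogue (pooled-MPM extractions only): patients' healthy-side
#'   nerves (N1) vs healthy people's pooled bilateral nerves (N3), and
#'   patients' affected nerves (N2) vs N4 = N3 + N1, both unpaired with
#'   pooled variance.
#'
#' All tests are two-tailed; diffusivities are carried in mm^2/s (use
#' [format_tables()] for the display convention of MD in 1e-3 mm^2/s).
#'
#' @param measurements long data.frame as produced by [extract_indices()] or
#'   [simulate_index_cohort()].
#' @param pooled_mpm the `mpm` label holding the pooled-map extraction used
#'   for the Table 3 analogue (default `"all"`, falling back to the single
#'   available label).
#' @return list of data.frames `table1`, `table2`, `table3`.
#' @export
build_tables <- function(measurements, pooled_mpm = NULL) {
  stopifnot(all(c("subject_id", "group", "mpm", "role", index_cols) %in%
                  names(measurements)))
  has_healthy <- any(measurements$group == "healthy")
  has_patient <- any(measurements$group == "patient")
  if (!has_healthy && !has_patient) stop_bad("no measurements")
  mpms <- unique(measurements$mpm)
  pooled_mpm <- pooled_mpm %||% (if ("all" %in% mpms) "all" else mpms[[1L]])

  table1 <- NULL
  if (has_healthy) {
    h_mpms <- unique(measurements$mpm[measurements$group == "healthy"])
    rows <- list()
    for (mp in h_mpms) {
      left <- pivot_role(measurements, "healthy", mp, "left")
      right <- pivot_role(measurements, "healthy", mp, "right")
      stopifnot(identical(left$subject_id, right$subject_id))
      for (ix in index_cols) {
        rows[[length(rows) + 1L]] <-
          paired_row(ix, mp, left[[ix]], right[[ix]], c("left", "right"))
      }
    }
    table1 <- do.call(rbind, rows)
  }

  table2 <- NULL
  if (has_patient) {
    p_mpms <- unique(measurements$mpm[measurements$group == "patient"])
    rows <- list()
    for (mp in p_mpms) {
      hs <- pivot_role(measurements, "patient", mp, "healthy_side")
      af <- pivot_role(measurements, "patient", mp, "affected")
      stopifnot(identical(hs$subject_id, af$subject_id))
      for (ix in index_cols) {
        rows[[length(rows) + 1L]] <-
          paired_row(ix, mp, hs[[ix]], af[[ix]], c("healthy_side", "affected"))
      }
    }
    table2 <- do.call(rbind, rows)
  }

  table3 <- NULL
  if (has_healthy && has_patient && pooled_mpm %in% mpms) {
    n1 <- pivot_role(measurements, "patient", pooled_mpm, "healthy_side")
    n2 <- pivot_role(measurements, "patient", pooled_mpm, "affected")
    h <- measurements[measurements$group == "healthy" &
                        measurements$mpm == pooled_mpm, , drop = FALSE]
    rows <- list()
    for (ix in index_cols) {
      n3 <- h[[ix]]                       # both sides of healthy people
      n4 <- c(n3, n1[[ix]])               # plus patients' healthy sides
      rows[[length(rows) + 1L]] <-
        unpaired_row(ix, pooled_mpm, n1[[ix]], n3, c("N1_patient_healthy_side", "N3_healthy_nerves"))
      rows[[length(rows) + 1L]] <-
        unpaired_row(ix, pooled_mpm, n2[[ix]], n4, c("N2_patient_affected", "N4_healthy_plus_N1"))
    }
    table3 <- do.call(rbind, rows)
  }

  list(table1 = table1, table2 = table2, table3 = table3)
}

#' Format comparison tables for display
#'
#' Applies the reporting conventions: MD scaled to 1e-3 mm^2/s, FA/t/p to
#' 3 decimals, diffusivities to 5 significant figures, mean +/- SD columns.
#'
#' @param tab one data.frame from [build_tables()].
#' @return a character-formatted data.frame.
#' @export
format_tables <- function(tab) {
  if (is.null(tab)) return(NULL)
  fmt_val <- function(index, m, s) {
    scale <- ifelse(index == "md", 1e3, 1)
    ifelse(index %in% c("md", "ad", "rd"),
           sprintf("%.5g ± %.5g", m * scale, s * scale),
           sprintf("%.3f ± %.3f", m, s))
  }
  data.frame(index = toupper(tab$index), mpm = tab$mpm,
             x = sprintf("%s (n=%d)", tab$group_x, tab$n_x),
             value_x = fmt_val(tab$index, tab$mean_x, tab$sd_x),
             y = sprintf("%s (n=%d)", tab$group_y, tab$n_y),
             value_y = fmt_val(tab$index, tab$mean_y, tab$sd_y),
             p_t = sprintf("%.3f (t = %.3f)", tab$p, tab$t),
             stringsAsFactors = FALSE)
}
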