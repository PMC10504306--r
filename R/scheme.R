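# Diffusion acquisition scheme: b-values and unit gradient directions.

#' Construct and validate an acquisition scheme
#'
#' An acquisition scheme pairs one b-value (s/mm^2) with one gradient
#' direction per acquired volume. Directions of diffusion-weighted volumes
#' must be unit vectors; b = 0 volumes carry the zero vector. A tensor fit
#' needs at least one b = 0 volume and six non-collinear weighted directions.
#'
#' @param bvals numeric vector of b-values, s/mm^2, one per volume.
#' @param bvecs n x 3 matrix of direction cosines, one row per volume.
#' @return an object of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- to_points_matrix(bvecs)
  if (length(bvals) != nrow(bvecs)) {
    stop_bad("scheme has %d b-values but %d directions", length(bvals), nrow(bvecs))
  }
  if (any(bvals < 0)) stop_bad("negative b-value in scheme")
  if (sum(bvals == 0) < 1L) stop_bad("scheme needs at least one b = 0 volume")
  if (sum(bvals > 0) < 6L) stop_bad("scheme needs at least 6 diffusion-weighted volumes")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[bvals > 0] - 1) > 1e-6)) {
    stop_bad("non-unit gradient direction for a b > 0 volume (|g| deviates by > 1e-6)")
  }
  if (any(nrm[bvals == 0] > 1e-6)) {
    stop_bad("b = 0 volumes must carry the zero direction vector")
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf(
    "Acquisition scheme: %d volumes (%d b=0, %d weighted), b up to %g s/mm^2\n",
    length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0), max(x$bvals)
  ))
  invisible(x)
}

#' Default 20-direction scheme
#'
#' One b = 0 volume followed by `n_dirs` electrostatically spread unit
#' directions at a single shell (default b = 1000 s/mm^2), mirroring a
#' clinical single-shell nerve protocol.
#'
#' @param n_dirs number of diffusion-weighted directions.
#' @param bvalue shell b-value, s/mm^2.
#' @return an `acquisition_scheme`.
#' @export
default_scheme <- function(n_dirs = 20L, bvalue = 1000) {
  dirs <- spread_directions(n_dirs)
  acquisition_scheme(
    bvals = c(0, rep(bvalue, n_dirs)),
    bvecs = rbind(c(0, 0, 0), dirs)
  )
}

#' Electrostatically spread unit directions
#'
#' Deterministic minimisation of the antipodally symmetric Coulomb energy
#' sum over pairs of 1/d^2 (each point interacting with the others and their
#' antipodes), starting from a Fibonacci hemisphere and descending with a
#' fixed step schedule. No RNG is used, so the set is reproducible across
#' platforms and sessions.
#'
#' @param n number of directions.
#' @param iterations descent iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
spread_directions <- function(n, iterations = 400L) {
  stopifnot(n >= 6L)
  # Fibonacci hemisphere start (z > 0)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n
  r <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(r * cos(phi), r * sin(phi), z)
  step <- 0.05
  energy <- function(p) {
    e <- 0
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      d1 <- sum((p[a, ] - p[b, ])^2)
      d2 <- sum((p[a, ] + p[b, ])^2)
      e <- e + 1 / d1 + 1 / d2
    }
    e
  }
  e_old <- energy(p)
  for (it in seq_len(iterations)) {
    grad <- matrix(0, n, 3L)
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        d <- p[a, ] - p[b, ]
        s <- p[a, ] + p[b, ]
        g1 <- -2 * d / sum(d^2)^2    # d/dp_a of 1/|d|^2
        g2 <- -2 * s / sum(s^2)^2
        grad[a, ] <- grad[a, ] + g1 + g2
        grad[b, ] <- grad[b, ] - g1 + g2
      }
    }
    cand <- p - step * grad
    cand <- cand / sqrt(rowSums(cand^2))
    e_new <- energy(cand)
    if (e_new < e_old) {
      p <- cand
      e_old <- e_new
      step <- step * 1.1
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  p
}

#' Read an FSL-style gradient table
#'
#' `bvals` is a single whitespace-separated row of b-values; `bvecs` holds
#' three rows (x, y, z) of direction components, one column per volume.
#'
#' @param bval_path,bvec_path file paths.
#' @return an `acquisition_scheme`.
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3L) stop_bad("bvec file must have 3 rows, found %d", nrow(bv))
  if (ncol(bv) != length(bvals)) {
    stop_bad("bvec columns (%d) do not match bval count (%d)", ncol(bv), length(bvals))
  }
  acquisition_scheme(bvals, t(bv))
}

#' Write an FSL-style gradient table
#'
#' @param scheme an `acquisition_scheme`.
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the two paths.
#' @export
write_bvalbvec <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval_path)
  bv <- t(scheme$bvecs)
  writeLines(apply(bv, 1L, function(r) paste(format(r, digits = 10, trim = TRUE), collapse = " ")),
             bvec_path)
  invisible(c(bval_path, bvec_path))
}
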