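# Pocket geometry: distance series and densities, hydrogen-bond occupancy,
# triangle-area collective variables and 2D free-energy landscapes.

#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCAL <- 0.0019872

#' Per-frame distance between two atoms
#'
#' @param ensemble an `md_ensemble`.
#' @param a,b atom references (see [resolve_atom_ref()]).
#' @param motif optional `motif_mapping` for relative labels like `"R+2:NE"`.
#' @return numeric vector of per-frame distances, Angstrom.
#' @export
distance_series <- function(ensemble, a, b, motif = NULL) {
  ia <- resolve_atom_ref(ensemble, a, motif)
  ib <- resolve_atom_ref(ensemble, b, motif)
  d <- ensemble$coords[, ia, , drop = TRUE] - ensemble$coords[, ib, , drop = TRUE]
  if (is.null(dim(d))) d <- matrix(d, ncol = 3)
  sqrt(rowSums(d^2))
}

#' Density estimate of a distance series
#'
#' Histogram-based density integrating to one (Freedman-Diaconis bins by
#' default), optionally a Gaussian kernel density with Silverman bandwidth.
#' An all-identical series falls back to a single delta-like bin with a
#' warning.
#'
#' @param series numeric vector (>= 2 samples).
#' @param bins histogram breaks specification (count, vector, or a rule name
#'   accepted by [hist()]; default `"FD"`).
#' @param kde if TRUE, return a Gaussian kernel density instead.
#' @param bandwidth KDE bandwidth (default Silverman's rule via [stats::bw.nrd0()]).
#' @return data.frame with columns `x` (bin mid or evaluation point) and
#'   `density`; histogram versions carry the break vector as attribute
#'   `breaks`.
#' @export
distance_density <- function(series, bins = "FD", kde = FALSE, bandwidth = NULL) {
  if (length(series) < 2) stop("density needs at least 2 samples")
  if (diff(range(series)) < .Machine$double.eps) {
    warning("all samples identical; returning a delta-like single bin")
    width <- 1e-6
    out <- data.frame(x = series[1], density = 1 / width)
    attr(out, "breaks") <- c(series[1] - width / 2, series[1] + width / 2)
    return(out)
  }
  if (kde) {
    bw <- if (is.null(bandwidth)) stats::bw.nrd0(series) else bandwidth
    d <- stats::density(series, bw = bw)
    return(data.frame(x = d$x, density = d$y))
  }
  h <- graphics::hist(series, breaks = bins, plot = FALSE)
  out <- data.frame(x = h$mids, density = h$density)
  attr(out, "breaks") <- h$breaks
  out
}

#' Hydrogen-bond occupancy of a distance series
#'
#' Fraction of frames in which the donor-acceptor distance is at or below
#' the cutoff (inclusive); pairs farther than 3.5 Angstrom are considered
#' unable to hydrogen-bond.
#'
#' @param series per-frame distances, Angstrom.
#' @param cutoff distance cutoff, Angstrom (default 3.5).
#' @return fraction in \[0, 1\].
#' @export
hbond_occupancy <- function(series, cutoff = 3.5) {
  if (length(series) == 0) stop("empty distance series")
  mean(series <= cutoff)
}

#' Define a triangle collective variable
#'
#' @param a,b,c atom references of the three vertices (distinct atoms).
#' @param name label for outputs (e.g. `"D590-K579-E755"`).
#' @return object of class `triangle_cv`.
#' @export
triangle_cv <- function(a, b, c, name = paste(a, b, c, sep = "|")) {
  if (anyDuplicated(c(a, b, c))) stop("triangle vertices must be three distinct atoms")
  structure(list(a = a, b = b, c = c, name = name), class = "triangle_cv")
}

#' Per-frame triangle area collective variable
#'
#' Area of the triangle spanned by three atoms (half the magnitude of the
#' cross product of two edge vectors). Used as a pocket-openness collective
#' variable; by convention the vertices are the C-alpha atoms of the three
#' pocket residues.
#'
#' @param ensemble an `md_ensemble`.
#' @param cv a `triangle_cv`.
#' @param motif optional `motif_mapping`.
#' @return numeric vector of per-frame areas, Angstrom^2.
#' @export
triangle_area_series <- function(ensemble, cv, motif = NULL) {
  ia <- resolve_atom_ref(ensemble, cv$a, motif)
  ib <- resolve_atom_ref(ensemble, cv$b, motif)
  ic <- resolve_atom_ref(ensemble, cv$c, motif)
  u <- ensemble$coords[, ib, , drop = TRUE] - ensemble$coords[, ia, , drop = TRUE]
  v <- ensemble$coords[, ic, , drop = TRUE] - ensemble$coords[, ia, , drop = TRUE]
  if (is.null(dim(u))) { u <- matrix(u, ncol = 3); v <- matrix(v, ncol = 3) }
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Two-dimensional free-energy landscape from two collective variables
#'
#' Bins the joint samples, converts counts to probabilities and reports
#' F = -kT ln(P / Pmax), so the global minimum is exactly zero. Bins with
#' zero counts are masked (NA), never assigned -kT ln 0.
#'
#' @param cv1,cv2 equal-length collective-variable series.
#' @param bins number of bins per axis (default 50).
#' @param temperature temperature in Kelvin (default 300).
#' @param pad fractional padding of the observed range per side (default 0.05).
#' @return object of class `landscape_grid` with `counts`, `free_energy`
#'   (kcal/mol, NA on empty bins), `cv1_edges`, `cv2_edges`, `temperature`.
#' @export
fel_2d <- function(cv1, cv2, bins = 50, temperature = 300, pad = 0.05) {
  if (length(cv1) != length(cv2)) stop("collective-variable series differ in length")
  n <- length(cv1)
  edges <- function(v) {
    r <- range(v)
    span <- max(diff(r), .Machine$double.eps)
    seq(r[1] - pad * span, r[2] + pad * span, length.out = bins + 1)
  }
  e1 <- edges(cv1); e2 <- edges(cv2)
  i1 <- findInterval(cv1, e1, rightmost.closed = TRUE, all.inside = TRUE)
  i2 <- findInterval(cv2, e2, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(i1, levels = 1:bins), factor(i2, levels = 1:bins))
  counts[] <- as.integer(tab)
  P <- counts / n
  kT <- KB_KCAL * temperature
  G <- matrix(NA_real_, bins, bins)
  occ <- counts > 0
  G[occ] <- -kT * log(P[occ] / max(P))
  structure(list(counts = counts, free_energy = G,
                 cv1_edges = e1, cv2_edges = e2,
                 temperature = temperature, n_samples = n),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("landscape_grid: %d x %d bins, %d samples, T=%g K, %d occupied bins\n",
              nrow(x$counts), ncol(x$counts), x$n_samples, x$temperature,
              sum(x$counts > 0)))
  invisible(x)
}
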