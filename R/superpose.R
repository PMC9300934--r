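# Rigid-body superposition (Kabsch), RMSD and RMSF.

# Least-squares rigid fit of mobile points P (n x 3) onto reference Q (n x 3).
# Returns the proper rotation R (det = +1) and translation t such that
# P %*% R + t approximates Q. Mass-unweighted.
kabsch_fit <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) stop("rigid fit needs at least 3 atoms")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  # collinearity check: rank of the centered cloud must be >= 2
  if (svd(Pc)$d[2] < 1e-8) stop("fit atoms are collinear; rotation is underdetermined")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cq - as.vector(cp %*% R)
  list(rotation = R, translation = t)
}

#' Superpose every frame of an ensemble onto a reference
#'
#' Each frame is rigidly transformed (proper rotation + translation, Kabsch)
#' to minimise the mass-unweighted RMSD of the fit selection to the
#' reference; all other atoms are carried along by the same transform.
#' Chirality is preserved (the fitted rotation always has determinant +1).
#'
#' @param ensemble an `md_ensemble`.
#' @param reference a `structure_model` with the same topology; defaults to
#'   the ensemble's own topology coordinates.
#' @param fit_sel selection expression defining the fit atoms (default all
#'   C-alpha atoms).
#' @return the superposed `md_ensemble` (flagged `superposed = TRUE`).
#' @export
superpose <- function(ensemble, reference = NULL, fit_sel = "name CA") {
  if (is.null(reference)) reference <- ensemble$topology
  idx <- resolve_selection(ensemble, fit_sel)
  ref_idx <- resolve_selection(reference, fit_sel)
  if (length(idx) != length(ref_idx)) {
    stop("fit selection resolves to different atom counts in ensemble and reference")
  }
  Q <- structure_coords(reference)[ref_idx, , drop = FALSE]
  coords <- ensemble$coords
  for (f in seq_len(dim(coords)[1])) {
    frame <- coords[f, , , drop = TRUE]
    fit <- kabsch_fit(frame[idx, , drop = FALSE], Q)
    coords[f, , ] <- sweep(frame %*% fit$rotation, 2, fit$translation, "+")
  }
  ensemble$coords <- coords
  ensemble$superposed <- TRUE
  ensemble
}

#' Per-frame RMSD relative to a reference structure
#'
#' RMSD_f = sqrt(mean over selected atoms of the squared deviation from the
#' reference). No fitting is performed here; superpose first (or pass
#' `fit = TRUE`).
#'
#' @param ensemble an `md_ensemble`.
#' @param reference reference `structure_model`; defaults to the topology.
#' @param sel selection expression (default all C-alpha atoms).
#' @param fit if TRUE, superpose on `sel` before measuring.
#' @return numeric vector of length F (Angstrom).
#' @export
rmsd_series <- function(ensemble, reference = NULL, sel = "name CA", fit = FALSE) {
  if (is.null(reference)) reference <- ensemble$topology
  if (fit) ensemble <- superpose(ensemble, reference, fit_sel = sel)
  idx <- resolve_selection(ensemble, sel)
  ref_idx <- resolve_selection(reference, sel)
  if (length(idx) != length(ref_idx)) stop("selection mismatch between ensemble and reference")
  ref <- structure_coords(reference)[ref_idx, , drop = FALSE]
  vapply(seq_len(n_frames(ensemble)), function(f) {
    dif <- ensemble$coords[f, idx, , drop = TRUE] - ref
    sqrt(mean(rowSums(matrix(dif, ncol = 3)^2)))
  }, numeric(1))
}

#' Per-atom RMSF profile
#'
#' RMSF_i = sqrt(mean over frames of the squared deviation of atom i from
#' its time-averaged position). The ensemble should be superposed first so
#' that rigid-body motion does not inflate the fluctuations.
#'
#' @param ensemble a superposed `md_ensemble` with at least 2 frames.
#' @param sel selection expression (default all C-alpha atoms).
#' @return data.frame with columns `key` (chain:resid), `name`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(ensemble, sel = "name CA") {
  if (n_frames(ensemble) < 2) {
    stop("RMSF is undefined for fewer than 2 frames")
  }
  idx <- resolve_selection(ensemble, sel)
  x <- ensemble$coords[, idx, , drop = FALSE]
  mean_pos <- apply(x, c(2, 3), mean)
  dev2 <- sweep(x, c(2, 3), mean_pos)^2
  rmsf <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & axes, times 3 axes
  atoms <- ensemble$topology$atoms[idx, ]
  data.frame(key = paste(atoms$chain, atoms$resid, sep = ":"),
             name = atoms$name, rmsf = rmsf, stringsAsFactors = FALSE)
}
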