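# Covariance and dynamic cross-correlation matrices (DCCM) over selected
# atoms (C-alpha by convention) of a superposed ensemble.

#' Scalar covariance matrix of atomic positions
#'
#' c_ij = <r_i . r_j> - <r_i> . <r_j> over frames, where r_i is the
#' 3-vector position of selected atom i and the average is the plain frame
#' mean (population normalisation, 1/F). The ensemble must be superposed so
#' that rigid-body motion does not masquerade as internal correlation.
#'
#' @param ensemble a superposed `md_ensemble` with F >= 2.
#' @param sel selection expression, one atom per residue (default C-alpha).
#' @return R x R covariance matrix (Angstrom^2) with residue keys as
#'   dimnames; class `covariance_matrix`.
#' @export
covariance_matrix <- function(ensemble, sel = "name CA") {
  if (n_frames(ensemble) < 2) stop("covariance needs at least 2 frames")
  if (!isTRUE(ensemble$superposed)) {
    warning("ensemble is not flagged as superposed; covariance may include rigid-body motion")
  }
  idx <- resolve_selection(ensemble, sel)
  F_ <- n_frames(ensemble)
  C <- matrix(0, length(idx), length(idx))
  for (ax in 1:3) {
    Xa <- ensemble$coords[, idx, ax, drop = TRUE]
    if (is.null(dim(Xa))) Xa <- matrix(Xa, nrow = F_)
    mu <- colMeans(Xa)
    C <- C + crossprod(Xa) / F_ - tcrossprod(mu)
  }
  C <- (C + t(C)) / 2
  atoms <- ensemble$topology$atoms[idx, ]
  keys <- paste(atoms$chain, atoms$resid, sep = ":")
  dimnames(C) <- list(keys, keys)
  class(C) <- c("covariance_matrix", class(C))
  C
}

#' Dynamic cross-correlation matrix
#'
#' C_ij = c_ij / sqrt(c_ii c_jj) from the scalar covariance. Entries lie in
#' \[-1, 1\]; the diagonal is exactly 1 where the variance is positive.
#' Zero-variance atoms give masked (NA) rows/columns with a warning; masked
#' entries propagate as missing, never as zero correlation.
#'
#' @param ensemble a superposed `md_ensemble` (or a precomputed
#'   `covariance_matrix`).
#' @param sel selection expression (ignored when a covariance is passed).
#' @return R x R correlation matrix, class `dccm_matrix`.
#' @export
dccm <- function(ensemble, sel = "name CA") {
  C <- if (inherits(ensemble, "covariance_matrix")) ensemble
       else covariance_matrix(ensemble, sel)
  v <- diag(C)
  zero <- v < 1e-12
  if (any(zero)) {
    warning("zero-variance atoms masked in DCCM: ",
            paste(rownames(C)[zero], collapse = ", "))
  }
  s <- ifelse(zero, NA_real_, 1 / sqrt(v))
  M <- unclass(C) * tcrossprod(s)
  over <- !is.na(M) & abs(M) > 1
  if (any(abs(M[over]) > 1 + 1e-12)) stop("correlation overflow beyond floating tolerance")
  M[over] <- sign(M[over])
  diag(M)[!zero] <- 1
  class(M) <- c("dccm_matrix", class(M))
  M
}

#' Difference between two correlation matrices
#'
#' Elementwise a - b, used to compare correlated motion across systems.
#' Residue labels must match.
#'
#' @param a,b `dccm_matrix` objects over the same residues.
#' @return R x R difference matrix.
#' @export
dccm_difference <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("correlation matrices differ in size")
  if (!identical(rownames(a), rownames(b))) stop("residue labels do not match")
  d <- unclass(a) - unclass(b)
  (d + t(d)) / 2
}

#' Average correlation matrices across replicas
#'
#' Elementwise mean of per-replica DCCMs (the default replica-handling
#' mode); NA (masked) entries stay NA if masked in any replica.
#'
#' @param ... `dccm_matrix` objects with identical residue labels.
#' @return averaged `dccm_matrix`.
#' @export
dccm_average <- function(...) {
  mats <- list(...)
  if (length(mats) == 1 && is.list(mats[[1]]) && !is.matrix(mats[[1]])) mats <- mats[[1]]
  ref <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(rownames(m), ref)) stop("residue labels do not match across replicas")
  }
  out <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  dimnames(out) <- dimnames(mats[[1]])
  class(out) <- c("dccm_matrix", class(out))
  out
}
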