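# Interaction energetics: molecular-mechanics cross terms (Lennard-Jones,
# Coulomb), Generalized Born polar solvation, Shrake-Rupley SASA with a
# linear nonpolar term, and single-trajectory per-residue binding
# decomposition:
#
#   dG_binding = dE_MM + dG_solv            (entropy term omitted)
#   dE_MM      = dE_vdw + dE_ele + dE_int   (dE_int = 0 in single-trajectory mode)
#   dG_solv    = dE_polar(GB) + dE_nonpolar
#   dE_nonpolar = gamma * SASA + b per species, combined complex - A - B.

#' Coulomb constant in kcal A / (mol e^2)
#' @export
KE_COULOMB <- 332.0637

#' Default energetics parameters
#'
#' Interior dielectric 1, solvent dielectric 80, surface tension gamma
#' 0.00542 kcal/mol/A^2, nonpolar offset b 0.92 kcal/mol, probe radius 1.4 A.
#' @return named list of defaults.
#' @export
energy_defaults <- function() {
  list(eps_in = 1.0, eps_solv = 80.0, gamma = 0.00542, b = 0.92,
       probe = 1.4, sasa_points = 240)
}

pair_distances <- function(coords, idxA, idxB, check_overlap = TRUE) {
  d2 <- outer(rowSums(coords[idxA, , drop = FALSE]^2),
              rowSums(coords[idxB, , drop = FALSE]^2), "+") -
    2 * coords[idxA, , drop = FALSE] %*% t(coords[idxB, , drop = FALSE])
  r <- sqrt(pmax(d2, 0))
  if (check_overlap && any(r < 0.1)) {
    w <- which(r < 0.1, arr.ind = TRUE)[1, ]
    stop(sprintf("atoms %d and %d overlap (r = %.3f A)",
                 idxA[w[1]], idxB[w[2]], r[w[1], w[2]]))
  }
  r
}

# per-pair Lennard-Jones energies, Lorentz-Berthelot combination
lj_pair_matrix <- function(coords, idxA, idxB, params) {
  r <- pair_distances(coords, idxA, idxB)
  rmin <- outer(params$lj_rmin_half_A[idxA], params$lj_rmin_half_A[idxB], "+")
  eps <- sqrt(outer(params$lj_eps_kcal_mol[idxA], params$lj_eps_kcal_mol[idxB]))
  x6 <- (rmin / r)^6
  eps * (x6^2 - 2 * x6)
}

#' Lennard-Jones cross energy between two atom groups
#'
#' Sum over cross pairs of eps_ij \[(Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6\] with
#' Lorentz-Berthelot combination (Rmin_ij = Rmin_i/2 + Rmin_j/2,
#' eps_ij = sqrt(eps_i eps_j)). No cutoff.
#'
#' @param coords A x 3 coordinate matrix (one frame).
#' @param idxA,idxB disjoint atom index vectors.
#' @param params per-atom parameter table (see [read_params()]), indexed by row.
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(coords, idxA, idxB, params) {
  if (length(intersect(idxA, idxB)) > 0) stop("atom groups must be disjoint")
  sum(lj_pair_matrix(coords, idxA, idxB, params))
}

#' Coulomb cross energy between two atom groups
#'
#' Sum over cross pairs of k_e q_i q_j / (eps_in r), with
#' k_e = 332.0637 kcal A / (mol e^2).
#'
#' @inheritParams lj_energy
#' @param eps_in interior dielectric constant (divides the energy).
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(coords, idxA, idxB, params, eps_in = 1.0) {
  if (length(intersect(idxA, idxB)) > 0) stop("atom groups must be disjoint")
  r <- pair_distances(coords, idxA, idxB)
  sum(KE_COULOMB / eps_in * outer(params$charge_e[idxA], params$charge_e[idxB]) / r)
}

gb_f <- function(r, ai, aj) {
  aa <- outer(ai, aj)
  sqrt(r^2 + aa * exp(-r^2 / (4 * aa)))
}

#' Generalized Born polar solvation energy of an atom set
#'
#' Pairwise GB energy with fixed (non-perturbed) Born radii a_i:
#' E = -1/2 k_e (1/eps_in - 1/eps_solv) sum_ij q_i q_j / f_GB(r_ij), with
#' f_GB = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j))) and the i = j
#' self-terms included (f_GB(0) = a_i, giving the Born self-energy).
#'
#' @param coords A x 3 coordinate matrix (one frame).
#' @param idx atom indices of the set.
#' @param params per-atom parameter table with Born radii.
#' @param eps_in,eps_solv interior and solvent dielectric constants.
#' @return energy in kcal/mol.
#' @export
gb_energy <- function(coords, idx, params, eps_in = 1.0, eps_solv = 80.0) {
  tau <- 1 / eps_in - 1 / eps_solv
  if (tau == 0) return(0)
  a <- params$born_radius_A[idx]
  if (anyNA(a)) stop("missing Born radius for atoms: ",
                     paste(idx[is.na(a)], collapse = ", "))
  r <- pair_distances(coords, idx, idx, check_overlap = FALSE)
  diag(r) <- 0
  q <- params$charge_e[idx]
  -0.5 * KE_COULOMB * tau * sum(outer(q, q) / gb_f(r, a, a))
}

# per-pair GB cross energies between two groups (each pair counted once);
# with fixed Born radii this equals E_GB(complex) - E_GB(A) - E_GB(B)
gb_pair_matrix <- function(coords, idxA, idxB, params, eps_in, eps_solv) {
  tau <- 1 / eps_in - 1 / eps_solv
  aA <- params$born_radius_A[idxA]; aB <- params$born_radius_A[idxB]
  if (anyNA(aA) || anyNA(aB)) stop("missing Born radius in energy selection")
  r <- pair_distances(coords, idxA, idxB, check_overlap = FALSE)
  -KE_COULOMB * tau * outer(params$charge_e[idxA], params$charge_e[idxB]) /
    gb_f(r, aA, aB)
}

#' Generalized Born polar binding term
#'
#' dE_polar = E_GB(complex) - E_GB(A) - E_GB(B) over the same frame, with
#' fixed Born radii (so self and intra-group terms cancel and only cross
#' pairs contribute). Zero for any geometry when eps_in = eps_solv.
#'
#' @inheritParams lj_energy
#' @param eps_in,eps_solv dielectric constants.
#' @return binding polar energy, kcal/mol.
#' @export
gb_polar <- function(coords, idxA, idxB, params, eps_in = 1.0, eps_solv = 80.0) {
  if (length(intersect(idxA, idxB)) > 0) stop("atom groups must be disjoint")
  if (eps_in == eps_solv) return(0)
  sum(gb_pair_matrix(coords, idxA, idxB, params, eps_in, eps_solv))
}

golden_sphere_points <- function(n) {
  i <- seq_len(n) - 1
  z <- (2 * i + 1) / n - 1
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places quasi-uniform (golden-spiral) test points on each atom's solvent
#' sphere of radius r_i + probe and counts the fraction not strictly inside
#' any neighbour's solvent sphere. Coincident centres occlude nothing: a
#' point exactly on a neighbour's sphere surface is accessible (strict-
#' inequality tie rule).
#'
#' @param coords A x 3 coordinate matrix (one frame).
#' @param radii per-atom radii, Angstrom.
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points test points per atom (>= 12, default 960).
#' @return per-atom SASA, Angstrom^2.
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  if (n_points < 12) stop("n_points must be at least 12")
  if (length(radii) != nrow(coords)) stop("one radius per atom required")
  if (any(radii <= 0)) stop("radii must be positive")
  A <- nrow(coords)
  pts <- golden_sphere_points(n_points)
  rs <- radii + probe
  out <- numeric(A)
  maxr <- max(rs)
  for (i in seq_len(A)) {
    d2_centres <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2_centres < (rs[i] + maxr)^2 & seq_len(A) != i)
    nb <- nb[sqrt(d2_centres[nb]) < rs[i] + rs[nb]]
    if (length(nb) == 0) {
      out[i] <- 4 * pi * rs[i]^2
      next
    }
    p <- sweep(pts * rs[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(p, 2, coords[j, ])^2)
      # strict interior occludes; points on the surface (within floating
      # tolerance) stay accessible, so coincident centres occlude nothing
      free <- free & (d2 >= rs[j]^2 * (1 - 1e-9))
      if (!any(free)) break
    }
    out[i] <- 4 * pi * rs[i]^2 * sum(free) / n_points
  }
  out
}

#' Nonpolar solvation energy of one species
#'
#' dE_nonpolar = gamma * SASA + b, with gamma = 0.00542 kcal/mol/A^2 and
#' b = 0.92 kcal/mol by default. For a binding energy the per-species values
#' are combined as complex - A - B.
#'
#' @param sasa_total total SASA of the species, Angstrom^2.
#' @param gamma surface tension, kcal/mol/A^2.
#' @param b offset, kcal/mol.
#' @return energy in kcal/mol.
#' @export
nonpolar_solvation <- function(sasa_total, gamma = 0.00542, b = 0.92) {
  gamma * sasa_total + b
}

#' Combine binding energy components through the decomposition identity
#'
#' dG_binding = dE_vdw + dE_ele + dE_int + dE_polar + dE_nonpolar. This is
#' the aggregation path used for all totals; exposing it allows identity
#' checks against published component tables.
#'
#' @param vdw,ele,polar,nonpolar,internal component energies, kcal/mol
#'   (vectorised).
#' @return dG_binding, kcal/mol.
#' @export
aggregate_binding <- function(vdw, ele, polar, nonpolar, internal = 0) {
  vdw + ele + internal + polar + nonpolar
}

#' Single-trajectory per-residue binding decomposition
#'
#' For every (strided) frame, computes the receptor-partner cross terms
#' dE_vdw and dE_ele, the Generalized Born polar binding term, and the
#' SASA-based nonpolar term (gamma SASA + b per species, combined
#' complex - A - B), then dG_binding through [aggregate_binding()] with
#' dE_int = 0 (single-trajectory mode: intramolecular bonded terms cancel).
#' Pairwise terms are attributed half to each partner residue; the nonpolar
#' per-residue share is gamma times the residue's buried SASA with the
#' constant -b distributed proportionally to buried area, so per-residue
#' rows sum exactly to the totals.
#'
#' @param ensemble an `md_ensemble`.
#' @param receptor_sel,partner_sel disjoint selection expressions.
#' @param params per-atom parameter table (row i = atom i of the topology).
#' @param stride frame stride (default 1).
#' @param eps_in,eps_solv,gamma,b,probe,sasa_points energetics settings (see
#'   [energy_defaults()]).
#' @return object of class `energy_decomposition` with `totals` (term, mean,
#'   sd), `per_frame` (frames x terms), `per_residue` (mean and sd per term
#'   per residue), `frames` (frame indices used).
#' @export
binding_decomposition <- function(ensemble, receptor_sel, partner_sel, params,
                                  stride = 1,
                                  eps_in = 1.0, eps_solv = 80.0,
                                  gamma = 0.00542, b = 0.92,
                                  probe = 1.4, sasa_points = 240) {
  idxA <- resolve_selection(ensemble, receptor_sel)
  idxB <- resolve_selection(ensemble, partner_sel)
  if (length(intersect(idxA, idxB)) > 0) {
    stop("receptor and partner selections overlap")
  }
  if (nrow(params) != n_atoms(ensemble)) {
    stop("parameter table must have one row per topology atom")
  }
  frames <- seq(1, n_frames(ensemble), by = stride)
  if (length(frames) == 0) stop("no frames left after stride")

  res_idx <- atom_residue_index(ensemble)
  res_tab <- residue_table(ensemble)
  resA <- res_idx[idxA]; resB <- res_idx[idxB]
  res_used <- sort(unique(c(resA, resB)))
  nres <- length(res_used)
  rmap <- match(res_idx, res_used)

  radii <- params$lj_rmin_half_A
  terms <- c("vdw", "ele", "int", "polar", "nonpolar", "solv", "mm", "binding")
  per_frame <- matrix(0, length(frames), length(terms),
                      dimnames = list(NULL, terms))
  per_res <- array(0, dim = c(length(frames), nres, 5),
                   dimnames = list(NULL, res_tab$key[res_used],
                                   c("vdw", "ele", "polar", "nonpolar", "binding")))
  both <- c(idxA, idxB)

  half_split <- function(pairE) {
    # attribute each cross-pair energy half to the A-side residue, half to B-side
    sh <- numeric(nres)
    byA <- rowsum(rowSums(pairE), rmap[idxA])
    byB <- rowsum(colSums(pairE), rmap[idxB])
    sh[as.integer(rownames(byA))] <- sh[as.integer(rownames(byA))] + byA / 2
    sh[as.integer(rownames(byB))] <- sh[as.integer(rownames(byB))] + byB / 2
    sh
  }

  for (fi in seq_along(frames)) {
    xyz <- ensemble$coords[frames[fi], , , drop = TRUE]
    ljm <- lj_pair_matrix(xyz, idxA, idxB, params)
    elm <- KE_COULOMB / eps_in *
      outer(params$charge_e[idxA], params$charge_e[idxB]) /
      pair_distances(xyz, idxA, idxB)
    gbm <- gb_pair_matrix(xyz, idxA, idxB, params, eps_in, eps_solv)

    s_complex <- sasa(xyz[both, , drop = FALSE], radii[both], probe, sasa_points)
    s_A <- sasa(xyz[idxA, , drop = FALSE], radii[idxA], probe, sasa_points)
    s_B <- sasa(xyz[idxB, , drop = FALSE], radii[idxB], probe, sasa_points)
    np <- nonpolar_solvation(sum(s_complex), gamma, b) -
      nonpolar_solvation(sum(s_A), gamma, b) -
      nonpolar_solvation(sum(s_B), gamma, b)

    vdw <- sum(ljm); ele <- sum(elm); pol <- sum(gbm)
    bind <- aggregate_binding(vdw, ele, pol, np)
    per_frame[fi, ] <- c(vdw, ele, 0, pol, np, pol + np, vdw + ele, bind)

    # per-atom buried SASA, attributed to residues
    dsasa_atom <- s_complex - c(s_A, s_B)
    dsasa_res <- numeric(nres)
    agg <- rowsum(dsasa_atom, rmap[both])
    dsasa_res[as.integer(rownames(agg))] <- agg
    dsasa_tot <- sum(dsasa_res)
    w <- if (abs(dsasa_tot) > 1e-9) dsasa_res / dsasa_tot else rep(1 / nres, nres)
    np_res <- gamma * dsasa_res - b * w

    per_res[fi, , "vdw"] <- half_split(ljm)
    per_res[fi, , "ele"] <- half_split(elm)
    per_res[fi, , "polar"] <- half_split(gbm)
    per_res[fi, , "nonpolar"] <- np_res
    per_res[fi, , "binding"] <- per_res[fi, , "vdw"] + per_res[fi, , "ele"] +
      per_res[fi, , "polar"] + per_res[fi, , "nonpolar"]
  }

  totals <- data.frame(term = terms,
                       mean = colMeans(per_frame),
                       sd = apply(per_frame, 2, stats::sd),
                       row.names = NULL)
  pr_mean <- apply(per_res, c(2, 3), mean)
  pr_sd <- apply(per_res, c(2, 3), stats::sd)
  per_residue <- data.frame(key = res_tab$key[res_used],
                            resname = res_tab$resname[res_used],
                            stringsAsFactors = FALSE)
  for (tm in colnames(pr_mean)) {
    per_residue[[paste0(tm, "_mean")]] <- pr_mean[, tm]
    per_residue[[paste0(tm, "_sd")]] <- pr_sd[, tm]
  }
  structure(list(totals = totals, per_frame = per_frame,
                 per_residue = per_residue, frames = frames,
                 settings = list(eps_in = eps_in, eps_solv = eps_solv,
                                 gamma = gamma, b = b, probe = probe,
                                 sasa_points = sasa_points, stride = stride)),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat("energy_decomposition over", nrow(x$per_frame), "frames (kcal/mol):\n")
  print(x$totals, digits = 4)
  invisible(x)
}
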