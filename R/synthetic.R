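# Synthetic conformational ensembles with planted correlation structure.
#
# These stand in for MD trajectories: every downstream stage (DCCM, network,
# communities, paths, clustering, energetics) can be checked against the
# planted ground truth without running any simulation.

#' Build a deterministic toy receptor-ligand-peptide complex
#'
#' Constructs, with no randomness, a receptor C-alpha trace on an ideal
#' helix-like curve (radius 1.6 A, 120 degrees and 1.2 A rise per residue)
#' with one side-chain pseudo-atom per residue, optionally a 5-atom ligand
#' placed in a mid-helix pocket, and optionally a 5-residue cofactor peptide
#' whose residue names form an LXXLL-style motif so that motif labels
#' (`L+1`..`L+5`, `R+2`) resolve. Geometry is chosen so that receptor
#' residues separated by 2 or 3 positions in sequence are within a 4.5 A
#' heavy-atom contact while more distant pairs are not, giving a connected,
#' chain-like contact graph once sequence neighbours are excluded.
#'
#' @param n_receptor_residues number of receptor residues (>= 6).
#' @param include_ligand add the 5-atom ligand.
#' @param include_peptide add the 5-residue LXXLL peptide.
#' @param first_resid author number of the first receptor residue (default
#'   580, so residue 590 exists for n >= 11).
#' @param special_residues named list `resid -> c(resname, sidechain_atom)`
#'   overriding the default alanine-like residues; default places an
#'   aspartate with an OD1 side-chain atom at residue 590 when in range.
#' @return list with `model` (a `structure_model`) and `params` (per-atom
#'   parameter table: `serial`, `charge_e`, `lj_rmin_half_A`,
#'   `lj_eps_kcal_mol`, `born_radius_A`).
#' @export
build_toy_complex <- function(n_receptor_residues = 20,
                              include_ligand = TRUE,
                              include_peptide = TRUE,
                              first_resid = 580L,
                              special_residues = NULL) {
  n <- n_receptor_residues
  if (n < 6) stop("toy receptor needs at least 6 residues")
  if (is.null(special_residues)) {
    special_residues <- list(`590` = c("ASP", "OD1"))
  }
  rows <- list()
  charges <- numeric(0)
  serial <- 0L
  add_atom <- function(name, resname, resid, chain, element, pos, charge, type = "ATOM") {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, resname = resname, resid = as.integer(resid),
      chain = chain, element = element, type = type,
      x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
    charges <<- c(charges, charge)
  }
  # receptor helix: CA at radius 1.6, side-chain pseudo-atom at radius 2.4
  twist <- 2 * pi / 3; rise <- 1.2
  for (i in seq_len(n)) {
    resid <- first_resid + i - 1L
    theta <- twist * (i - 1)
    sp <- special_residues[[as.character(resid)]]
    resname <- if (!is.null(sp)) sp[1] else "ALA"
    scname <- if (!is.null(sp)) sp[2] else "CB"
    scelem <- substr(scname, 1, 1)
    sccharge <- if (!is.null(sp) && scelem == "O") -0.6 else
                if (!is.null(sp) && scelem == "N") 0.6 else -0.05
    add_atom("CA", resname, resid, "A", "C",
             c(1.6 * cos(theta), 1.6 * sin(theta), rise * (i - 1)), 0.05)
    add_atom(scname, resname, resid, "A", scelem,
             c(2.4 * cos(theta), 2.4 * sin(theta), rise * (i - 1)), sccharge)
  }
  if (include_ligand) {
    centre <- c(0, 0, rise * (n - 1) / 2)
    offs <- rbind(c(0, 0, 0), c(0.9, 0, 0), c(-0.9, 0, 0), c(0, 0.9, 0), c(0, 0, 0.9))
    lnames <- c("C1", "C2", "C3", "C4", "O1")
    lcharges <- c(0.1, 0.1, 0.1, 0.1, -0.4)
    for (j in 1:5) {
      add_atom(lnames[j], "LIG", 901L, "L", substr(lnames[j], 1, 1),
               centre + offs[j, ], lcharges[j], type = "HETATM")
    }
  }
  if (include_peptide) {
    pep <- data.frame(resname = c("LEU", "ARG", "ALA", "LEU", "LEU"),
                      sc = c("CB", "NE", "CB", "CB", "CB"),
                      charge = c(0.1, 0.6, -0.05, 0.1, 0.1))
    # docked along the 120-degree side-chain face of the helix (the face
    # carrying residue 590 when present), backbone out and side chains
    # pointing at the receptor, with the arginine-like residue level with
    # residue 590 so the OD1..NE pair sits near the hydrogen-bond range and
    # its occupancy is fractional under thermal noise; the backbone stays
    # clear of steric clashes
    u <- c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
    i590 <- 590 - first_resid + 1
    z_centre <- if (i590 >= 1 && i590 <= n) rise * (i590 - 1) else rise * (n - 1) / 2
    for (j in 1:5) {
      resid <- 745L + j - 1L
      pos <- 7.6 * u + c(0, 0, z_centre + 2.0 * (j - 2) + 0.6)
      add_atom("CA", pep$resname[j], resid, "B", "C", pos, 0.05)
      add_atom(pep$sc[j], pep$resname[j], resid, "B", substr(pep$sc[j], 1, 1),
               pos - 1.4 * u, pep$charge[j])
    }
  }
  atoms <- do.call(rbind, rows)
  model <- structure_model(atoms, title = "synthetic toy complex")
  params <- data.frame(serial = atoms$serial,
                       charge_e = charges,
                       lj_rmin_half_A = 1.908,
                       lj_eps_kcal_mol = 0.12,
                       born_radius_A = 1.7,
                       stringsAsFactors = FALSE)
  list(model = model, params = params)
}

#' Plant a residue-level correlation matrix
#'
#' Builds a symmetric, unit-diagonal target correlation matrix from
#' correlated blocks ("communities"), an ordered high-correlation chain
#' ("allosteric path", adjacent chain members linked at `chain$rho`), and a
#' background correlation. If the assembled matrix is indefinite it is
#' repaired by clipping negative eigenvalues at zero and rescaling the
#' diagonal to one; the repair and the largest entry shift are reported in
#' the returned attributes.
#'
#' @param n_residues number of residues.
#' @param blocks list of `list(members = <indices>, rho = <value>)`; blocks
#'   must be disjoint.
#' @param chain optional `list(members = <ordered indices>, rho = <value>)`.
#' @param background off-diagonal background correlation (default 0).
#' @return correlation matrix with attributes `blocks`, `chain`,
#'   `repaired` (logical) and `max_shift` (largest |entry change| from the
#'   PSD repair).
#' @export
plant_correlation <- function(n_residues, blocks = list(), chain = NULL,
                              background = 0) {
  all_rho <- c(background, vapply(blocks, function(b) b$rho, numeric(1)),
               if (!is.null(chain)) chain$rho)
  if (any(abs(all_rho) >= 1)) stop("off-diagonal correlations must satisfy |rho| < 1")
  members <- unlist(lapply(blocks, function(b) b$members))
  if (anyDuplicated(members)) stop("blocks must be disjoint")
  C <- matrix(background, n_residues, n_residues)
  for (b in blocks) {
    C[b$members, b$members] <- b$rho
  }
  if (!is.null(chain) && length(chain$members) >= 2) {
    m <- chain$members
    for (i in seq_len(length(m) - 1)) {
      C[m[i], m[i + 1]] <- chain$rho
      C[m[i + 1], m[i]] <- chain$rho
    }
  }
  diag(C) <- 1
  raw <- C
  e <- eigen(C, symmetric = TRUE)
  repaired <- FALSE
  if (min(e$values) < -1e-10) {
    repaired <- TRUE
    d <- pmax(e$values, 0)
    C <- e$vectors %*% (d * t(e$vectors))
    s <- 1 / sqrt(diag(C))
    C <- C * tcrossprod(s)
    C <- (C + t(C)) / 2
    diag(C) <- 1
  }
  attr(C, "blocks") <- blocks
  attr(C, "chain") <- chain
  attr(C, "repaired") <- repaired
  attr(C, "max_shift") <- max(abs(C - raw))
  C
}

random_rotation <- function(max_deg) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, -max_deg, max_deg) * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Sample a synthetic ensemble around a reference structure
#'
#' Residue displacement vectors are drawn from a zero-mean multivariate
#' normal whose residue-level correlation equals `residue_corr`; the same
#' scalar correlation is applied identically and independently on x, y and
#' z, so the scalar dot-product DCCM recovers the planted matrix exactly in
#' expectation. All atoms of a residue move together (rigid residues).
#' Each frame is then given a rigid-body jitter (random rotation about the
#' centroid plus translation), which superposition must remove.
#'
#' @param reference a `structure_model`; fluctuations are about its coordinates.
#' @param residue_corr R x R correlation matrix, R = number of residues of
#'   the reference (e.g. from [plant_correlation()]).
#' @param per_residue_sigma per-axis displacement standard deviation, Angstrom.
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed; the only source of randomness.
#' @param rigid_jitter `c(max_translation_A, max_rotation_deg)` applied per
#'   frame; `c(0, 0)` disables jitter.
#' @return list with `ensemble` (an `md_ensemble`) and `truth`
#'   (a list recording the seed, sigma, the exact correlation matrix sampled
#'   from, residue keys, community labels and planted chain, if any).
#' @export
sample_ensemble <- function(reference, residue_corr, per_residue_sigma = 0.5,
                            n_frames = 1000, seed = 1,
                            rigid_jitter = c(0.5, 5)) {
  if (n_frames < 2) stop("n_frames must be at least 2")
  res <- residue_table(reference)
  R <- nrow(res)
  if (!all(dim(residue_corr) == c(R, R))) {
    stop("residue_corr must be ", R, " x ", R, " to match the reference residues")
  }
  e <- eigen(residue_corr, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop("residue_corr is not positive semidefinite; use plant_correlation()")
  }
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), R)
  res_of_atom <- atom_residue_index(reference)
  ref_xyz <- structure_coords(reference)
  A <- nrow(ref_xyz)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  coords <- array(NA_real_, dim = c(n_frames, A, 3))
  disp <- array(NA_real_, dim = c(n_frames, R, 3))
  for (ax in 1:3) {
    Z <- matrix(stats::rnorm(n_frames * R), n_frames, R)
    disp[, , ax] <- per_residue_sigma * (Z %*% t(L))
  }
  for (f in seq_len(n_frames)) {
    frame <- ref_xyz + disp[f, res_of_atom, ]
    if (any(rigid_jitter > 0)) {
      rot <- random_rotation(rigid_jitter[2])
      trans <- stats::runif(3, -rigid_jitter[1], rigid_jitter[1])
      centroid <- colMeans(frame)
      frame <- sweep(sweep(frame, 2, centroid) %*% rot, 2, centroid + trans, "+")
    }
    coords[f, , ] <- frame
  }
  blocks <- attr(residue_corr, "blocks")
  communities <- rep(0L, R)
  if (!is.null(blocks)) {
    for (bi in seq_along(blocks)) communities[blocks[[bi]]$members] <- bi
  }
  chain <- attr(residue_corr, "chain")
  truth <- list(seed = seed,
                per_residue_sigma = per_residue_sigma,
                n_frames = n_frames,
                rigid_jitter = rigid_jitter,
                residue_keys = res$key,
                corr_sampled = unclass(residue_corr),
                communities = communities,
                chain = if (!is.null(chain)) chain$members else integer(0),
                psd_repaired = isTRUE(attr(residue_corr, "repaired")),
                psd_max_shift = attr(residue_corr, "max_shift"))
  list(ensemble = md_ensemble(coords, reference), truth = truth)
}

#' Write a synthetic fixture to disk
#'
#' Emits the multi-model PDB ensemble, the per-atom parameter TSV and a
#' machine-readable truth manifest (JSON) into a directory.
#'
#' @param ensemble an `md_ensemble`.
#' @param truth truth list from [sample_ensemble()].
#' @param params per-atom parameter table from [build_toy_complex()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a named list of the written paths.
#' @export
write_fixture <- function(ensemble, truth, params, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(ensemble = file.path(out_dir, "ensemble.pdb"),
                params = file.path(out_dir, "params.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_ensemble(ensemble, paths$ensemble)
  utils::write.table(params, paths$params, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth$corr_sampled <- round(truth$corr_sampled, 10)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a per-atom parameter table
#' @param path TSV with columns `serial`, `charge_e`, `lj_rmin_half_A`,
#'   `lj_eps_kcal_mol`, `born_radius_A`.
#' @return validated data.frame.
#' @export
read_params <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("serial", "charge_e", "lj_rmin_half_A", "lj_eps_kcal_mol",
                "born_radius_A")
  missing_cols <- setdiff(required, names(p))
  if (length(missing_cols) > 0) {
    stop("parameter table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(p$lj_eps_kcal_mol < 0)) stop("negative Lennard-Jones epsilon")
  if (any(p$born_radius_A <= 0)) stop("non-positive Born radius")
  p
}
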