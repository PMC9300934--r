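#' Construct a structure model
#'
#' A structure model is the topology container used throughout the package:
#' an ordered atom table with PDB-style metadata plus one set of coordinates
#' in Angstrom. Residue numbering is author numbering as printed in PDB files
#' (e.g. D590); no internal renumbering is ever applied.
#'
#' @param atoms data.frame with columns `serial` (integer, unique), `name`
#'   (atom name, e.g. "CA", "OD1"), `resname` (3-letter residue name),
#'   `resid` (integer author residue number), `chain` (single character),
#'   `element` (character) and coordinates `x`, `y`, `z` in Angstrom.
#' @param title optional title string.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, title = "") {
  required <- c("serial", "name", "resname", "resid", "chain", "element",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure model must contain at least one atom")
  if (anyDuplicated(atoms$serial)) {
    stop("duplicate atom serial numbers: ",
         paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  atoms$resid <- as.integer(atoms$resid)
  atoms$serial <- as.integer(atoms$serial)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms), nrow(residue_table(x)),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure or ensemble
#' @param x a `structure_model` or `md_ensemble`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "structure_model")) return(nrow(x$atoms))
  if (inherits(x, "md_ensemble")) return(dim(x$coords)[2])
  stop("unsupported type")
}

#' Coordinates of a structure model as an A x 3 matrix
#' @param model a `structure_model`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
structure_coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure model
#' @param model a `structure_model`.
#' @param xyz A x 3 numeric matrix.
#' @return the updated `structure_model`.
#' @export
set_structure_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms), ncol(xyz) == 3)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Residue table of a structure model
#'
#' Residues in file order, keyed as "chain:resid". One row per residue.
#'
#' @param x a `structure_model` or `md_ensemble`.
#' @return data.frame with columns `key`, `chain`, `resid`, `resname`.
#' @export
residue_table <- function(x) {
  model <- if (inherits(x, "md_ensemble")) x$topology else x
  key <- paste(model$atoms$chain, model$atoms$resid, sep = ":")
  first <- !duplicated(key)
  data.frame(key = key[first],
             chain = model$atoms$chain[first],
             resid = model$atoms$resid[first],
             resname = model$atoms$resname[first],
             stringsAsFactors = FALSE)
}

#' Per-atom residue index
#'
#' Maps every atom to the row of [residue_table()] it belongs to.
#' @param x a `structure_model` or `md_ensemble`.
#' @return integer vector of length A.
#' @export
atom_residue_index <- function(x) {
  model <- if (inherits(x, "md_ensemble")) x$topology else x
  key <- paste(model$atoms$chain, model$atoms$resid, sep = ":")
  match(key, unique(key))
}

#' Construct a conformational ensemble
#'
#' @param coords numeric array of dimension F x A x 3 (frames, atoms, xyz), Angstrom.
#' @param topology a `structure_model` with A atoms in the same order.
#' @param frame_interval optional time between frames (arbitrary units).
#' @return An object of class `md_ensemble`.
#' @export
md_ensemble <- function(coords, topology, frame_interval = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[1] < 1) stop("ensemble must contain at least one frame")
  if (dim(coords)[2] != nrow(topology$atoms)) {
    stop("coordinate array atom count (", dim(coords)[2],
         ") does not match topology (", nrow(topology$atoms), ")")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  structure(list(coords = coords, topology = topology,
                 frame_interval = frame_interval,
                 superposed = FALSE),
            class = "md_ensemble")
}

#' @export
print.md_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("md_ensemble: %d frames x %d atoms%s\n", d[1], d[2],
              if (isTRUE(x$superposed)) " (superposed)" else ""))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `md_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' Extract one frame of an ensemble as a structure model
#' @param ensemble an `md_ensemble`.
#' @param frame frame index (1-based).
#' @return a `structure_model` carrying the full topology with that frame's
#'   coordinates.
#' @export
ensemble_frame <- function(ensemble, frame) {
  stopifnot(frame >= 1, frame <= n_frames(ensemble))
  set_structure_coords(ensemble$topology, ensemble$coords[frame, , , drop = TRUE])
}
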