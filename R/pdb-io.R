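# PDB reading (via bio3d) and multi-model PDB writing.
#
# Multi-model PDB is the canonical ensemble fixture format; DCD is supported
# behind the same contract when a topology PDB is supplied.

bio3d_atoms_to_table <- function(atom) {
  if (any(!is.na(atom$insert) & nzchar(atom$insert))) {
    stop("insertion codes are not supported; renumber the input structure")
  }
  alt <- atom$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  atom <- atom[keep, , drop = FALSE]
  if (nrow(atom) == 0) stop("no atoms left after altloc filtering")
  data.frame(serial = as.integer(atom$eleno),
             name = atom$elety,
             resname = atom$resid,
             resid = as.integer(atom$resno),
             chain = ifelse(is.na(atom$chain), " ", atom$chain),
             element = ifelse(is.na(atom$elesy), "", atom$elesy),
             type = atom$type,
             x = atom$x, y = atom$y, z = atom$z,
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Reads ATOM and HETATM records (first model only). Alternate locations
#' other than blank or "A" are discarded; insertion codes are rejected.
#'
#' @param path PDB file path.
#' @return a `structure_model`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
                  error = function(e) stop("cannot parse PDB file ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0) {
    stop("no ATOM/HETATM records in ", path)
  }
  atoms <- bio3d_atoms_to_table(pdb$atom)
  structure_model(atoms, title = basename(path))
}

count_model_atoms <- function(lines) {
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) return(NULL)
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL records")
  vapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    sum(grepl("^(ATOM|HETATM)", block))
  }, integer(1))
}

#' Read a conformational ensemble
#'
#' For multi-model PDB, every MODEL block becomes one frame; all models must
#' share atom count and order. For DCD, a topology PDB must be supplied.
#'
#' @param path ensemble file (multi-model PDB, or DCD).
#' @param format `"pdb"` or `"dcd"`.
#' @param topology path to a topology PDB (required for DCD).
#' @return an `md_ensemble`.
#' @export
read_ensemble <- function(path, format = c("pdb", "dcd"), topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dcd") {
    if (is.null(topology)) stop("DCD input requires a topology PDB")
    top <- read_structure(topology)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    coords <- xyz_to_array(xyz, nrow(top$atoms))
    return(md_ensemble(coords, top))
  }
  counts <- count_model_atoms(readLines(path))
  if (!is.null(counts) && length(unique(counts)) > 1) {
    stop("inconsistent atom counts across models: ",
         paste(unique(counts), collapse = " vs "))
  }
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = TRUE)),
                  error = function(e) stop("cannot parse PDB file ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0) {
    stop("no ATOM/HETATM records in ", path)
  }
  atoms <- bio3d_atoms_to_table(pdb$atom)
  top <- structure_model(atoms, title = basename(path))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords <- xyz_to_array(xyz, nrow(atoms))
  md_ensemble(coords, top)
}

xyz_to_array <- function(xyz, n_atoms) {
  if (ncol(xyz) != 3 * n_atoms) {
    stop("coordinate count does not match topology atom count")
  }
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, n_atoms, 3))
  for (ax in 1:3) coords[, , ax] <- xyz[, seq(ax, 3 * n_atoms, by = 3), drop = FALSE]
  coords
}

format_pdb_atom <- function(a, x, y, z) {
  rec <- if (!is.null(a$type) && identical(a$type, "HETATM")) "HETATM" else "ATOM"
  name <- a$name
  name <- if (nchar(name) <= 3) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial, name, " ", a$resname, a$chain, a$resid, " ",
          x, y, z, 1.00, 0.00, a$element)
}

model_pdb_lines <- function(model, xyz) {
  atoms <- model$atoms
  vapply(seq_len(nrow(atoms)), function(i) {
    format_pdb_atom(as.list(atoms[i, ]), xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
}

#' Write a structure model to a single-model PDB file
#' @param model a `structure_model`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_structure <- function(model, path) {
  lines <- c(model_pdb_lines(model, structure_coords(model)), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write an ensemble to a multi-model PDB file
#' @param ensemble an `md_ensemble`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_ensemble <- function(ensemble, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(model_pdb_lines(ensemble$topology,
                               ensemble$coords[f, , , drop = TRUE]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
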