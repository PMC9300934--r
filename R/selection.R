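# Atom selections and atom references.
#
# Selections are conjunctive mini-expressions over the atom table, e.g.
#   "chain A and resid 521-777 and name CA"
# Clauses: chain <id>, resid <n|a-b|n,m,...>, resname <NAME[,NAME]>,
# name <NAME[,NAME]>, or "all". Order of matched atoms is always file order.

parse_selection <- function(expression) {
  expression <- trimws(expression)
  if (!nzchar(expression)) stop("empty selection expression")
  clauses <- strsplit(expression, "\\s+and\\s+")[[1]]
  lapply(clauses, function(cl) {
    cl <- trimws(cl)
    if (identical(tolower(cl), "all")) return(list(field = "all"))
    parts <- strsplit(cl, "\\s+")[[1]]
    if (length(parts) != 2) {
      stop("cannot parse selection clause: '", cl, "'")
    }
    field <- tolower(parts[1])
    value <- parts[2]
    if (!field %in% c("chain", "resid", "resname", "name")) {
      stop("unknown selection keyword: '", field, "'")
    }
    if (field == "resid") {
      ids <- integer(0)
      for (tok in strsplit(value, ",")[[1]]) {
        if (grepl("-", tok)) {
          rng <- as.integer(strsplit(tok, "-")[[1]])
          if (length(rng) != 2 || anyNA(rng)) stop("bad resid range: '", tok, "'")
          ids <- c(ids, seq(rng[1], rng[2]))
        } else {
          id <- as.integer(tok)
          if (is.na(id)) stop("bad resid: '", tok, "'")
          ids <- c(ids, id)
        }
      }
      return(list(field = "resid", value = ids))
    }
    list(field = field, value = strsplit(value, ",")[[1]])
  })
}

#' Resolve an atom selection to atom indices
#'
#' Resolves a selection expression (e.g. `"chain A and resid 580-599 and
#' name CA"`) against the topology, returning atom indices in file order.
#' The order is deterministic and identical for every frame of an ensemble.
#'
#' @param x a `structure_model` or `md_ensemble`.
#' @param selection selection expression string.
#' @return integer vector of atom indices (1-based, file order).
#' @export
resolve_selection <- function(x, selection) {
  model <- if (inherits(x, "md_ensemble")) x$topology else x
  atoms <- model$atoms
  keep <- rep(TRUE, nrow(atoms))
  for (clause in parse_selection(selection)) {
    keep <- keep & switch(clause$field,
      all = TRUE,
      chain = atoms$chain %in% clause$value,
      resid = atoms$resid %in% clause$value,
      resname = atoms$resname %in% clause$value,
      name = atoms$name %in% clause$value
    )
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    stop("empty selection: '", selection, "' matches no atoms")
  }
  idx
}

#' Map LXXLL-style motif labels to residues
#'
#' Anchors relative residue labels at the first leucine of the cofactor
#' peptide's LXXLL motif (leucines at motif positions 1, 4 and 5). A label
#' of the form `"<letter>+<k>"` (e.g. `"L+1"`, `"L+5"`, `"R+2"`) resolves to
#' motif position k, i.e. residue `anchor + k - 1` of the peptide chain.
#'
#' @param topology a `structure_model` containing the peptide chain.
#' @param chain chain identifier of the cofactor peptide.
#' @return named list mapping labels `"L+1"`..`"L+5"` and `"R+2"` to
#'   `list(chain, resid)`; class `motif_mapping`.
#' @export
motif_mapping <- function(topology, chain) {
  res <- residue_table(topology)
  res <- res[res$chain == chain, ]
  if (nrow(res) < 5) stop("chain ", chain, " has fewer than 5 residues")
  anchor <- NA_integer_
  for (i in seq_len(nrow(res) - 4)) {
    if (res$resname[i] == "LEU" && res$resname[i + 3] == "LEU" &&
        res$resname[i + 4] == "LEU") {
      anchor <- i
      break
    }
  }
  if (is.na(anchor)) stop("no LXXLL motif found on chain ", chain)
  labels <- c("L+1", "L+2", "L+3", "L+4", "L+5", "R+2")
  positions <- c(1L, 2L, 3L, 4L, 5L, 2L)
  mapping <- list()
  for (j in seq_along(labels)) {
    row <- res[anchor + positions[j] - 1L, ]
    mapping[[labels[j]]] <- list(chain = row$chain, resid = row$resid)
  }
  structure(mapping, class = "motif_mapping")
}

#' Resolve an atom reference to a single atom index
#'
#' Atom references name exactly one atom, either absolutely as
#' `"chain:resid:name"` (e.g. `"A:590:OD1"`) or through a motif label as
#' `"label:name"` (e.g. `"R+2:NE"`, requiring `motif`).
#'
#' @param x a `structure_model` or `md_ensemble`.
#' @param ref reference string.
#' @param motif optional `motif_mapping` for relative labels.
#' @return single integer atom index.
#' @export
resolve_atom_ref <- function(x, ref, motif = NULL) {
  model <- if (inherits(x, "md_ensemble")) x$topology else x
  parts <- strsplit(ref, ":")[[1]]
  if (length(parts) == 3) {
    chain <- parts[1]; resid <- as.integer(parts[2]); name <- parts[3]
    if (is.na(resid)) stop("bad atom reference: '", ref, "'")
  } else if (length(parts) == 2) {
    if (is.null(motif)) {
      stop("atom reference '", ref, "' uses a motif label but no motif mapping was given")
    }
    entry <- motif[[parts[1]]]
    if (is.null(entry)) stop("unknown motif label: '", parts[1], "'")
    chain <- entry$chain; resid <- entry$resid; name <- parts[2]
  } else {
    stop("bad atom reference: '", ref, "' (expected chain:resid:name or label:name)")
  }
  atoms <- model$atoms
  idx <- which(atoms$chain == chain & atoms$resid == resid & atoms$name == name)
  if (length(idx) == 0) stop("atom reference '", ref, "' resolves to no atom")
  if (length(idx) > 1) stop("atom reference '", ref, "' is ambiguous (", length(idx), " atoms)")
  idx
}
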