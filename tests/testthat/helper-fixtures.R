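# Fixture builders shared across the test suite. Everything is generated in
# code; no binary fixtures.

`%||%` <- function(a, b) if (is.null(a)) b else a

# one atom per residue by default
toy_model <- function(xyz, name = "CA", resname = "ALA", chain = "A",
                      resid = NULL, element = "C") {
  n <- nrow(xyz)
  resid <- resid %||% seq_len(n)
  structure_model(data.frame(
    serial = seq_len(n),
    name = rep_len(name, n), resname = rep_len(resname, n),
    resid = resid, chain = rep_len(chain, n),
    element = rep_len(element, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

ensemble_from_frames <- function(frames, model) {
  coords <- array(NA_real_, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  md_ensemble(coords, model)
}

# uniform per-atom parameter table for a model
uniform_params <- function(model, charge = 0, eps = 0.12, rmin_half = 1.908,
                           born = 1.7) {
  n <- nrow(model$atoms)
  data.frame(serial = model$atoms$serial,
             charge_e = rep_len(charge, n),
             lj_rmin_half_A = rep_len(rmin_half, n),
             lj_eps_kcal_mol = rep_len(eps, n),
             born_radius_A = rep_len(born, n))
}

# hand-written PDB text lines (independent of the package's writer)
pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          record = "ATOM") {
  nm <- if (nchar(name) <= 3) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          record, serial, nm, resname, chain, resid, x, y, z)
}

random_rigid_transform <- function() {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  list(R = R, t = stats::runif(3, -10, 10))
}

apply_rigid <- function(xyz, tr) sweep(xyz %*% tr$R, 2, tr$t, "+")

# build a contact_network object directly from an edge table
make_network <- function(nodes, edges) {
  nt <- data.frame(key = nodes,
                   chain = sub(":.*", "", nodes),
                   resid = as.integer(sub(".*:", "", nodes)),
                   resname = "ALA", stringsAsFactors = FALSE)
  e <- data.frame(i = match(edges$a, nodes), j = match(edges$b, nodes),
                  node_a = edges$a, node_b = edges$b,
                  occupancy = edges$occupancy %||% rep(1, nrow(edges)),
                  abs_c = edges$abs_c %||% exp(-edges$weight),
                  weight = edges$weight, stringsAsFactors = FALSE)
  structure(list(edges = e, nodes = nt, settings = list()),
            class = "contact_network")
}

# random connected-ish weighted graph as a contact_network
random_network <- function(n, p = 0.5) {
  nodes <- sprintf("A:%d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  # always keep a spanning path so the graph is connected
  path_pairs <- cbind(seq_len(n - 1), 2:n)
  sel <- unique(rbind(pairs[keep, , drop = FALSE], path_pairs))
  make_network(nodes, data.frame(a = nodes[sel[, 1]], b = nodes[sel[, 2]],
                                 weight = stats::runif(nrow(sel), 0.1, 2)))
}

network_as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("node_a", "node_b")],
                                     directed = FALSE, vertices = net$nodes$key)
  igraph::E(g)$weight <- net$edges$weight
  g
}

# exhaustive enumeration of all simple paths between two nodes (oracle)
enumerate_simple_paths <- function(net, source, target) {
  n <- nrow(net$nodes)
  adj <- matrix(Inf, n, n)
  for (r in seq_len(nrow(net$edges))) {
    adj[net$edges$i[r], net$edges$j[r]] <- net$edges$weight[r]
    adj[net$edges$j[r], net$edges$i[r]] <- net$edges$weight[r]
  }
  si <- match(source, net$nodes$key); ti <- match(target, net$nodes$key)
  out <- list()
  recurse <- function(path, len) {
    cur <- path[length(path)]
    if (cur == ti) {
      out[[length(out) + 1L]] <<- list(path = path, len = len)
      return()
    }
    for (nb in which(is.finite(adj[cur, ]))) {
      if (!(nb %in% path)) recurse(c(path, nb), len + adj[cur, nb])
    }
  }
  recurse(si, 0)
  out
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
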