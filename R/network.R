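# Occupancy-gated, correlation-weighted residue interaction network:
# contacts (<= 4.5 A in >= 75% of frames), edge weights d_ij = -log|C_ij|,
# Girvan-Newman communities, inter-community connectivity, and
# optimal/suboptimal source-target paths (Floyd-Warshall).

#' Residue contact occupancy over an ensemble
#'
#' Two residues are in contact in a frame when their minimum heavy-atom
#' distance (default) or C-alpha distance is at or below the cutoff. The
#' occupancy is the fraction of frames in contact; residue pairs closer than
#' `exclusion` in sequence on the same chain are excluded (trivial backbone
#' contacts).
#'
#' @param ensemble an `md_ensemble`.
#' @param node_sel selection defining the node atoms (default `"all"`; one
#'   node per residue of the selection).
#' @param cutoff contact distance cutoff, Angstrom (default 4.5).
#' @param min_occupancy minimum fraction of frames (default 0.75).
#' @param contact_mode `"heavy"` (minimum over all selected atoms of the two
#'   residues) or `"ca"` (C-alpha only).
#' @param exclusion exclude same-chain pairs with |resid_i - resid_j| <=
#'   exclusion (default 1).
#' @return object of class `contact_adjacency`: `occupancy` (R x R fraction
#'   matrix), `adjacency` (logical), `nodes` (residue table), settings.
#' @export
contact_occupancy <- function(ensemble, node_sel = "all", cutoff = 4.5,
                              min_occupancy = 0.75,
                              contact_mode = c("heavy", "ca"),
                              exclusion = 1) {
  contact_mode <- match.arg(contact_mode)
  idx <- resolve_selection(ensemble, node_sel)
  if (contact_mode == "ca") {
    atoms <- ensemble$topology$atoms
    idx <- idx[atoms$name[idx] == "CA"]
    if (length(idx) == 0) stop("no C-alpha atoms in node selection")
  }
  res_idx <- atom_residue_index(ensemble)[idx]
  res_ids <- unique(res_idx)
  res_tab <- residue_table(ensemble)[res_ids, ]
  R <- length(res_ids)
  if (R == 0) stop("empty node set")
  # atom -> node indicator matrix
  M <- matrix(0, length(idx), R)
  M[cbind(seq_along(idx), match(res_idx, res_ids))] <- 1
  F_ <- n_frames(ensemble)
  count <- matrix(0, R, R)
  cut2 <- cutoff^2
  for (f in seq_len(F_)) {
    xyz <- ensemble$coords[f, idx, , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
    A <- (d2 <= cut2) * 1
    count <- count + ((t(M) %*% A %*% M) > 0)
  }
  occupancy <- count / F_
  diag(occupancy) <- 0
  adjacency <- occupancy >= min_occupancy
  if (exclusion >= 0) {
    same_chain <- outer(res_tab$chain, res_tab$chain, "==")
    near <- abs(outer(res_tab$resid, res_tab$resid, "-")) <= exclusion
    adjacency[same_chain & near] <- FALSE
  }
  dimnames(occupancy) <- list(res_tab$key, res_tab$key)
  dimnames(adjacency) <- dimnames(occupancy)
  structure(list(occupancy = occupancy, adjacency = adjacency,
                 nodes = res_tab,
                 settings = list(cutoff = cutoff, min_occupancy = min_occupancy,
                                 contact_mode = contact_mode,
                                 exclusion = exclusion)),
            class = "contact_adjacency")
}

#' Weight contact edges by correlation
#'
#' Edge weight d_ij = -log(|C_ij|) (natural log by default, base 10 by
#' flag): highly correlated residue pairs become short, so shortest paths
#' trace correlated chains. Edges with |C| = 0 are dropped (infinite
#' distance); masked (NA) correlations drop the edge with a warning.
#'
#' @param adjacency a `contact_adjacency`.
#' @param dccm a `dccm_matrix` covering all nodes (matching residue keys).
#' @param log_base base of the logarithm (default e).
#' @return object of class `contact_network`: `edges` (data.frame node_a,
#'   node_b, occupancy, abs_c, weight), `nodes`.
#' @export
weight_edges <- function(adjacency, dccm, log_base = exp(1)) {
  keys <- adjacency$nodes$key
  if (!all(keys %in% rownames(dccm))) {
    stop("DCCM is missing nodes: ",
         paste(setdiff(keys, rownames(dccm)), collapse = ", "))
  }
  C <- unclass(dccm)[keys, keys]
  adj <- adjacency$adjacency
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  absC <- abs(C[pairs])
  masked <- is.na(absC)
  if (any(masked)) {
    warning(sum(masked), " edge(s) dropped: masked correlation")
  }
  zero <- !masked & absC == 0
  keep <- !masked & !zero
  edges <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                      node_a = keys[pairs[keep, 1]],
                      node_b = keys[pairs[keep, 2]],
                      occupancy = adjacency$occupancy[pairs[keep, , drop = FALSE]],
                      abs_c = absC[keep],
                      weight = pmax(-log(pmin(absC[keep], 1)) / log(log_base), 0),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = adjacency$nodes,
                 settings = c(adjacency$settings, list(log_base = log_base))),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("contact_network: %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

network_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = network$nodes$key)
  igraph::E(g)$distance <- network$edges$weight
  igraph::E(g)$abs_c <- network$edges$abs_c
  g
}

# distance matrix (R x R, Inf where no edge) from the edge list
network_dist_matrix <- function(network) {
  keys <- network$nodes$key
  n <- length(keys)
  D <- matrix(Inf, n, n, dimnames = list(keys, keys))
  diag(D) <- 0
  e <- network$edges
  D[cbind(e$i, e$j)] <- e$weight
  D[cbind(e$j, e$i)] <- e$weight
  D
}

#' Girvan-Newman community detection
#'
#' Weighted Girvan-Newman: edge betweenness is computed with d_ij =
#' -log|C_ij| as the distance, divided by the edge's correlation weight
#' |C_ij| (Newman's prescription for weighted graphs, so that strongly
#' correlated edges are not removed merely for carrying much of the
#' shortest-path traffic), and the highest-scoring edge is removed
#' iteratively. The component partition of maximal modularity along the
#' hierarchy is returned; modularity is evaluated on the original graph
#' with |C_ij| as edge similarity weights. Ties are broken by the
#' deterministic edge order (lexicographic residue keys), so results are
#' bit-stable.
#'
#' @param network a `contact_network`.
#' @return object of class `community_partition`: `membership` (named integer
#'   vector, labels renumbered in node order), `modularity`, `n_communities`.
#' @export
detect_communities <- function(network) {
  if (nrow(network$edges) == 0) stop("empty network")
  g0 <- network_igraph(network)
  sim <- igraph::E(g0)$abs_c
  g <- g0
  best <- list(modularity = -Inf, membership = NULL)
  repeat {
    comp <- igraph::components(g)$membership
    q <- igraph::modularity(g0, comp[igraph::V(g0)$name], weights = sim)
    if (q > best$modularity + 1e-12) {
      best <- list(modularity = q, membership = comp[igraph::V(g0)$name])
    }
    if (igraph::ecount(g) == 0) break
    eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$distance)
    g <- igraph::delete_edges(g, which.max(eb / igraph::E(g)$abs_c))
  }
  memb <- best$membership
  # renumber labels by first appearance in node order
  memb <- match(memb, unique(memb))
  names(memb) <- network$nodes$key
  structure(list(membership = memb, modularity = best$modularity,
                 n_communities = length(unique(memb))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, modularity %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

# all-pairs shortest distances and next-hop matrix by Floyd-Warshall
floyd_warshall <- function(network) {
  D <- network_dist_matrix(network)
  n <- nrow(D)
  nxt <- matrix(NA_integer_, n, n)
  has_edge <- is.finite(D) & (row(D) != col(D))
  nxt[has_edge] <- col(D)[has_edge]
  diag(nxt) <- seq_len(n)
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], "+")
    improve <- via < D - 1e-12
    if (any(improve)) {
      D[improve] <- via[improve]
      nxt[improve] <- matrix(nxt[, k], n, n)[improve]
    }
  }
  list(dist = D, next_hop = nxt, keys = rownames(D))
}

fw_path <- function(fw, si, ti) {
  if (!is.finite(fw$dist[si, ti])) return(NULL)
  path <- si
  cur <- si
  while (cur != ti) {
    cur <- fw$next_hop[path[length(path)], ti]
    if (is.na(cur)) return(NULL)
    path <- c(path, cur)
    if (length(path) > length(fw$keys)) stop("path reconstruction cycle")
  }
  path
}

node_index <- function(network, node) {
  i <- match(node, network$nodes$key)
  if (is.na(i)) stop("node not in network: ", node)
  i
}

make_path_result <- function(network, path_idx, length_raw) {
  keys <- network$nodes$key[path_idx]
  structure(list(found = TRUE, nodes = keys,
                 residues = network$nodes$resid[path_idx],
                 length = length_raw,
                 length_x100 = as.integer(round(100 * length_raw)),
                 n_residues = length(path_idx)),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  if (!isTRUE(x$found)) {
    cat("path_result: no path\n")
  } else {
    cat(sprintf("path_result: length %.4f (x100: %d), %d residues: %s\n",
                x$length, x$length_x100, x$n_residues,
                paste(x$nodes, collapse = " -> ")))
  }
  invisible(x)
}

#' Optimal (minimum-weight) path between two residues
#'
#' Floyd-Warshall shortest path over edge weights d_ij = -log|C_ij|, with
#' path reconstruction. Reports the raw weighted length, the x100-rounded
#' integer length, and the residue count. Disconnected source/target yields
#' a no-path result (`found = FALSE`), not an error.
#'
#' @param network a `contact_network`.
#' @param source,target residue keys ("chain:resid").
#' @return a `path_result`.
#' @export
optimal_path <- function(network, source, target) {
  si <- node_index(network, source)
  ti <- node_index(network, target)
  fw <- floyd_warshall(network)
  if (si == ti) return(make_path_result(network, si, 0))
  p <- fw_path(fw, si, ti)
  if (is.null(p)) {
    return(structure(list(found = FALSE, nodes = character(0),
                          residues = integer(0), length = Inf,
                          length_x100 = NA_integer_, n_residues = 0L),
                     class = "path_result"))
  }
  make_path_result(network, p, fw$dist[si, ti])
}

#' Suboptimal paths within a length tolerance of the optimal path
#'
#' Enumerates all simple source-target paths of weighted length at most
#' optimal + delta (depth-first search pruned by the Floyd-Warshall
#' distance-to-target bound), sorted by length then lexicographic node
#' order. Optionally truncated to the k shortest.
#'
#' @param network a `contact_network`.
#' @param source,target residue keys.
#' @param delta length tolerance above the optimum, in raw weight units
#'   (default 0.2, i.e. 20 in the x100 integer convention).
#' @param max_k optional cap on the number of returned paths.
#' @return list of `path_result`, optimal first.
#' @export
suboptimal_paths <- function(network, source, target, delta = 0.2, max_k = NULL) {
  si <- node_index(network, source)
  ti <- node_index(network, target)
  fw <- floyd_warshall(network)
  if (!is.finite(fw$dist[si, ti])) return(list())
  bound <- fw$dist[si, ti] + delta + 1e-12
  D <- network_dist_matrix(network)
  n <- nrow(D)
  neighbours <- lapply(seq_len(n), function(i) which(is.finite(D[i, ]) & seq_len(n) != i))
  paths <- list()
  visit <- function(path, len) {
    cur <- path[length(path)]
    if (cur == ti) {
      paths[[length(paths) + 1L]] <<- list(path = path, len = len)
      return()
    }
    for (nb in neighbours[[cur]]) {
      if (nb %in% path) next
      new_len <- len + D[cur, nb]
      if (new_len + fw$dist[nb, ti] <= bound) visit(c(path, nb), new_len)
    }
  }
  visit(si, 0)
  keys <- network$nodes$key
  ord <- order(vapply(paths, function(p) p$len, numeric(1)),
               vapply(paths, function(p) paste(keys[p$path], collapse = "|"),
                      character(1)))
  paths <- paths[ord]
  if (!is.null(max_k)) paths <- paths[seq_len(min(max_k, length(paths)))]
  lapply(paths, function(p) make_path_result(network, p$path, p$len))
}

#' Inter-community connectivity from all-pairs shortest paths
#'
#' For every unordered node pair, reconstructs the shortest path and counts,
#' for each community pair (p, q), how many of those paths traverse an edge
#' crossing the p-q boundary. The counts mirror the line widths of community
#' network diagrams.
#'
#' @param network a `contact_network`.
#' @param partition a `community_partition` over the same nodes.
#' @return symmetric k x k count matrix (k communities).
#' @export
intercommunity_connectivity <- function(network, partition) {
  memb <- partition$membership[network$nodes$key]
  k <- max(memb)
  counts <- matrix(0L, k, k)
  if (k == 1) return(counts[0, 0, drop = FALSE])
  fw <- floyd_warshall(network)
  n <- nrow(network$nodes)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      p <- fw_path(fw, s, t)
      if (is.null(p) || length(p) < 2) next
      cm <- memb[p]
      cross <- which(cm[-1] != cm[-length(cm)])
      for (ci in cross) {
        a <- cm[ci]; b <- cm[ci + 1]
        counts[a, b] <- counts[a, b] + 1L
        counts[b, a] <- counts[b, a] + 1L
      }
    }
  }
  counts
}
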