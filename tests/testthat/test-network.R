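test_that("contact occupancy counts frames like a brute-force loop", {
  # two residues fixed 3 A apart: occupancy 1, edge present
  m2 <- toy_model(rbind(c(0, 0, 0), c(3, 0, 0)), resid = c(1, 5))
  ens2 <- ensemble_from_frames(list(structure_coords(m2), structure_coords(m2)), m2)
  adj <- contact_occupancy(ens2, "all", exclusion = 1)
  expect_equal(adj$occupancy[1, 2], 1.0)
  expect_true(adj$adjacency[1, 2])

  # contact in half the frames: no edge at the 75% threshold
  far <- rbind(c(0, 0, 0), c(9, 0, 0))
  ens_half <- ensemble_from_frames(list(structure_coords(m2), far,
                                        structure_coords(m2), far), m2)
  adj_half <- contact_occupancy(ens_half, "all", exclusion = 1)
  expect_equal(adj_half$occupancy[1, 2], 0.5)
  expect_false(adj_half$adjacency[1, 2])

  # 6-residue chain with 2 atoms per residue vs frame-by-frame brute force
  set.seed(60)
  toy <- build_toy_complex(6, include_ligand = FALSE, include_peptide = FALSE)
  s <- sample_ensemble(toy$model, diag(6), n_frames = 40, seed = 2,
                       per_residue_sigma = 0.4)
  ens <- s$ensemble
  adj6 <- contact_occupancy(ens, "all", cutoff = 4.5, exclusion = 1)
  res_of <- atom_residue_index(ens)
  brute <- matrix(0, 6, 6)
  for (f in 1:40) {
    xyz <- ens$coords[f, , , drop = TRUE]
    D <- as.matrix(dist(xyz))
    for (i in 1:5) {
      for (j in (i + 1):6) {
        dmin <- min(D[res_of == i, res_of == j])
        if (dmin <= 4.5) {
          brute[i, j] <- brute[i, j] + 1
          brute[j, i] <- brute[j, i] + 1
        }
      }
    }
  }
  expect_equal(unname(adj6$occupancy), brute / 40)
  # sequence neighbours are excluded from adjacency
  expect_false(any(diag(adj6$adjacency[-1, ])))
})

test_that("raising the occupancy threshold never adds edges", {
  set.seed(61)
  toy <- build_toy_complex(8, include_ligand = FALSE, include_peptide = FALSE)
  s <- sample_ensemble(toy$model, diag(8), n_frames = 50, seed = 3,
                       per_residue_sigma = 0.8)
  lo <- contact_occupancy(s$ensemble, "all", min_occupancy = 0.5)
  hi <- contact_occupancy(s$ensemble, "all", min_occupancy = 0.9)
  expect_true(all(lo$adjacency | !hi$adjacency))
})

test_that("edge weights follow -log|C|", {
  m <- toy_model(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)), resid = c(1, 3, 5))
  ens <- ensemble_from_frames(list(structure_coords(m), structure_coords(m)), m)
  adj <- contact_occupancy(ens, "all", cutoff = 3.5, exclusion = 1)
  C <- matrix(c(1, 1, 0, 1, 1, exp(-1), 0, exp(-1), 1), 3, 3,
              dimnames = list(c("A:1", "A:3", "A:5"), c("A:1", "A:3", "A:5")))
  net <- weight_edges(adj, C)
  w <- setNames(net$edges$weight, paste(net$edges$node_a, net$edges$node_b))
  expect_equal(unname(w["A:1 A:3"]), 0)          # |C| = 1 -> d = 0
  expect_equal(unname(w["A:3 A:5"]), 1.0)        # |C| = e^-1 -> d = 1
  C2 <- C; C2[1, 2] <- C2[2, 1] <- 0.5
  net2 <- weight_edges(adj, C2)
  w2 <- setNames(net2$edges$weight, paste(net2$edges$node_a, net2$edges$node_b))
  expect_equal(unname(w2["A:1 A:3"]), 0.693147, tolerance = 1e-6)
  # base-10 flag
  net10 <- weight_edges(adj, C2, log_base = 10)
  w10 <- setNames(net10$edges$weight, paste(net10$edges$node_a, net10$edges$node_b))
  expect_equal(unname(w10["A:1 A:3"]), log10(2), tolerance = 1e-9)
  # masked correlation drops the edge with a warning
  C3 <- C; C3[1, 2] <- C3[2, 1] <- NA
  expect_warning(net3 <- weight_edges(adj, C3), "masked")
  expect_false(any(net3$edges$node_a == "A:1" & net3$edges$node_b == "A:3"))
})

test_that("Floyd-Warshall agrees with Dijkstra on random graphs", {
  set.seed(62)
  for (trial in 1:50) {
    net <- random_network(sample(5:9, 1))
    fw <- allodyn:::floyd_warshall(net)
    g <- network_as_igraph(net)
    ig <- igraph::distances(g, weights = igraph::E(g)$weight,
                            algorithm = "dijkstra")
    expect_equal(fw$dist, ig[rownames(fw$dist), colnames(fw$dist)],
                 tolerance = 1e-9)
  }
})

test_that("optimal paths match exhaustive enumeration", {
  # a direct heavier edge beats a lighter-looking two-hop route
  net <- make_network(c("A:1", "A:2", "A:3"),
                      data.frame(a = c("A:1", "A:1", "A:2"),
                                 b = c("A:3", "A:2", "A:3"),
                                 weight = c(0.5, 0.3, 0.3)))
  p <- optimal_path(net, "A:1", "A:3")
  expect_equal(p$nodes, c("A:1", "A:3"))
  expect_equal(p$length, 0.5)
  expect_equal(p$length_x100, 50L)
  # source = target
  p0 <- optimal_path(net, "A:2", "A:2")
  expect_equal(p0$length, 0)
  expect_equal(p0$nodes, "A:2")
  # random graphs vs brute-force enumeration of simple paths
  set.seed(63)
  for (trial in 1:10) {
    netr <- random_network(6)
    all_paths <- enumerate_simple_paths(netr, "A:1", "A:6")
    best <- min(vapply(all_paths, function(x) x$len, numeric(1)))
    po <- optimal_path(netr, "A:1", "A:6")
    expect_equal(po$length, best, tolerance = 1e-9)
  }
  # disconnected target: a no-path result, not an exception
  net_dis <- make_network(c("A:1", "A:2", "A:3"),
                          data.frame(a = "A:1", b = "A:2", weight = 1))
  pd <- optimal_path(net_dis, "A:1", "A:3")
  expect_false(pd$found)
  expect_error(optimal_path(net_dis, "A:1", "A:9"), "not in network")
})

test_that("path lengths decompose edge by edge", {
  set.seed(64)
  net <- random_network(7)
  p <- optimal_path(net, "A:1", "A:7")
  if (p$found && p$n_residues > 2) {
    tail_p <- optimal_path(net, p$nodes[2], "A:7")
    D <- allodyn:::network_dist_matrix(net)
    first_edge <- D[match(p$nodes[1], net$nodes$key),
                    match(p$nodes[2], net$nodes$key)]
    expect_lte(tail_p$length, p$length - first_edge + 1e-9)
  }
  expect_equal(sum(diff(seq_along(p$nodes))), p$n_residues - 1)
})

test_that("suboptimal paths equal an exhaustive filtered enumeration", {
  # exactly two equal-length routes: both returned, deterministic order
  net_tie <- make_network(c("A:1", "A:2", "A:3", "A:4"),
                          data.frame(a = c("A:1", "A:2", "A:1", "A:3"),
                                     b = c("A:2", "A:4", "A:3", "A:4"),
                                     weight = c(1, 1, 1, 1)))
  subs <- suboptimal_paths(net_tie, "A:1", "A:4", delta = 0)
  expect_length(subs, 2)
  expect_equal(subs[[1]]$nodes, c("A:1", "A:2", "A:4"))  # lexicographic tie order
  expect_equal(subs[[2]]$nodes, c("A:1", "A:3", "A:4"))
  # delta = 0 keeps only optimal-length paths
  expect_true(all(vapply(subs, function(p) p$length, numeric(1)) ==
                    subs[[1]]$length))
  # 7-node graphs with a generous delta vs exhaustive enumeration
  set.seed(65)
  for (trial in 1:5) {
    netr <- random_network(7)
    delta <- 1.0
    subs <- suboptimal_paths(netr, "A:1", "A:7", delta = delta)
    all_paths <- enumerate_simple_paths(netr, "A:1", "A:7")
    lens <- sort(vapply(all_paths, function(x) x$len, numeric(1)))
    keep <- lens[lens <= lens[1] + delta + 1e-12]
    expect_equal(sort(vapply(subs, function(p) p$length, numeric(1))), keep,
                 tolerance = 1e-9)
    # k-shortest truncation
    expect_length(suboptimal_paths(netr, "A:1", "A:7", delta = delta, max_k = 1), 1)
  }
})

test_that("communities split cliques at the bridge", {
  clique_edges <- function(nodes) {
    pr <- t(combn(nodes, 2))
    data.frame(a = pr[, 1], b = pr[, 2], weight = 0.2, abs_c = 0.8)
  }
  left <- sprintf("A:%d", 1:6); right <- sprintf("A:%d", 11:16)
  edges <- rbind(clique_edges(left), clique_edges(right),
                 data.frame(a = "A:6", b = "A:11", weight = 2.5, abs_c = 0.08))
  net <- make_network(c(left, right), edges)
  part <- detect_communities(net)
  expect_equal(part$n_communities, 2)
  memb <- part$membership
  expect_true(same_partition(memb, rep(1:2, each = 6)))
  expect_true(part$modularity >= -0.5 && part$modularity <= 1)
  # a single clique stays together
  net1 <- make_network(left, clique_edges(left))
  expect_equal(detect_communities(net1)$n_communities, 1)
})

test_that("inter-community connectivity counts boundary crossings", {
  left <- sprintf("A:%d", 1:4); right <- sprintf("A:%d", 11:14)
  clique_edges <- function(nodes) {
    pr <- t(combn(nodes, 2))
    data.frame(a = pr[, 1], b = pr[, 2], weight = 0.2, abs_c = 0.8)
  }
  edges <- rbind(clique_edges(left), clique_edges(right),
                 data.frame(a = "A:4", b = "A:11", weight = 2.5, abs_c = 0.08))
  net <- make_network(c(left, right), edges)
  part <- detect_communities(net)
  conn <- intercommunity_connectivity(net, part)
  expect_equal(dim(conn), c(2, 2))
  expect_equal(conn[1, 2], conn[2, 1])  # symmetric
  # every cross-community pair routes over the single bridge exactly once
  expect_equal(conn[1, 2], 4 * 4)
  # one community: empty matrix
  net1 <- make_network(left, clique_edges(left))
  conn1 <- intercommunity_connectivity(net1, detect_communities(net1))
  expect_equal(length(conn1), 0)
})
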