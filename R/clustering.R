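# k-means clustering of superposed frames and representative structures.
#
# Feature space is the flattened Cartesian coordinates of the selection
# after superposition (the cpptraj convention). Lloyd iterations with
# k-means++ seeding from an explicit seed; empty clusters are re-seeded from
# the point farthest from its assigned centroid, so k clusters always
# survive.

frame_features <- function(ensemble, sel) {
  idx <- resolve_selection(ensemble, sel)
  F_ <- n_frames(ensemble)
  X <- matrix(NA_real_, F_, 3 * length(idx))
  for (ax in 1:3) {
    Xa <- ensemble$coords[, idx, ax, drop = TRUE]
    if (is.null(dim(Xa))) Xa <- matrix(Xa, nrow = F_)
    X[, seq(ax, by = 3, length.out = length(idx))] <- Xa
  }
  X
}

sq_dist_to_centers <- function(X, centers) {
  # n x k matrix of squared Euclidean distances
  xx <- rowSums(X^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * X %*% t(centers)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- apply(sq_dist_to_centers(X, centers[1:(j - 1), , drop = FALSE]), 1, min)
      d2 <- pmax(d2, 0)
      if (sum(d2) <= 0) {
        centers[j, ] <- X[sample.int(n, 1), ]
      } else {
        centers[j, ] <- X[sample.int(n, 1, prob = d2), ]
      }
    }
  }
  centers
}

#' k-means clustering of ensemble frames
#'
#' @param ensemble a superposed `md_ensemble`.
#' @param sel selection defining the feature atoms (default C-alpha).
#' @param k number of clusters, 1 <= k <= F.
#' @param seed integer seed for the k-means++ initialisation.
#' @param max_iter maximum Lloyd iterations.
#' @param tol convergence threshold on the largest centroid shift (Angstrom).
#' @return object of class `cluster_result`: `assignments` (per-frame labels
#'   1..k), `centroids` (k x 3m), `inertia`, `representative_frames`
#'   (per-cluster frame index nearest its centroid), `iterations`,
#'   `inertia_trace`.
#' @export
kmeans_frames <- function(ensemble, sel = "name CA", k = 5, seed = 1,
                          max_iter = 100, tol = 1e-6) {
  F_ <- n_frames(ensemble)
  if (k < 1) stop("k must be at least 1")
  if (k > F_) stop("k (", k, ") exceeds the number of frames (", F_, ")")
  X <- frame_features(ensemble, sel)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  centers <- kmeanspp_init(X, k)
  assignments <- rep(1L, F_)
  inertia_trace <- numeric(0)
  iter <- 0
  repeat {
    iter <- iter + 1
    D2 <- sq_dist_to_centers(X, centers)
    assignments <- max.col(-D2, ties.method = "first")
    point_d2 <- D2[cbind(seq_len(F_), assignments)]
    # re-seed empty clusters from the globally farthest point
    for (j in seq_len(k)) {
      if (!any(assignments == j)) {
        far <- which.max(point_d2)
        centers[j, ] <- X[far, ]
        assignments[far] <- j
        point_d2[far] <- 0
      }
    }
    inertia_trace <- c(inertia_trace, sum(pmax(point_d2, 0)))
    new_centers <- centers
    for (j in seq_len(k)) {
      new_centers[j, ] <- colMeans(X[assignments == j, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol || iter >= max_iter) break
  }
  D2 <- sq_dist_to_centers(X, centers)
  assignments <- max.col(-D2, ties.method = "first")
  inertia <- sum(pmax(D2[cbind(seq_len(F_), assignments)], 0))
  reps <- vapply(seq_len(k), function(j) {
    members <- which(assignments == j)
    members[which.min(D2[members, j])]
  }, integer(1))
  structure(list(assignments = assignments, centroids = centers,
                 inertia = inertia, representative_frames = reps,
                 iterations = iter, inertia_trace = inertia_trace,
                 k = k, selection = sel),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k=%d, inertia=%.4g, sizes: %s\n", x$k, x$inertia,
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}

#' Representative structure of a cluster
#'
#' Returns the full-topology frame whose selected-coordinate vector is
#' nearest (Euclidean) to the cluster centroid.
#'
#' @param result a `cluster_result`.
#' @param ensemble the `md_ensemble` the clustering was computed on.
#' @param cluster cluster label (1..k).
#' @return a `structure_model`.
#' @export
representative_structure <- function(result, ensemble, cluster) {
  if (cluster < 1 || cluster > result$k) stop("invalid cluster label: ", cluster)
  frame <- result$representative_frames[cluster]
  if (is.na(frame)) stop("cluster ", cluster, " is empty")
  ensemble_frame(ensemble, frame)
}

#' Within-cluster inertia across a range of k (elbow report)
#'
#' @param ensemble a superposed `md_ensemble`.
#' @param sel feature selection.
#' @param k_range integer vector of k values.
#' @param seed seed passed to every run.
#' @return data.frame with columns `k`, `inertia`.
#' @export
kmeans_elbow <- function(ensemble, sel = "name CA", k_range = 1:8, seed = 1) {
  data.frame(k = k_range,
             inertia = vapply(k_range, function(k) {
               kmeans_frames(ensemble, sel, k = k, seed = seed)$inertia
             }, numeric(1)))
}
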