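# independent naive double-loop covariance/correlation oracle
naive_cov <- function(coords, idx) {
  F_ <- dim(coords)[1]; n <- length(idx)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dots <- numeric(F_)
      for (f in seq_len(F_)) {
        dots[f] <- sum(coords[f, idx[i], ] * coords[f, idx[j], ])
      }
      mi <- colMeans(coords[, idx[i], , drop = TRUE])
      mj <- colMeans(coords[, idx[j], , drop = TRUE])
      C[i, j] <- mean(dots) - sum(mi * mj)
    }
  }
  C
}

test_that("vectorised covariance equals the naive double loop", {
  set.seed(30)
  for (trial in 1:5) {
    model <- toy_model(matrix(rnorm(9), 3, 3))
    frames <- lapply(1:5, function(f) matrix(rnorm(9, sd = 2), 3, 3))
    ens <- ensemble_from_frames(frames, model)
    ens$superposed <- TRUE
    C <- covariance_matrix(ens, "name CA")
    expect_equal(unclass(C), naive_cov(ens$coords, 1:3),
                 tolerance = 1e-10, ignore_attr = TRUE)
    M <- dccm(ens, "name CA")
    oracle <- naive_cov(ens$coords, 1:3)
    d <- 1 / sqrt(diag(oracle))
    expect_equal(unclass(M), oracle * outer(d, d),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("covariance diagonals match the isotropic closed form", {
  set.seed(31)
  model <- toy_model(matrix(0, 2, 3))
  n <- 5000
  coords <- array(rnorm(n * 2 * 3), dim = c(n, 2, 3))
  ens <- md_ensemble(coords, model)
  ens$superposed <- TRUE
  C <- covariance_matrix(ens, "name CA")
  expect_equal(unname(diag(C)), c(3, 3), tolerance = 0.15)  # sigma^2 = 1 per axis
  # static ensemble: all-zero covariance
  stat <- ensemble_from_frames(list(matrix(1, 2, 3), matrix(1, 2, 3)), model)
  stat$superposed <- TRUE
  expect_equal(max(abs(covariance_matrix(stat, "name CA"))), 0)
})

test_that("perfect and mirrored motion give +1 and -1", {
  set.seed(32)
  model <- toy_model(matrix(0, 3, 3))
  base <- matrix(rnorm(60), 20, 3)
  frames <- lapply(1:20, function(f) rbind(base[f, ], base[f, ], -base[f, ]))
  ens <- ensemble_from_frames(frames, model)
  ens$superposed <- TRUE
  M <- dccm(ens, "name CA")
  expect_equal(M[1, 2], 1, tolerance = 1e-9)
  expect_equal(M[1, 3], -1, tolerance = 1e-9)
  expect_equal(diag(M), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(abs(M) <= 1 + 1e-12))
})

test_that("zero-variance atoms are masked, not zeroed", {
  set.seed(33)
  model <- toy_model(matrix(0, 2, 3))
  frames <- lapply(1:10, function(f) rbind(rnorm(3), c(5, 5, 5)))
  ens <- ensemble_from_frames(frames, model)
  ens$superposed <- TRUE
  expect_warning(M <- dccm(ens, "name CA"), "masked")
  expect_true(is.na(M[1, 2]))
  expect_true(is.na(M[2, 2]))
})

test_that("DCCM is invariant under a global rigid motion before refitting", {
  set.seed(34)
  toy <- build_toy_complex(10, include_ligand = FALSE, include_peptide = FALSE)
  corr <- plant_correlation(10, blocks = list(list(members = c(2, 7), rho = 0.8)))
  s <- sample_ensemble(toy$model, corr, n_frames = 300, seed = 8,
                       rigid_jitter = c(0, 0))
  e1 <- superpose(s$ensemble, fit_sel = "name CA")
  M1 <- dccm(e1, "name CA")
  tr <- random_rigid_transform()
  moved <- s$ensemble
  for (f in seq_len(n_frames(moved))) {
    moved$coords[f, , ] <- apply_rigid(moved$coords[f, , , drop = TRUE], tr)
  }
  M2 <- dccm(superpose(moved, reference = toy$model, fit_sel = "name CA"), "name CA")
  expect_lt(max(abs(M1 - M2)), 1e-9)
})

test_that("difference maps are antisymmetric and label-checked", {
  set.seed(35)
  toy <- build_toy_complex(8, include_ligand = FALSE, include_peptide = FALSE)
  corr_a <- plant_correlation(8, blocks = list(list(members = 1:4, rho = 0.8)))
  corr_b <- plant_correlation(8)
  # raw displacement ensembles (no jitter): difference maps are tested
  # independently of the superposition stage
  ens_a <- sample_ensemble(toy$model, corr_a, 2000, seed = 1,
                           rigid_jitter = c(0, 0))$ensemble
  ens_b <- sample_ensemble(toy$model, corr_b, 2000, seed = 2,
                           rigid_jitter = c(0, 0))$ensemble
  ens_a$superposed <- TRUE
  ens_b$superposed <- TRUE
  Ma <- dccm(ens_a, "name CA")
  Mb <- dccm(ens_b, "name CA")
  expect_equal(max(abs(dccm_difference(Ma, Ma))), 0)
  expect_equal(dccm_difference(Ma, Mb), -dccm_difference(Mb, Ma))
  # block present only in a: mean difference over the block near the plant
  blk <- dccm_difference(Ma, Mb)[1:4, 1:4]
  expect_equal(mean(blk[upper.tri(blk)]), 0.8, tolerance = 0.1)
  Mc <- Mb[-1, -1]
  class(Mc) <- class(Mb)
  expect_error(dccm_difference(Ma, Mc), "size")
})

test_that("subsampling frames leaves planted estimates stable", {
  set.seed(36)
  toy <- build_toy_complex(12, include_ligand = FALSE, include_peptide = FALSE)
  corr <- plant_correlation(12, blocks = list(list(members = c(3, 9), rho = 0.7)))
  s <- sample_ensemble(toy$model, corr, n_frames = 4000, seed = 5)
  ens <- superpose(s$ensemble, fit_sel = "name CA")
  M_full <- dccm(ens, "name CA")
  half <- ens
  half$coords <- ens$coords[seq(1, 4000, by = 2), , , drop = FALSE]
  M_half <- dccm(half, "name CA")
  expect_lt(abs(M_full[3, 9] - M_half[3, 9]), 0.05)
})
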