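euler_rot <- function(a) {
  cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# independent brute-force rigid-fit oracle: multi-start optimisation over
# Euler angles after centroid matching
brute_force_fit_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(a) sqrt(mean(rowSums((Pc %*% euler_rot(a) - Qc)^2)))
  best <- Inf
  for (s1 in seq(0, 2 * pi, length.out = 5)) {
    for (s2 in seq(0, pi, length.out = 4)) {
      for (s3 in seq(0, 2 * pi, length.out = 5)) {
        r <- stats::optim(c(s1, s2, s3), obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 5000))
        best <- min(best, r$value)
      }
    }
  }
  best
}

test_that("superposition removes pure rigid transforms exactly", {
  set.seed(41)
  ref_xyz <- matrix(rnorm(30, sd = 4), 10, 3)
  model <- toy_model(ref_xyz)
  tr90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  frames <- list(sweep(ref_xyz, 2, c(5, 5, 5), "+"),     # translation
                 ref_xyz %*% tr90,                        # 90 deg about z
                 apply_rigid(ref_xyz, random_rigid_transform()))
  ens <- superpose(ensemble_from_frames(frames, model), fit_sel = "name CA")
  expect_true(all(rmsd_series(ens, sel = "name CA") < 1e-6))
})

test_that("fitted rotations are always proper (no mirroring)", {
  set.seed(42)
  for (i in 1:20) {
    P <- matrix(rnorm(12, sd = 3), 4, 3)
    Q <- matrix(rnorm(12, sd = 3), 4, 3)
    fit <- allodyn:::kabsch_fit(P, Q)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("fit RMSD matches a brute-force optimiser on displaced clouds", {
  set.seed(43)
  Q <- matrix(rnorm(12, sd = 3), 4, 3)
  P <- Q + matrix(rnorm(12), 4, 3) / sqrt(3)  # ~1 A per-atom displacement
  model <- toy_model(Q)
  ens <- superpose(ensemble_from_frames(list(P), model), reference = model)
  expect_equal(rmsd_series(ens, model)[1], brute_force_fit_rmsd(P, Q),
               tolerance = 1e-6)
})

test_that("collinear fit atoms are rejected", {
  line <- cbind(1:4, 0, 0)
  model <- toy_model(line)
  ens <- ensemble_from_frames(list(line + 1), model)
  expect_error(superpose(ens), "collinear")
})

test_that("rmsd_series matches the direct formula", {
  set.seed(44)
  ref_xyz <- matrix(rnorm(15), 5, 3)
  model <- toy_model(ref_xyz)
  # identical copies give zero
  ens0 <- ensemble_from_frames(list(ref_xyz, ref_xyz), model)
  expect_equal(rmsd_series(ens0, model), c(0, 0))
  # one atom displaced 2 A in a 1-atom selection
  f <- ref_xyz; f[3, ] <- f[3, ] + c(0, 0, 2)
  ens1 <- ensemble_from_frames(list(f), model)
  expect_equal(rmsd_series(ens1, model, sel = "resid 3"), 2.0)
  # random frames against a hand-computed sqrt-mean-square
  frames <- lapply(1:5, function(i) ref_xyz + matrix(rnorm(15), 5, 3))
  ens <- ensemble_from_frames(frames, model)
  got <- rmsd_series(ens, model)
  expected <- vapply(frames, function(fr) {
    sqrt(mean(rowSums((fr - ref_xyz)^2)))
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("rmsf matches closed forms and scales linearly", {
  ref_xyz <- matrix(rnorm(9), 3, 3)
  model <- toy_model(ref_xyz)
  static <- ensemble_from_frames(list(ref_xyz, ref_xyz, ref_xyz), model)
  static$superposed <- TRUE
  expect_equal(rmsf_profile(static)$rmsf, rep(0, 3))
  # atom alternating +/- 1 A about its mean on one axis
  up <- ref_xyz; up[2, 1] <- up[2, 1] + 1
  dn <- ref_xyz; dn[2, 1] <- dn[2, 1] - 1
  alt <- ensemble_from_frames(list(up, dn, up, dn), model)
  alt$superposed <- TRUE
  expect_equal(rmsf_profile(alt)$rmsf[2], 1.0)
  # doubling the displacements doubles the RMSF
  up2 <- ref_xyz; up2[2, 1] <- up2[2, 1] + 2
  dn2 <- ref_xyz; dn2[2, 1] <- dn2[2, 1] - 2
  alt2 <- ensemble_from_frames(list(up2, dn2, up2, dn2), model)
  alt2$superposed <- TRUE
  expect_equal(rmsf_profile(alt2)$rmsf[2], 2 * rmsf_profile(alt)$rmsf[2])
  # single frame: fluctuation undefined
  expect_error(rmsf_profile(ensemble_from_frames(list(ref_xyz), model)),
               "fewer than 2 frames")
})

test_that("rmsf of isotropic Gaussian jitter approaches sigma * sqrt(3)", {
  set.seed(45)
  model <- toy_model(matrix(0, 1, 3))
  frames <- lapply(1:10000, function(i) matrix(rnorm(3, sd = 0.5), 1, 3))
  ens <- ensemble_from_frames(frames, model)
  ens$superposed <- TRUE
  expect_equal(rmsf_profile(ens)$rmsf, 0.5 * sqrt(3), tolerance = 0.02)
})
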