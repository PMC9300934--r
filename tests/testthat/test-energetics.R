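two_atom_frame <- function(r) rbind(c(0, 0, 0), c(r, 0, 0))

test_that("Lennard-Jones energies hit the analytic minimum and asymptote", {
  model <- toy_model(two_atom_frame(1))
  p <- uniform_params(model, eps = 0.2, rmin_half = 1.7)
  rmin <- 1.7 + 1.7
  expect_equal(lj_energy(two_atom_frame(rmin), 1, 2, p), -sqrt(0.2 * 0.2))
  expect_lt(abs(lj_energy(two_atom_frame(1e6), 1, 2, p)), 1e-12)
  expect_error(lj_energy(two_atom_frame(0.05), 1, 2, p), "overlap")
  expect_error(lj_energy(two_atom_frame(3), c(1, 2), 2, p), "disjoint")
})

test_that("multi-atom LJ sums match a pair-by-pair hand loop", {
  set.seed(50)
  xyz <- matrix(rnorm(15, sd = 3), 5, 3)
  model <- toy_model(xyz)
  p <- uniform_params(model)
  p$lj_eps_kcal_mol <- runif(5, 0.05, 0.3)
  p$lj_rmin_half_A <- runif(5, 1.5, 2.1)
  idxA <- 1:3; idxB <- 4:5
  hand <- 0
  for (i in idxA) {
    for (j in idxB) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      rm <- p$lj_rmin_half_A[i] + p$lj_rmin_half_A[j]
      ee <- sqrt(p$lj_eps_kcal_mol[i] * p$lj_eps_kcal_mol[j])
      hand <- hand + ee * ((rm / r)^12 - 2 * (rm / r)^6)
    }
  }
  expect_equal(lj_energy(xyz, idxA, idxB, p), hand, tolerance = 1e-10)
})

test_that("Coulomb energies reproduce the k_e identity", {
  model <- toy_model(two_atom_frame(1))
  p <- uniform_params(model, charge = 1)
  expect_equal(coulomb_energy(two_atom_frame(332.0637), 1, 2, p), 1.0)
  p2 <- p; p2$charge_e <- c(1, -1)
  expect_equal(coulomb_energy(two_atom_frame(3.320637), 1, 2, p2), -100.0)
  p3 <- p; p3$charge_e <- c(0, 0)
  expect_equal(coulomb_energy(two_atom_frame(3), 1, 2, p3), 0)
  # interior dielectric divides
  expect_equal(coulomb_energy(two_atom_frame(332.0637), 1, 2, p, eps_in = 2), 0.5)
})

test_that("Generalized Born matches its dielectric and distance limits", {
  model <- toy_model(two_atom_frame(5))
  p <- uniform_params(model, charge = 1, born = 2)
  # identical dielectrics: zero for any geometry
  expect_equal(gb_energy(two_atom_frame(5), 1:2, p, eps_in = 80, eps_solv = 80), 0)
  expect_equal(gb_polar(two_atom_frame(5), 1, 2, p, eps_in = 80, eps_solv = 80), 0)
  # Born self-energy of a single ion: -k_e (1 - 1/80) q^2 / (2a)
  self <- gb_energy(two_atom_frame(5), 1, p)
  expect_equal(self, -332.0637 * (1 - 1 / 80) / (2 * 2), tolerance = 1e-12)
  # two distant ions: screened Coulomb within 1% at r = 100 sqrt(a_i a_j)
  r <- 100 * 2
  cross <- gb_polar(two_atom_frame(r), 1, 2, p)
  screened <- -332.0637 * (1 - 1 / 80) / r
  expect_equal(cross / screened, 1, tolerance = 0.01)
  # binding term equals complex minus parts
  full <- gb_energy(two_atom_frame(5), 1:2, p)
  a_only <- gb_energy(two_atom_frame(5), 1, p)
  b_only <- gb_energy(two_atom_frame(5), 2, p)
  expect_equal(gb_polar(two_atom_frame(5), 1, 2, p), full - a_only - b_only,
               tolerance = 1e-10)
})

test_that("SASA matches sphere closed forms and a point-in-sphere oracle", {
  # isolated atom: full solvent sphere
  expect_equal(sasa(matrix(0, 1, 3), 1.6, probe = 1.4, n_points = 960),
               4 * pi * 3.0^2, tolerance = 0.005 * 4 * pi * 9)
  # coincident identical atoms occlude nothing (strict-interior tie rule)
  two <- matrix(0, 2, 3)
  s2 <- sasa(two, c(1.6, 1.6), probe = 1.4, n_points = 240)
  expect_equal(s2, rep(4 * pi * 9, 2), tolerance = 1e-9)
  # fully buried atom inside a tight cage
  cage <- rbind(c(0, 0, 0),
                2.0 * rbind(diag(3), -diag(3),
                            cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0) / sqrt(2),
                            cbind(0, c(1, 1), c(1, -1)) / sqrt(2)))
  s_cage <- sasa(cage, rep(1.6, nrow(cage)), probe = 1.4, n_points = 240)
  expect_equal(s_cage[1], 0)
  # oracle: recompute occlusion of the exact golden point set naively
  set.seed(51)
  xyz <- matrix(rnorm(12, sd = 2), 4, 3)
  radii <- runif(4, 1.2, 2.0)
  got <- sasa(xyz, radii, probe = 1.4, n_points = 120)
  pts <- allodyn:::golden_sphere_points(120)
  rs <- radii + 1.4
  oracle <- vapply(1:4, function(i) {
    p <- sweep(pts * rs[i], 2, xyz[i, ], "+")
    free <- vapply(seq_len(120), function(k) {
      for (j in seq_len(4)) {
        if (j != i && sum((p[k, ] - xyz[j, ])^2) < rs[j]^2) return(FALSE)
      }
      TRUE
    }, logical(1))
    4 * pi * rs[i]^2 * mean(free)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(sasa(matrix(0, 1, 3), 1.6, n_points = 6), "at least 12")
})

test_that("nonpolar solvation reproduces the printed linear form", {
  expect_equal(nonpolar_solvation(0), 0.92)
  expect_equal(nonpolar_solvation(100), 0.00542 * 100 + 0.92)
  expect_equal(nonpolar_solvation(100), 1.462)
  expect_equal(nonpolar_solvation(50, gamma = 0, b = 0), 0)
})

test_that("binding decomposition keeps its summation identities", {
  toy <- build_toy_complex(8, include_ligand = FALSE, include_peptide = TRUE)
  corr <- plant_correlation(nrow(residue_table(toy$model)))
  s <- sample_ensemble(toy$model, corr, n_frames = 6, seed = 17,
                       rigid_jitter = c(0, 0), per_residue_sigma = 0.2)
  ens <- s$ensemble
  dec <- binding_decomposition(ens, "chain A", "chain B", toy$params,
                               sasa_points = 120)
  pf <- dec$per_frame
  # per-frame identity: binding = vdw + ele + int + polar + nonpolar
  expect_equal(pf[, "binding"],
               pf[, "vdw"] + pf[, "ele"] + pf[, "int"] + pf[, "polar"] +
                 pf[, "nonpolar"], tolerance = 1e-10)
  expect_equal(pf[, "solv"], pf[, "polar"] + pf[, "nonpolar"], tolerance = 1e-12)
  expect_true(all(pf[, "int"] == 0))
  # per-residue rows sum to totals for every term
  for (tm in c("vdw", "ele", "polar", "nonpolar", "binding")) {
    expect_equal(sum(dec$per_residue[[paste0(tm, "_mean")]]),
                 dec$totals$mean[dec$totals$term == tm], tolerance = 1e-6)
  }
  # swapping receptor and partner leaves the binding energy unchanged
  dec2 <- binding_decomposition(ens, "chain B", "chain A", toy$params,
                                sasa_points = 120)
  expect_equal(dec2$totals$mean[dec2$totals$term == "binding"],
               dec$totals$mean[dec$totals$term == "binding"], tolerance = 1e-9)
  expect_error(binding_decomposition(ens, "chain A", "chain A", toy$params),
               "overlap")
})

test_that("a single charged contact residue dominates the electrostatics", {
  # toy with one strongly charged receptor side chain near the peptide
  toy <- build_toy_complex(10, include_ligand = FALSE, include_peptide = TRUE,
                           first_resid = 580L,
                           special_residues = list(`584` = c("ASP", "OD1")))
  p <- toy$params
  m <- toy$model
  od1 <- resolve_atom_ref(m, "A:584:OD1")
  p$charge_e[m$atoms$chain == "A"] <- 0.001
  p$charge_e[od1] <- -1.0
  ens <- ensemble_from_frames(list(structure_coords(m)), m)
  dec <- binding_decomposition(ens, "chain A", "chain B", p, sasa_points = 60)
  ele <- dec$per_residue$ele_mean[grepl("^A:", dec$per_residue$key)]
  keys <- dec$per_residue$key[grepl("^A:", dec$per_residue$key)]
  share <- abs(ele[keys == "A:584"]) / sum(abs(ele))
  expect_gt(share, 0.9)
})

test_that("cross-term energies are rigid-transform invariant", {
  set.seed(52)
  toy <- build_toy_complex(6, include_ligand = TRUE, include_peptide = FALSE)
  m <- toy$model; p <- toy$params
  xyz <- structure_coords(m)
  idxA <- resolve_selection(m, "chain A")
  idxB <- resolve_selection(m, "chain L")
  tr <- random_rigid_transform()
  xyz2 <- apply_rigid(xyz, tr)
  expect_equal(lj_energy(xyz2, idxA, idxB, p), lj_energy(xyz, idxA, idxB, p),
               tolerance = 1e-9)
  expect_equal(coulomb_energy(xyz2, idxA, idxB, p),
               coulomb_energy(xyz, idxA, idxB, p), tolerance = 1e-9)
  expect_equal(gb_polar(xyz2, idxA, idxB, p), gb_polar(xyz, idxA, idxB, p),
               tolerance = 1e-9)
})
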