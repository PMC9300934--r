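# allodyn

Allosteric-communication analysis for protein conformational ensembles, built
around the question of how a nuclear receptor's ligand-binding pocket talks to
its cofactor-binding (AF-2) groove. Given a reference structure and an
ensemble (multi-model PDB, optionally DCD), the package computes the full
chain of analyses a structural-dynamics study of this kind rests on — and
ships a synthetic-ensemble generator with *planted* correlation structure so
every stage can be validated against a known answer without running any
molecular dynamics.

## What it computes

* **Superposition & fluctuations** — Kabsch least-squares fitting (proper
  rotations only), per-frame RMSD, per-residue RMSF.
* **Representative structures** — k-means (k-means++ seeding, Lloyd
  iterations, deterministic for a fixed seed) on fitted coordinates, with the
  member frame nearest each centroid as the cluster representative.
* **DCCM** — scalar cross-correlation of position fluctuations,
  C_ij = c_ij / (c_ii c_jj)^1/2 with c_ij = ⟨r_i·r_j⟩ − ⟨r_i⟩·⟨r_j⟩,
  entries in [−1, 1]; replica averaging and difference maps.
* **Residue interaction network** — nodes in contact when within 4.5 Å
  (minimum heavy-atom distance) in ≥ 75% of frames; edge weights
  d_ij = −log|C_ij|; Girvan–Newman communities cut at maximal modularity;
  inter-community connectivity; optimal paths by Floyd–Warshall and all
  suboptimal simple paths within a stated tolerance.
* **Pocket geometry** — atom-pair distance series and densities,
  hydrogen-bond occupancy at the 3.5 Å criterion, triangle-area collective
  variables over three pocket residues, and 2D free-energy landscapes
  F = −kT ln(P/Pmax) at 300 K.
* **Interaction energetics** — single-trajectory per-residue decomposition
  ΔG_binding = ΔE_vdw + ΔE_ele + ΔE_polar(GB) + ΔE_nonpolar, with a pairwise
  Generalized Born polar term, Shrake–Rupley SASA and the linear nonpolar
  model γ·SASA + b (γ = 0.00542 kcal·mol⁻¹·Å⁻², b = 0.92 kcal/mol).
* **Pipeline** — one configuration drives all stages with fail-fast
  validation, deterministic TSV outputs, a provenance manifest and cached
  resume (`run_pipeline()`).

The methods vignette (`vignettes/allosteric-pipeline.Rmd`) documents the
models, defaults, numerical choices and limitations in detail.

## Worked example

Plant a high-correlation chain between two correlated blocks, sample an
ensemble, and recover the chain as the optimal allosteric path:

```r
library(allodyn)

toy  <- build_toy_complex(20)                      # receptor + ligand + LXXLL peptide
corr <- plant_correlation(
  nrow(residue_table(toy$model)),
  blocks = list(list(members = 1:8,   rho = 0.75),
                list(members = 13:20, rho = 0.75)),
  chain  = list(members = c(4, 6, 8, 10, 12, 14, 16), rho = 0.9))

samp <- sample_ensemble(toy$model, corr, n_frames = 2000, seed = 1)
ens  <- superpose(samp$ensemble, fit_sel = "chain A and name CA")

M   <- dccm(ens, "chain A and name CA")
net <- weight_edges(contact_occupancy(ens, "chain A"), M)
optimal_path(net, "A:583", "A:595")
```

```
path_result: length 3.9248 (x100: 392), 7 residues:
  A:583 -> A:585 -> A:587 -> A:589 -> A:591 -> A:593 -> A:595
```

Every residue on the recovered path is a member of the planted chain
(residues 583, 585, …, 595): shortest paths over d = −log|C| weights trace
the planted correlated chain, not the many spatially available detours.
Hydrogen-bond occupancy of the designated cofactor contact behaves the same
way — `hbond_occupancy(distance_series(ens, "A:590:OD1", "R+2:NE",
motif_mapping(ens$topology, "B")))` gives a fractional occupancy (≈ 0.23)
because the toy docks the motif arginine at the edge of the 3.5 Å criterion.

The numbered drivers under `analysis/` run the full study on the synthetic
systems (simulation → structure dynamics → pocket geometry → correlation
network → energetics → full pipeline) and write their tables under
`results/`.

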