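---
title: "Linking pocket dynamics through correlation networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking pocket dynamics through correlation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Nuclear receptors such as the glucocorticoid receptor (GR) couple two
distant functional sites: the buried agonist pocket and the surface groove
(AF-2) where LXXLL-motif coactivator peptides such as TIF2 dock. Different
agonists produce different transcriptional efficacies, and one mechanistic
hypothesis is that the coupling — the allosteric communication — between the
two pockets differs between agonist-bound states. `allodyn` implements the
trajectory-analysis machinery used to interrogate that hypothesis on
conformational ensembles: superposition and fluctuation profiles,
representative structures, pocket collective variables and free-energy
landscapes, hydrogen-bond occupancies, dynamic cross-correlation matrices
(DCCM), occupancy-gated residue interaction networks with correlation-derived
edge weights, community partitions, optimal and suboptimal paths, and
per-residue interaction-energy decomposition.

The package does not run molecular dynamics. Its inputs are a reference
structure and an ensemble (multi-model PDB, optionally DCD with a topology
PDB); its ground-truth instrument is a synthetic-ensemble generator with a
*planted* residue-level correlation matrix, so that every downstream stage
can be validated against a known answer.

## The synthetic generator and what it emulates

`build_toy_complex()` lays a receptor C-alpha trace on an ideal helix-like
curve (radius 1.6 Å, 120° twist and 1.2 Å rise per residue) with one
side-chain pseudo-atom per residue (radius 2.4 Å). The geometry is chosen so
that residues 2 and 3 apart in sequence are within the 4.5 Å heavy-atom
contact gate while residues 4+ apart are not; with the default exclusion of
sequence neighbours this yields a connected, locally dense, chain-like
contact graph — the topology regime residue-interaction networks live in.
Author numbering starts at 580 so residue D590 (with an OD1 side-chain atom)
exists in the default complex; an optional 5-atom ligand occupies a
mid-helix pocket, and an optional 5-residue LXXLL-style peptide docks
against the helix face carrying D590, its arginine-like residue (`R+2`,
side-chain atom NE) level with D590 so that the OD1–NE distance fluctuates
around the 3.5 Å hydrogen-bond criterion and its occupancy is fractional
rather than saturated. Per-atom charges, Lennard-Jones parameters and Born
radii are emitted alongside.

`plant_correlation()` assembles the target residue correlation matrix from
correlated blocks (the planted "communities"), an ordered chain whose
adjacent members are linked at a chosen correlation (the planted
"allosteric path"), and a background value. If the assembled matrix is
indefinite it is repaired by clipping negative eigenvalues at zero and
rescaling the diagonal to one; the repair is flagged and the largest entry
shift reported, and the *repaired* matrix is what the truth manifest
records, because it is what the ensemble is actually sampled from.

`sample_ensemble()` draws residue displacement vectors from a zero-mean
multivariate normal with that correlation, applied identically and
independently on x, y and z and scaled by a per-residue standard deviation
(default 0.5 Å per axis, giving RMSF values in the 0.5–0.9 Å range typical
of a stable folded domain). Sharing one scalar correlation across the three
axes makes the dot-product DCCM recover the planted value exactly in
expectation, which is what turns the generator into an analytic oracle. All
atoms of a residue move together (rigid residues). Each frame then receives
a rigid-body jitter (default up to 0.5 Å translation and 5° rotation) that
superposition must remove. One explicitly seeded RNG stream drives the whole
draw and the seed is recorded in the truth manifest.

What the generator does *not* emulate: bonded geometry and excluded volume
(residues can approach closer than physical contact under large
fluctuations), anisotropic and time-correlated dynamics, solvent, and any
real relationship between correlation and spatial proximity beyond what is
planted. Tests passing on these ensembles therefore validate the *machinery*
— estimators, graph algorithms, bookkeeping — not the biological conclusions
one would draw from real trajectories.

## Superposition, RMSD/RMSF, and a caveat that shaped the tests

Frames are superposed by the Kabsch algorithm (SVD with a determinant
correction, so the rotation is always proper and chirality is preserved),
mass-unweighted over the fit selection, with all other atoms carried along.

Least-squares fitting absorbs whatever part of the displacement field looks
like a rigid-body motion. For a single correlated residue pair among R
residues this perturbs the apparent correlation by O(1/R); for correlated
blocks that span a large fraction of the structure the planted coherent
motion *is* (nearly) a rigid motion and is substantially absorbed, deflating
intra-block correlations and manufacturing cross-block anticorrelation. This
is a property of the method, not of the implementation, and it dictated two
fixture choices:

* the planted-correlation recovery checks use a 60-residue receptor with
  planted pairs, where the fit perturbation (~0.02) is well inside the 0.05
  recovery tolerance at 5000 frames;
* the two-block community-recovery fixture is emitted pre-aligned (no rigid
  jitter, no refit), because its two 10-residue blocks jointly span the whole
  receptor; fitting would redefine the planted correlations rather than
  merely add noise. The jitter-removal property itself is tested separately
  (jitter on vs off changes the post-fit DCCM by < 0.02).

RMSD is reported per frame over the fit selection against the reference;
RMSF per atom about its time-mean position after superposition, undefined
for fewer than two frames.

## DCCM

The covariance is the scalar (dot-product) covariance of position vectors,
population-normalised over frames; the DCCM divides by the geometric mean of
the diagonal. Entries are clamped to [−1, 1] only against floating error
(overflow beyond 1e−12 is an error, not silently clamped). Zero-variance
atoms yield masked (NA) rows with a warning, and masked entries propagate as
missing — never as zero correlation — into the network stage, where they
drop the edge. With several replicas the default is the elementwise average
of per-replica DCCMs (`dccm_average()`); pooled concatenation is available
by concatenating ensembles before calling `dccm()`.

## The residue interaction network

Nodes are residues; a pair is adjacent when its minimum heavy-atom distance
(C-alpha mode by flag) is within 4.5 Å in at least 75% of frames, and
same-chain sequence neighbours (|i−j| ≤ 1 by default) are excluded. Edge
weights are d = −log|C| — natural log by default, base 10 by flag, since the
source convention writes the transform without a base; path lengths are
reported both raw and in a ×100-rounded integer convention, because
published path-length tables are consistent with scaled integers and we
prefer emitting both to guessing silently.

Communities use Girvan–Newman with one deliberate refinement: edge
betweenness is computed with d = −log|C| as the distance, then divided by
the edge's correlation weight |C| before choosing the edge to remove
(Newman's prescription for weighted graphs). Without the division, strongly
correlated (short) edges attract most shortest paths, accumulate the highest
betweenness, and are removed *first* — on chain-like contact graphs this
reliably cuts through the middle of a correlated block before severing its
weak boundary. The hierarchy is cut at maximal modularity, evaluated on the
original graph with |C| as similarity weights; ties are broken by the
deterministic lexicographic edge order, so partitions are bit-stable.
Inter-community connectivity counts, over all-pairs shortest paths, how
often each community boundary is crossed — the quantity community diagrams
draw as line width.

Optimal paths come from Floyd–Warshall with next-hop reconstruction
(all-pairs, cross-checked against Dijkstra in the tests); disconnected
endpoints produce a no-path result rather than an error. Suboptimal paths
enumerate all simple paths within a tolerance δ of the optimum (default 0.2
in raw units, i.e. 20 in the ×100 convention) by depth-first search pruned
with the Floyd–Warshall distance-to-target bound, sorted by length then
lexicographic node order.

## Pocket geometry and landscapes

Triangle collective variables use the C-alpha atoms of three named residues
by default (the vertex atom is configurable): the area responds sensitively
to pocket opening and is rigid-transform invariant. Distances resolve
through absolute references (`"A:590:OD1"`) or motif labels (`"R+2:NE"`)
anchored at the first leucine of the LXXLL motif; the ligand atom paired
against a pocket threonine is configuration, never code, because the
appropriate conserved carbon differs per ligand. Hydrogen-bond occupancy is
the fraction of frames with distance ≤ 3.5 Å, inclusive, so boundary frames
count as bonded. Densities default to Freedman–Diaconis histograms with an
optional Gaussian KDE (Silverman bandwidth); an all-identical series falls
back to a delta-like bin with a warning.

The 2D free-energy landscape bins the joint CV samples (50×50 by default
over the observed range padded 5% per side), converts to probabilities, and
reports −kT ln(P/Pmax) at 300 K (k_B = 0.0019872 kcal/mol/K), so the global
minimum is exactly zero. Empty bins are masked NA — never −kT ln 0. The
uniform-limit test aligns bins to the exact sample range (zero padding),
since padded edge bins carry partial mass by construction.

## Interaction energetics

The decomposition follows the end-point convention: ΔG_binding = ΔE_MM +
ΔG_solv with the entropy term omitted; ΔE_MM = ΔE_vdw + ΔE_ele + ΔE_int;
ΔG_solv = ΔE_polar + ΔE_nonpolar with ΔE_nonpolar = γ·SASA + b per species
(γ = 0.00542 kcal·mol⁻¹·Å⁻², b = 0.92 kcal/mol) combined as complex − A − B.
The polar term is a pairwise Generalized Born model with fixed, user-supplied
Born radii — f_GB = sqrt(r² + a_i a_j exp(−r²/(4 a_i a_j))) with self-terms
included — chosen because it is deterministic, desk-scale, has exact
analytic limits (zero at equal dielectrics; screened Coulomb at large
separation; the Born self-energy at r = 0), and preserves the published
decomposition structure; outputs label it as the polar (GB) term. In
single-trajectory mode (complex, receptor and partner from the same frames)
intramolecular bonded terms cancel, so ΔE_int ≡ 0; the field is kept so the
published table layout is reproducible. Energies use k_e = 332.0637
kcal·Å·mol⁻¹·e⁻², Lorentz–Berthelot combination for LJ, no cutoff by default.

SASA is Shrake–Rupley on a deterministic golden-spiral point set (default
960 points standalone, 240 inside the per-frame decomposition); occlusion is
strict-interior with a 1e−9 relative tolerance, so a test point exactly on a
neighbour's sphere — including the coincident-centre degenerate case — stays
accessible.

Per-residue attribution: each cross-pair term is split half to each
partner residue; the per-residue nonpolar share is γ times the residue's
buried area with the constant −b distributed proportionally to buried area
(equal split if the total buried area vanishes). This makes per-residue rows
sum to the totals exactly, at the cost of per-residue values being half the
"full interaction of this residue with the whole partner" convention some
tables use; the bookkeeping identity seemed the more valuable property to
guarantee. Standard deviations are over (strided) frames, matching the
parenthesised values of published per-residue tables.

## Clustering

Frames are clustered by k-means on the flattened Cartesian coordinates of
the selection after superposition (the cpptraj convention), with k-means++
seeding from an explicit seed, Lloyd iterations to a 1e−6 Å centroid-shift
tolerance, and empty clusters re-seeded from the point farthest from its
centroid. k-means++ and the empty-cluster rule are part of the stated
contract (deterministic for a fixed seed), which is why the loop is
implemented here rather than delegated to `stats::kmeans`, whose
initialisation cannot express it. k is user-chosen (default 5) with an
elbow report; the representative structure of a cluster is the member frame
nearest its centroid, cross-checked against an exhaustive scan in the tests.

## Pipeline and provenance

`run_pipeline()` drives every stage from one configuration
(`default_config()`, or YAML via `read_run_config()`), validates every
selection, atom reference and numeric range up front with an aggregated
error list, writes deterministic TSV outputs plus a JSON manifest (config
hash, seed, per-stage output registry), and resumes finished stages from an
on-disk cache unless forced. Identical configuration and seed reproduce
byte-identical TSVs; the test suite asserts this literally.

## Problem sizes and defaults used in the shipped analyses

The shipped analyses and checks use: 20-residue toy complexes (26 residues
including ligand and peptide) at 500–2000 frames for the end-to-end
pipeline, network and energetics stages; a 60-residue receptor at 5000
frames for correlation-recovery checks (recovery tolerance ±0.05); 3000
frames for the two-block community fixture; 10⁵ samples for the two-basin
landscape check, whose free-energy gap must match −kT ln(1/9) = 1.31
kcal/mol at 300 K within 0.1; energetics with frame stride 25 and 240 SASA
points. These sizes give sampling errors comfortably inside each stated
tolerance while keeping every analysis a desk-scale computation.

## Known limitations

* Correlations deflate by O(1/R) per pair under least-squares fitting, and
  collective motions spanning much of the structure are partially absorbed;
  interpret DCCM magnitudes accordingly (this affects real MD analysis the
  same way).
* The GB polar term uses fixed input Born radii; no self-consistent
  (perturbed-radii) GB, and no Poisson–Boltzmann solver.
* Hydrogen bonds are distance-gated only; no angular criterion.
* The generator's ensembles are temporally uncorrelated; autocorrelation-
  aware error estimates are out of scope.
* Modularity-based community detection inherits the usual resolution limits;
  on quasi-one-dimensional contact graphs, partitions of elongated blocks
  can be degenerate in modularity even when the planted boundary is clear.
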