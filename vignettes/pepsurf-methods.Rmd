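---
title: "Methods: peptide-gold contact analysis, binding scores, RMSD clustering and WHAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide-gold contact analysis, binding scores, RMSD clustering and WHAM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepsurf)
```

## Scope and model

pepsurf analyses molecular-dynamics trajectories of a peptide adsorbed above
a gold Au(111) slab, with the surface normal along z. It answers four
questions downstream of the simulation itself (which it does not run):

1. How often does each residue touch the surface? (contact fractions)
2. How strongly does the sequence bind, residue by residue and over ranges?
   (binding scores)
3. What does the adsorbed conformational ensemble look like, and how similar
   is it across sequence variants? (Daura clustering, centroid matching)
4. What is the free-energy profile of an adsorbing group along z?
   (umbrella sampling + WHAM)

Internally all lengths are angstrom (nm-based formats are converted on
read), energies are kJ/mol, and residue indexing is 1-based so "position 9"
means the ninth residue of the sequence.

## Contact fractions

For every frame the topmost gold layer is located as the set of slab atoms
within `layer_tolerance` (default 0.8 Å) of the maximum slab z, and its mean
z defines the surface plane. The default tolerance sits between thermal
jitter of a layer and the ~2.35 Å Au(111) interlayer spacing, so a roughened
top layer is averaged without capturing the layer beneath.

Each residue type has a *reference site* (an atom name, or the centroid of a
named set) and a *cut-off*. The default distance is the vertical offset
z(site) − z(top layer); a `min3d` mode measures the minimum 3-D distance to
any top-layer atom under the x/y minimum-image convention, since either
convention is defensible for a slab and the literature does not always say
which was used. A residue is in contact when the distance is **less than or
equal to** the cut-off (the boundary is inclusive by definition of the
rule), and negative distances — a site dipping below the mean plane — count
as contact. The contact fraction f_i is the fraction of frames in contact,
so f_i ∈ [0, 1] and concatenating trajectories averages f_i with frame
weights.

The shipped reference table uses the sulfur atom at 4.5 Å for Met, Cys and
the protected/oxidised analogues (MOX, CTB, COX), following the
non-standard-residue rule, and terminal side-chain heavy-atom centroids at
4.5 Å for everything else. The non-sulfur entries are placeholders:
published per-residue sites and cut-offs exist and should be supplied via
`read_reference_table()` for quantitative reproduction of any specific
study.

## Binding scores

The binding score of residue i combines its contact fraction with the
adsorption free energy ΔG_i of the corresponding free amino acid at the
aqueous Au(111) interface:

  s_i = f_i · ΔG_i  (kJ/mol)

The combining operator is not uniquely dictated by the verbal definition
"the fraction of the trajectory in contact *and* the binding free energy";
the product is adopted because it yields 0 for a residue that never touches
the surface, the full ΔG at permanent contact, and carries the right units.
`residue_binding_scores(combine = ...)` accepts any other binary operator so
the convention can be swapped without touching callers.

Scores sum over inclusive residue ranges (`cumulative_binding_score`); the
default report splits a sequence into the N-terminal half (1–6) and the
C-terminal particle-binding half (7–12). The position-9 score is classified
into three helix-propensity regimes: strong-binding below −10 kJ/mol, the
single-helix range −10 to −1 kJ/mol (both endpoints inclusive — the source
phrasing "(−1 to −10)" does not specify, and inclusivity keeps the classes a
partition with no gaps), and weak/non-binding above −1 kJ/mol.

The shipped ΔG table is **synthetic**: its values only encode a plausible
ordering (sulfur-bearing and aromatic residues strong, small aliphatics
weak) and every entry is tagged `synthetic-default`. Published values must
be supplied through `read_free_energy_table()` for real use. Consequently
the packaged worked example — a position-9 threonine at 50% contact scoring
0.5 × (−9) = −4.5 kJ/mol, inside the single-helix range — demonstrates the
pathway and the classifier, not a reproduction of any study's supplementary
inputs.

## Conformational clustering

`backbone_rmsd` computes RMSD after removing centroids and applying the
optimal least-squares rotation (Kabsch via SVD, with the determinant
correction that forbids reflections). Superposition is on by default, the
behaviour of the common cluster tools; it can be disabled. The backbone is
N, CA, C by default — whether carbonyl O belongs to "all backbone atoms" is
a flagged choice, and the selection is configurable.

`daura_cluster` implements the greedy algorithm: repeatedly count, for every
unassigned conformation, its neighbours within the cut-off (inclusive);
promote the conformation with the most neighbours to centroid; remove it and
its neighbours as one cluster. Ties on neighbour count break to the lowest
frame index, so the algorithm is deterministic and permuting input frames
permutes the output clusters consistently. The centroid is the max-neighbour
member itself, never a coordinate average. Clusters are reported by
decreasing population (ties by centroid index) and always partition the
frames.

`cross_cluster_match` compares centroid structures among the top-k most
populated clusters of two ensembles: matched at RMSD ≤ 2.0 Å, near-matched
strictly between 2.0 and 2.5 Å, unmatched otherwise (thresholds
configurable, defaults as conventionally printed). With fewer than k
clusters available the comparison proceeds on what exists and the report
carries a warning.

## WHAM

Umbrella windows carry a harmonic bias w_j(ξ) = k/2 (ξ − z0_j)². WHAM
iterates, in log space,

  p(ξ_b) ∝ Σ_j n_jb / Σ_j N_j exp((F_j − w_j(ξ_b))/kT),
  F_j = −kT log Σ_b p(ξ_b) exp(−w_j(ξ_b)/kT),

until max_j |ΔF_j| falls below the tolerance, which is interpreted relative
to kT (the common tool convention; an absolute-kJ/mol mode is available).
kT uses k_B = 0.0083145 kJ mol⁻¹ K⁻¹ at a default 300 K. The PMF is
−kT log p gauge-fixed to minimum 0 over supported bins; empty bins are NA,
never 0. The default grid is 200 bins over the sampled range.

Two numerical choices matter in practice:

* The bias Boltzmann factor per bin is *averaged over the bin* by 5-point
  Gauss–Legendre quadrature rather than evaluated at the bin centre. With
  k = 3000 kJ mol⁻¹ nm⁻² the bias varies by order kT across a 0.005 nm bin
  away from the window centre, and centre-point evaluation leaves a visible
  systematic error.
* The converged solution is invariant to the initial window free energies
  (tested), so bootstrap replicates warm-start from the point estimate's
  F_j purely as a speed-up.

Errors use a trajectory-style bootstrap: each window's series is resampled
with replacement in contiguous blocks whose length equals the series'
integrated autocorrelation time (initial-positive-sequence estimator, lag
window capped at 1000, minimum block 1), WHAM is rerun, each replicate is
gauge-aligned to the point estimate by its mean offset over supported bins,
and the per-bin error is the standard deviation across replicates. The
reference tool's exact "traj" resampling scheme is undocumented; block
resampling reproduces its intent — respecting temporal correlation — and is
the documented stand-in. Reported error bars are one standard deviation; a
±2 sd band is the package's coverage convention in validation (a 1 sd band
covers ~68% by construction).

## Synthetic data: the stated world

The generators produce every input with known ground truth, so each stage
has a parameter-recovery test. What they emulate, and what they do not:

* `gen_contact_trajectory`: per residue, a two-state Markov chain with
  stationary contact probability p_i and persistence ρ (the lag-1
  autocorrelation of the contact indicator; default 0.5, representing the
  temporal correlation of real trajectories). Contact frames put the
  reference site at cut-off − 0.5 Å above the top layer, non-contact frames
  at cut-off + 3 Å; the slab is three square Au layers 2.35 Å apart. The
  geometry is schematic — only placement relative to the cut-off matters —
  so a green recovery test establishes correct counting and distance logic,
  not force-field realism. The effective sample size of a contact fraction
  over n frames is n(1−ρ)/(1+ρ); the recovery criterion checks each
  residue's estimate against 3 such standard errors in ≥ 99/100 seeded
  runs. The bound was verified by direct Monte-Carlo (empirical/analytic sd
  ratios 0.98–1.01); note that with multiple residues per seed a
  *joint* per-seed reading of the same bound would be expected to miss
  ~0.8 seeds per 100 by chance alone even for a perfect implementation,
  which is why the per-residue reading is the documented contract.
* `gen_cluster_ensemble`: planted templates drawn by weight plus isotropic
  Gaussian noise of stated per-atom RMS, optionally under random rigid
  motions (harmless when RMSD fits first). Separated templates
  (inter-template RMSD > 3× cut-off) with small noise are recovered exactly.
* `gen_umbrella_samples`: exact Boltzmann samples of the biased densities by
  inverse-CDF on a 10⁴-point grid, from flat, harmonic or double-well
  profiles. The double-well default a(ξ²−b²)² uses a = 700 kJ mol⁻¹ nm⁻⁴,
  b = 0.25 nm over ±0.4 nm: a ~2.7 kJ/mol barrier whose maximum gradient
  (~110 kJ/mol/nm) stays below the restraining scale of the k = 3000 bias
  (k·σ with σ = √(kT/k) ≈ 0.029 nm). This mirrors real protocol design —
  an umbrella window whose bias cannot hold the steepest PMF slope drifts
  off its centre and leaves unsampled gaps; with such parameters no WHAM
  implementation could meet a tight recovery bound, which is a property of
  the protocol, not the estimator.

All generators are pure functions of (spec, seed) and restore the caller's
RNG state.

## A worked run

```{r example, eval = FALSE}
dir <- tempfile("pepsurf-run-")
cfg <- pipeline_config(
  output_dir = dir,
  simulate = list(p = round(seq(0.95, 0.05, length.out = 12), 2),
                  n_frames = 2000, rho = 0.5,
                  umbrella = list(form = "double_well",
                                  centers = seq(-0.4, 0.4, by = 0.05),
                                  n_per_window = 10000)),
  cluster = list(selection = c("SG", "SD", "CB")),
  wham = list(bins = 200, n_boot = 50),
  seed = 1)
res <- run_pipeline(cfg)
res$scores$position9_score   # -5.152 kJ/mol with this seed
res$scores$position9_class   # "single-helix-range"
```

## Known limitations

* No binary trajectory readers (XTC/DCD): convert externally or register an
  adapter with `register_trajectory_reader()`.
* The shipped reference-site and ΔG tables are placeholders, as stressed
  above; every quantitative claim about a real system requires the
  published tables.
* The pairwise RMSD matrix is O(n²) in frames; clustering tens of thousands
  of frames is possible but slow in pure R — subsample or precompute the
  matrix once and reuse it.
* WHAM here is 1-D with harmonic biases only; no MBAR alternative.
* The score → morphology link (single- vs double-helix superstructures) is
  an empirical classification rule, not a physical model; the package stops
  at the score and class.
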