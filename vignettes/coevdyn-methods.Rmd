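---
title: "Methods: coevolution, trajectory dynamics and biosensor curves in coevdyn"
author: "coevdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coevolution, trajectory dynamics and biosensor curves in coevdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevdyn)
```

# Scope and model

`coevdyn` implements a three-stage computational route used to study
allosteric regulation in small-molecule-binding regulatory domains such
as the cGMP-binding GAF domains of phosphodiesterases:

1. **Sequence stage.** A family alignment is filtered (redundancy, gap
   columns), statistical coupling analysis (SCA) scores how strongly the
   amino-acid distribution at each position covaries with every other
   position, and hierarchical clustering of the coupling matrix extracts
   the top coevolving cluster, which is then mapped onto a structure and
   classified against the ligand binding site at a 5 Å cutoff.
2. **Dynamics stage.** Coordinate trajectories (multi-model PDB) are
   reduced to the standard structural-dynamics statistics — RMSD, RMSF,
   radius of gyration, inter-group distances, ligand SASA, hydrogen-bond
   counts, dynamic cross-correlation (DCC) — and to a 2D kernel-density
   conformational landscape over two element-distance coordinates.
3. **Biosensor stage.** Plate-reader curve models: BRET ratios,
   two-Gaussian bioluminescence spectra, a variable-slope four-parameter
   logistic dose-response (EC50), and a Boltzmann sigmoidal thermal melt
   (Tm, slope).

Because family alignments, microsecond trajectories and wet-lab plates
are not reproducible at the desk, each stage has a seeded synthetic
generator that plants known ground truth; the test suite and the
acceptance script measure how well the analysis recovers what was
planted.

# Statistical coupling analysis

## Frequencies and weights

Sequences are weighted by redundancy: the weight of sequence $s$ is
$1/|\{s' : \mathrm{id}(s, s') \ge 0.8\}|$ (the 0.8 identity cutoff is
standard SCA practice and exposed as a parameter), and
$M_\mathrm{eff} = \sum_s w_s$. Pairwise identity is the fraction of
matching non-gap columns over columns where at least one sequence is
non-gap.

Weighted frequencies are regularized with a pseudocount
$\lambda = 0.03$ toward a background $q$ (uniform $1/20$ by default;
database frequencies may be supplied):

$$f_i^a = (1-\lambda)\,\hat f_i^a + \lambda q^a, \qquad
  f_{ij}^{ab} = (1-\lambda)\,\hat f_{ij}^{ab} + \lambda q^a q^b .$$

Gaps carry no residue mass: frequencies are over the 20 amino acids
only, with no 21st gap state. Non-standard residue codes (B, Z, X, U,
O, J, '.') are mapped to gap on input with a warning.

## Coupling scores

The positional weight is the derivative of the positional relative
entropy,
$\phi_i^a = \ln\!\big[f_i^a (1-q^a) / ((1-f_i^a)\, q^a)\big]$, clipped
to $\pm 50$ so that nearly conserved positions under a tiny pseudocount
cannot overflow. The weighted covariance tensor
$\tilde C_{ij}^{ab} = \phi_i^a \phi_j^b\,(f_{ij}^{ab} - f_i^a f_j^b)$
is reduced to one score per position pair by the Frobenius norm over
the residue indices, the diagonal is set to zero, and symmetry is
enforced exactly. The published SCA literature spans several variants;
this positional-weight/Frobenius-norm form is the most common published
formulation and is the package's fixed choice — it is the one modelling
decision here that a different SCA lineage would make differently, so
it is stated prominently. Both raw scores and max-normalized scores are
available (`fraction_above(..., normalized = )`).

## Clustering and the cut

Average-linkage hierarchical clustering runs on the distance
$d_{ij} = 1 - \tilde C_{ij} / \max \tilde C$. The cut is configurable
(`n_clusters`, `height`); the default cuts at the midpoint of the
largest gap in the sorted merge heights. The usual alternative — fixing
a cluster count — fails in exactly the regime this analysis cares
about: strongly coevolving positions also couple (weakly) to the
background more than background positions couple to each other, so at
small fixed $k$ the agglomeration buries the coevolving block inside
the main cluster and peels off background outliers instead. The merge
heights, in contrast, separate cleanly (planted clusters merge at
heights near 0, the background near 1), so the largest-gap cut isolates
the tight core without a tuned parameter. The *top cluster* is then the
cluster (of size ≥ `min_size`) with the highest mean intra-cluster
coupling.

Reported positions can be translated to a reference numbering via
`map_to_reference()`. Reference numbering is assigned on the alignment
*before* gap-column filtering and restricted afterwards
(`subset_position_map()`), so dropping a gappy column that happens to
contain reference residues never renumbers the surviving columns.

# Structure mapping

PDB files are parsed with `bio3d`; alternate locations are resolved by
highest occupancy (ties toward altloc A), elements come from columns
77–78 with atom-name heuristics as fallback, and the first model of an
NMR ensemble is used for static analyses by default. Binding-site
classification follows the 5 Å convention: a protein residue belongs to
the site when any of its heavy atoms lies within 5 Å (inclusive) of any
ligand heavy atom; hydrogens never count. Group distances support
mass-weighted whole-residue centers of mass (standard atomic masses),
Cα–Cα, and minimum heavy-atom distance; whole-residue COM is the
default because the side-chain-only alternative is equally defensible —
it is exposed via the selection rule instead of being hard-coded.
Numbering offsets between reference and structure numbering (e.g. a
+10 shift between a template construct and the human sequence) are
explicit arguments, and unmapped positions are reported rather than
dropped.

Because a deposited holo GAF-domain structure cannot be bundled, the
package ships `inst/extdata/gafa_synthetic.pdb`, a *synthetic*
GAF-like domain (149 CA/CB pseudo-residues numbered 154–302 plus a
5-atom `PCG` ligand) constructed so the documented binding-site
geometry holds: the residues at template numbers 220/256/273/275
(human numbering 230/266/283/285 under the +10 offset) carry heavy
atoms within 5 Å of the ligand, two further residues sit in the 5–6 Å
shell, and the distant coevolving pair 257/285 (human 267/295) is
placed 5.3 Å apart. It exercises the mapping and proximity machinery;
it asserts nothing about any real structure.

# Trajectory statistics

All superposition-based metrics use the Kabsch least-squares rigid fit
with the proper-rotation (det = +1) branch, so mirror images are never
matched by reflection. Defaults follow common practice and are
configurable, since trajectory-analysis tools differ in their
selections: superposition/RMSD/RMSF/DCC default to Cα atoms; the RMSF
and DCC reference is the iteratively refined mean structure (two
refinement passes). RMSD on fewer than three fit atoms falls back to a
translation-only fit. Rg is mass-weighted over heavy atoms; group
distances are frame-internal (no superposition), as are SASA and
H-bond counts — all four are invariant under per-frame rigid
transforms, which the tests verify to 1e-9.

Ligand SASA is Shrake–Rupley: 960 golden-spiral test points per atom on
the probe-expanded sphere (probe 1.4 Å; radii C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80), points strictly inside another expanded sphere are
buried (boundary points count as exposed), and the ligand total is
summed over its heavy atoms in the context of all protein + ligand
heavy atoms. H-bonds between ligand and protein use N/O pairs at ≤
3.5 Å with a D–H⋯A angle ≥ 150° when hydrogens are present in the
topology; without hydrogens the criterion is distance-only and a
notice is emitted. Both cutoffs are parameters because MD packages
ship different defaults.

DCC is the normalized covariance of positional fluctuations after
superposition,
$\mathrm{DCC}_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
\sqrt{\langle\|\Delta r_i\|^2\rangle\langle\|\Delta r_j\|^2\rangle}$,
with zero-variance atoms zeroed out under a warning rather than
dividing by zero.

## The conformational landscape

Two element-distance coordinates summarize the binding-site "lid"
closure and the terminal-helix juxtaposition: per frame, x = Cα-centroid
distance between sheet β3 and helix α4, y = Cα-centroid distance
between helices α2 and α5. Element residue ranges are **required
inputs** (`element_def()` / `read_element_def()`): the domain's
secondary-structure topology (ααβββαβαββα) fixes the element order but
not the exact ranges, so silently hard-coding ranges would be wrong.
Distances pooled over replicates feed a 2D Gaussian-kernel density with
Scott's-rule bandwidth per axis ($\hat\sigma\,n^{-1/6}$), evaluated on
a regular grid (0.1 Å default step) and normalized over the grid (the
tests check integration to 1 within 1%). Modes are strict grid local
maxima above 10% of the global maximum, sorted by density; an
all-identical-frames input degenerates to a single delta-like mode
under a warning. Mode positions are quantized by the grid, so recovery
tolerances are one bandwidth plus one grid step.

# Curve models

* **BRET ratio** = acceptor / donor emission; percentage change
  relative to basal is $100\,(B - B_0)/B_0$ (the plotting convention
  "percentage increase in BRET" spelled out as a formula).
* **Spectra**: $\sum_k A_k e^{-(\lambda-\mu_k)^2/2\sigma_k^2}$ with 1
  or 2 components, bounded nonlinear least squares (amplitudes ≥ 0,
  centers inside the measured window), components sorted by center.
* **Dose–response**: variable-slope 4PL on the log axis,
  $y = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})\big/\big(1 +
  10^{(\log EC_{50} - \log c)\,h}\big)$, fitted with 5 deterministic
  multi-starts (logEC50 seeded at the half-max crossing and response
  quartiles). Variable slope with unconstrained plateaus is the
  default since fixed-slope fits are a special case. Zero
  concentrations are excluded from the fit. When the response does not
  plateau within the measured range (fitted EC50 beyond the top dose,
  or the curve reaching < 95% of its span at the top dose) the fit is
  flagged *EC50 under-determined* and should be read as a lower bound.
* **Melt**: Boltzmann sigmoid
  $y = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/\big(1 +
  e^{(T_m - T)/\mathrm{slope}}\big)$; a decreasing melt has a negative
  slope, matching the sign convention used when such slopes are
  reported. $T_m$ is the half-maximal temperature, and the fitted
  curve satisfies $y(T_m) = (\mathrm{bottom}+\mathrm{top})/2$ exactly;
  the exponent is clamped at ±50 so near-step data keep finite
  gradients. The default temperature grid in the melt generator is the
  15-point 30–80 °C assay schedule.

# Synthetic generators: what they emulate, and what they do not

`make_coupled_msa()` plants covariation: each sequence draws a hidden
class, planted positions emit their class residue with fidelity $p$
(else one of the other 19), background positions are i.i.d. The
defaults used in the acceptance runs — 1000 sequences × 100 columns,
5 planted positions at $p = 0.9$, and 800 × 120 with 9 planted
positions at $p = 0.85$ for the domain-scale run — give a realistic
post-filter family size and a cluster size matching the
nine-coevolving-position scale. The generator has no phylogeny: real
alignments correlate sequences through shared ancestry, which SCA's
sequence weights only approximate. Passing recovery tests therefore
shows the estimator recovers *planted exchangeable* covariation, not
that it defeats phylogenetic confounding.

`make_gaussian_trajectory()` draws per-axis Gaussian fluctuations with
a planted per-residue σ and cross-correlation ρ around a helical mean
path (2.3 Å radius, 100°/residue, 1.5 Å rise, ≈3.8 Å Cα spacing). The
helical rather than straight-line mean is deliberate: a collinear mean
makes the Kabsch rotation ill-conditioned, and the rotation fit then
absorbs correlated noise (a planted ρ = 0.5 reads back ≈0.45 on a line
versus ≈0.49 on a helix). Even so, superposition necessarily removes
six rigid degrees of freedom, deflating RMSF by roughly
$\sqrt{1 - 6/(3N)}$ and planted correlations by O(1/N); recovery
conditions therefore use N = 100 residues and 20000 frames, where both
biases sit inside the 2% / ±0.05 tolerances. Real MD has anharmonic,
time-correlated dynamics; these trajectories are i.i.d. in time, so
they validate the estimators, not any sampling-convergence claim.

`make_landscape_trajectory()` moves rigid four-residue elements so the
(β3–α4, α2–α5) distance pair follows a specified Gaussian mixture —
the ground truth for mode recovery (e.g. a single mode at (11, 13) Å,
or a 50/50 two-component mixture for bimodal landscapes).

The curve generators add i.i.d. Gaussian noise to exact model values;
all generators take one seed, use a local RNG, and restore the global
RNG state.

# Numerical choices and degenerate inputs

* Redundancy filtering is greedy in input order with a strict `>`
  threshold; gap-column filtering uses a strict `>` rule on unweighted
  gap fractions; filters run redundancy-first. Both are idempotent.
* All-gap pairwise identity is 0 by convention; an all-gap reference
  yields an empty position map with a warning; an alignment whose
  columns are all gappy raises an explicit "empty after filtering"
  error.
* λ = 0 is allowed for frequencies but positions conserved at λ = 0
  trigger a warning, and `coupling_matrix()` refuses frequencies at
  exactly 0/1 with a pointer to λ > 0.
* A constant coupling matrix ("no coupling signal") and single-frame
  RMSF both raise explicit errors; a zero-variance atom in DCC zeroes
  its row/column with a warning.
* Superposition requires ≥ 3 non-collinear fit atoms; collinear
  selections raise a degenerate-fit error.
* Problem sizes in the shipped tests and acceptance runs (10 recovery
  seeds, 20000-frame recovery trajectories, 1e5-point Monte-Carlo SASA
  oracle) were chosen to keep the full run in the minutes range while
  leaving the statistical tolerances comfortably non-binding.

# Known limitations

* The SCA variant is fixed; eigenmode/ICA "sector" decompositions and
  direct-coupling (DCA) methods are out of scope.
* No aligner, no phylogenetic trees, no mmCIF, no force-field energies,
  no MD engine: inputs are alignments, PDB coordinates and tables.
* The 5 Å rule classifies "in the binding site" only; no second cutoff
  for "near the site" is defined, since no such threshold is
  established.
* DCD trajectories are not read natively; convert to multi-model PDB.
* H-bond detection without explicit hydrogens is distance-only and
  correspondingly permissive.
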