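---
title: "Ligand validation metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand validation metrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandqc)
```

# The problem

A ligand in a crystal structure can be wrong in three largely independent
ways: it can sit in density that does not support it, it can carry more
(or less) density than its modelled occupancy accounts for, and its
internal geometry or packing can be physically strained. `ligandqc` scores
each failure mode with one number, places each number on a percentile
scale against a reference corpus of ligands, and combines the ranks into a
single score. This vignette records the models behind each metric, the
tunable parameters, and the design decisions taken where more than one
reasonable choice existed.

# Ligand selection

Non-polymer residue types (excluding water and the standard amino acids
and nucleotides; the exclusion list is an argument) are ranked by their
**dictionary** non-hydrogen atom count — the dictionary is authoritative
so that incompletely modelled instances do not shrink a ligand. An
instance is rejected, with a logged reason, if its comp-id is annotated
obsolete, any of its atoms appears in a covalent link record, any atom
carries an alternate-location code, or the experimental data are flagged
unavailable or twinned. The data flags are caller-supplied metadata:
twinning tests are out of scope here, and recomputing them would drag
reflection processing into a coordinate-level tool.

Ties are resolved deterministically: types with equal atom counts by
lexicographic comp-id, instances of one type by (chain, sequence number).
Determinism matters more than any particular convention — re-running a
validation must reproduce the selection and the rejection log bit for bit.

# Density model

No structure-factor round trip is performed. Model maps are real-space
Gaussian syntheses: atom *i* contributes

$$\rho_i(r) = occ_i \, Z_i \, (2\pi(u_i^2+w^2))^{-3/2}
  \exp\!\left(-\frac{|r-r_i|^2}{2(u_i^2+w^2)}\right),
  \qquad u_i^2 = B_i/8\pi^2,$$

with $Z_i$ the atomic number and $w$ a fixed softening width (default
0.5 Å, added in quadrature) standing in for the width of the atomic
scattering factor. The single-Gaussian form drops the multi-Gaussian
scattering tables of a real map calculation but preserves the properties
the metrics rely on: total mass $occ \cdot Z$, linearity in occupancy,
B-dependent smearing, and a peak at the atomic position. "Observed" maps
are the same synthesis at the ground-truth occupancy plus i.i.d. normal
grid noise; the 2mFo−DFc and difference-map machinery of reciprocal-space
refinement is emulated by plain grid subtraction. Consequences to keep in
mind: there is no series-termination ripple, no solvent contribution, no
model-phase bias, and the maps are exactly self-consistent when noise is
zero — which is what makes the exact acceptance limits (`cc_direct` = 1,
identically zero difference grid) meaningful.

The **direct map** is computed as observed minus the non-ligand model
density, i.e. a real-space ligand-omit map; `cc_direct` correlates it with
the ligand-only model density. The **difference map** is observed minus
the full model, recomputed through the identical code path as the
observed synthesis so that self-consistent inputs cancel bitwise.
`cc_diff` correlates it with the ligand density: negative means too much
modelled density (over-occupancy), positive too little.

Default grid spacing is 0.5 Å — fine enough that the masked region of a
six-atom ligand holds a few thousand points, coarse enough that a full
validation runs in well under a second.

# Masking

Correlations are taken only over grid points within the mask radius of at
least one ligand atom and outside the (optionally inflated) mask radius of
every environment atom, removing density contributions from neighbouring
residues. The radius follows a REFMAC-like displacement-inflated form
$r = r_0(\mathrm{el}) + c_b\sqrt{B/8\pi^2}$ with defaults
$r_0$(C/N/O/S/P) = 1.7/1.6/1.5/1.8/1.8 Å, $c_b = 3$, neighbour inflation
0 Å. The exact radius function used by refinement programs is not public
in closed form, so all three pieces are exposed in `mask_spec()`. An
empty masked set (a ligand completely swallowed by its environment) is an
error, not an empty answer: it signals pathological overlap that no
correlation could describe honestly.

# Geometry Z-worst

Every dictionary bond and angle present in the instance is measured from
the coordinates (Euclidean length; arccos of the normalized dot product)
and scored as $Z = (\mathrm{obs} - \mathrm{target}) /
\max(\sigma, \mathrm{floor})$, with floors of 0.015 Å for bonds and 1° for
angles. The floor inflates implausibly tight reference sigmas — spreads
estimated from a handful of correlated observations — so it can only
*lower* |Z|: weak prior knowledge never strengthens a distortion claim.
The alternative reading of a sigma cutoff, discarding the feature
entirely, would silently hide distortions on exactly the features least
supported by data; inflation keeps them visible but honest.

The summary statistic is the feature with the largest |Z| ("Z-worst").
Ties keep the first feature in dictionary order, bonds before angles.
Hydrogen restraints are skipped (model H positions are riding or absent),
as are features with missing atoms — skipped, warned about and counted,
never silently dropped. The slider bands used for reporting are |Z| ≤ 1
"likely" and |Z| ≥ 5 "unlikely", linear in between.

# Contacts

Contacts are computed on heavy atoms with united-atom van der Waals radii
(C 1.90, N 1.70, O 1.60, S 1.95, P 1.95 Å, configurable), without explicit
hydrogen placement — a deliberate simplification of the Reduce/Probe
pipeline; absolute counts will differ from Probe's, but the metric (an
integer count of badly overlapping pairs) and its orientation are
preserved. The gap is distance minus summed radii; categories are wide
(> 0.25 Å), close (0 – 0.25 Å], small overlap [−0.4 – 0 Å], bad
(< −0.4 Å, the MolProbity clash convention). Nitrogen/oxygen pairs can
hydrogen bond, so their gap is relaxed by 0.2 Å before classification
(default on, configurable); the reported gap stays geometric. Pairs within
two bonds of each other through covalent link records never appear:
ligand connectivity comes from the dictionary, environment connectivity
from intra-residue distances below 1.8 Å.

# Ranking and the combined score

Percentile ranks use the mid-rank convention,
$R = 100\,(n_{worse} + \tfrac12 n_{equal})/N$, after orienting each metric
so larger is better: `cc_direct` higher-better, `z_worst` and `n_bad`
lower-better, and `cc_diff` **nearer-zero-better** — both signs of a
difference-map correlation indicate mismodelling, so magnitude is what
should be penalized. The orientation is an argument for users who prefer
to reward positive residual correlation.

The combined score is $S = (R_{dir}^2 + R_{diff}^2 + R_{MogulZ}^2 +
R_{bumps}^2)/400$, the simplest unit-weight form that is strictly
increasing in every rank, maps (0,0,0,0) to 0 and (100,100,100,100) to
100, and spreads out the top end relative to linear addition: of two
profiles with the same rank sum, the more extreme one scores higher
((100,100,100,50) beats (87.5,87.5,87.5,87.5)). It is a single
config-swappable function. Resolution is stored with each record but is
deliberately **not** part of the scoring model; it remains available for
descriptive binning queries.

The store is an in-memory data frame persisted as versioned CSV with
JSON export. A relational single-file backend would serve equally; the
store surface (`build-db` / `percentile` verbs, round-trip identity of
every percentile) is independent of the backend.

# Effective resolution

$R_{eff} = d_{min}(N_{total}/N_{eff})^{1/3}$ with
$N_{eff} = \sum_{obs} F^2/(F^2+\sigma(F)^2)$. The form is a declared
stand-in honouring the idea of discounting missing and weak reflections:
complete error-free data give $R_{eff} = d_{min}$ exactly, half-missing
error-free data give $d_{min}2^{1/3}$, added noise can only worsen it,
and duplicating every record changes nothing. It is metadata alongside
the four scored metrics, not a scored metric itself.

# The synthetic-data generator

`make_toy_complex()` builds one of two bundled ligands from internal
coordinates — `TGL`, a glycerol-like triol (6 heavy atoms) and `TPU`, a
purine-like C₅N₄O₂ compound (11 heavy atoms) — and measures the restraint
dictionary (bond targets, all connected angle triples) directly from the
ideal geometry, so a fresh complex scores Z = 0 on every feature by
construction. Both templates are acyclic so that `distort_ligand()` can
perturb internal coordinates independently and rebuild Cartesian
coordinates exactly; ring-closure constraints would couple them. Pocket
atoms (C/N/O, B-factors uniform on 10–30 Å²) are scattered with every
ligand-pocket vdW gap at least `pocket_min_gap` (default 0.3 Å; negative
values deliberately force clashes for contact tests).

Reference corpora draw from documented parametric families whose medians
are solved to match their targets: `cc_direct` from a shifted Beta on
[−1, 1] (second shape fixed at 2, first solved numerically),
`cc_diff` from a clamped Normal (sd 0.15; clamping is monotone, so the
median is preserved), `z_worst` from a log-Normal (log-sd 0.6), `n_bad`
from a Poisson with rate median + 0.4, which reproduces small integer
medians exactly. The default medians — `cc_diff` −0.073 and `n_bad` 1 —
anchor the corpus to wwPDB-scale ligand statistics; `cc_direct` 0.92 and
`z_worst` 2.0 are round values consistent with a corpus dominated by
acceptable ligands.

What the generator does **not** emulate: crystallographic symmetry mates,
solvent structure, correlated map noise, anisotropic displacement,
multi-conformer ligands, and refinement feedback (the occupancy scan runs
without re-refining, so on real data the scan's crossing is an estimate,
not the exactly recoverable truth it is on synthetic maps). Tests passing
on synthetic data therefore demonstrate the correctness of the metric
*definitions* and their implementation, not the field accuracy of any
particular threshold.

# Numerical choices and degenerate inputs

* Gaussian synthesis truncates atoms at 6 combined standard deviations;
  the mass error is below 0.1%, well inside the 2% integral tolerance
  tested.
* Correlations with fewer than two points or zero variance raise errors;
  the occupancy scan converts them to `NA` entries (a zero residual at
  the true occupancy is information, not a failure), and treats residual
  standard deviations below 10⁻¹⁰ of the observed signal as
  floating-point cancellation, not density.
* Q–Q plotting positions are $(i-\tfrac12)/n$; the observed side is
  standardized by its own mean and standard deviation, so the plot reads
  shape only.
* Angle computations clamp the cosine into [−1, 1]; zero-length bond
  vectors skip the feature with a warning.
* The coverage check in map synthesis warns (3 Å margin, with a 0.01 Å
  tolerance absorbing coordinate rounding in file formats) rather than
  errors: partial coverage degrades, but does not invalidate, a
  correlation.

# Problem sizes

The test suite and the acceptance script run on complexes of 6–11 ligand
atoms with 3–13 pocket atoms on 0.5–0.9 Å grids (10³–10⁵ grid points),
50–100-seed oracle sweeps, and 10⁴-record corpora. These sizes keep the
whole suite under half a minute while leaving every oracle comparison
exact; the implementation itself is size-agnostic, and a full-size
protein environment only grows the vectorized per-atom loops linearly.

# Known limitations

No chirality validation (a yes/no result that does not fit the sliding
scale, and CIP conversion is genuinely hard); no torsion or planarity
scoring; no symmetry-expanded environments; Z-scores come from dictionary
(target, sigma) pairs rather than empirical fragment distributions, so a
ligand refined with the same dictionary will look better than an
independent reference would judge it; contact counts are united-atom
approximations; and the combined score uses unit weights even though the
density-fit term is arguably the most important metric — non-unit weights
are a one-line change in the score strategy.
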