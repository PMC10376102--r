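---
title: "Predicting backbone torsion-angle fluctuations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting backbone torsion-angle fluctuations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A folded protein is not rigid: each residue's backbone torsions — phi (the
rotation about N–Cα) and psi (about Cα–C) — fluctuate, and the amplitude of
those fluctuations varies along the chain. Flexible segments (loops, termini,
intrinsically disordered regions) show large torsional spread; well-packed
secondary structure shows almost none. Multi-model structural ensembles such
as NMR depositions capture this directly: each deposited model is an
alternative conformation, and the per-residue spread of phi/psi across the
models is an observable, per-residue measure of backbone flexibility.

`torsionflux` implements the full path from such ensembles to a
sequence-based predictor of these fluctuations:

1. **labels** — parse multi-model structures, measure per-residue circular
   dispersion of phi and psi across models, normalise to `[0, 1]`;
2. **features** — assemble per-residue sequence-derived profiles into a
   sliding-window feature matrix;
3. **selection** — wrapper feature selection with a genetic algorithm (GA)
   scored by a gradient-boosted tree regressor;
4. **regression** — train and evaluate the final boosted regressor under
   chain-level cross-validation.

A synthetic-data module generates every input the pipeline consumes, so all
stages can be exercised and verified without external databases or
third-party feature programs.

# Labels: circular dispersion of backbone torsions

## Dihedral geometry

Dihedrals follow the IUPAC sign convention (cis = 0°, trans = 180°, positive
clockwise viewed from the second to the third atom). phi(i) is measured over
C(i−1)–N(i)–Cα(i)–C(i), psi(i) over N(i)–Cα(i)–C(i)–N(i+1); the first phi
and last psi of a chain do not exist and are flagged undefined rather than
set to zero. The inverse operation, `build_backbone()`, places N/Cα/C atoms
by natural extension from idealised bond lengths (N–Cα 1.458 Å, Cα–C
1.525 Å, C–N 1.329 Å) and angles (111.2°, 116.2°, 121.7°), with a trans
peptide bond (omega = 180°) by default. Building a backbone from angles and
re-measuring recovers the inputs to better than 1e−6 degrees; this
round-trip, together with rigid-motion invariance at 1e−9 degrees, is the
correctness oracle for the whole geometry layer.

## The fluctuation statistic

Angles live on a circle, so dispersion must be circular. For the M model
values of one residue's torsion we take the circular mean (atan2 of mean
sine and cosine), wrap each deviation into (−180°, 180°], and report the
root mean square deviation with population (1/M) normalisation:

$$\sigma = \sqrt{\tfrac{1}{M}\sum_m \mathrm{wrap}(\theta_m - \bar\theta)^2}.$$

Two properties motivated this choice over the alternative
$\sqrt{-2\ln R}$ dispersion: the wrapped standard deviation is bounded by
180°, so dividing by 180 gives a label that provably lives in `[0, 1]`,
which is the scale on which fluctuation predictors report their errors; and
it reduces to the ordinary standard deviation for tightly clustered angles.
The 1/180 normalisation itself is fixed by a consistency observation: the
earlier neural-network baseline reports MAEs of 22.7° and 24.3° on the
degree scale and 0.126 / 0.135 on the dimensionless scale, and only
division by 180 maps one onto the other (see `reference_benchmarks()`; the
acceptance script recomputes this).

Population rather than sample (1/(M−1)) normalisation is the default and is
configurable; for the ensemble sizes involved (M ≥ 5, typically 20) the
difference is well under the noise floor, and the population form keeps the
M-replication invariance exact (repeating every model k times leaves labels
unchanged). Residues where fewer than two models define the torsion — chain
termini, incomplete backbones, degenerate geometry — get an undefined label
and are excluded from training and evaluation rather than imputed; imputing
zeros would systematically understate flexibility exactly where the data
are least trustworthy.

## Dataset filters

Ensemble sets are filtered by three rules, applied in order and reported
per rule: fewer than 5 models, shorter than 25 residues, any nonstandard
residue. Thresholds are strict (exactly 5 models or exactly 25 residues is
kept). Parsing policy where the ensemble format is underspecified:
alternate locations resolve to the highest-occupancy copy (ties: first
encountered), insertion codes participate in residue ordering, and a
residue missing a backbone atom is excluded from labels rather than the
whole model being dropped — this maximises the number of usable residues.

# Features

Five per-residue profile groups are assembled, with a documented default
layout of 77 base columns:

| group | width | content |
|---|---|---|
| residue | 20 | one-hot amino-acid identity, alphabetical (ACDEFGHIKLMNPQRSTVWY) |
| physiochemical | 5 | five-factor scores: polarity, secondary-structure propensity, volume, codon diversity, charge |
| pssm | 20 | logistic-normalised position-specific scoring matrix |
| monogram | 1 | row mean of the normalised PSSM |
| bigram | 20 | expected forward-transition products |
| structural | 7 | predicted ASA + two three-state SS probability sets (H, C, E) |
| flexibility | 4 | disorder probability, upstream predicted dphi/dpsi, contact energy (PSEE) |

Design decisions where the inputs left room:

* **One-hot residue identity.** "One numerical value per amino acid" admits
  both a single ordinal column and an indicator block; the 20-column
  indicator is the standard encoding that composes with tree models and is
  what a 20-wide residue profile implies.
* **Logistic PSSM normalisation.** Integer log-odds scores are mapped by
  `1/(1+exp(−x))` into (0, 1), the convention of the upstream disorder /
  structure feature tools; a score of 0 maps to 0.5.
* **Bigram formula.** The 20-wide bigram is defined per residue as
  `BG_k(i) = (1/20) Σ_j P(i,j) · P(i+1,k)` — the expected transition
  product into the successor profile — with a self-transition fallback at
  the chain's last residue.
* **Total width 77, configurable.** The five groups as described sum to 77
  columns. Published feature sets for this task cite a 179-dimensional
  vector whose exact breakdown is not recoverable from the available
  description; the assembly is therefore config-driven (groups can be
  enabled, disabled and reordered) and no particular total is asserted
  beyond the documented default.
* **Imputation.** After assembly any remaining NA cells (e.g. a missing
  PSEE input) are filled with the chain-level column mean, falling back to
  zero for an entirely absent column, so downstream stages never see NaNs.
  Out-of-range probabilities are clipped to `[0, 1]` with a warning.

Sliding windows concatenate each residue's features with its ws−1
neighbours (ws odd). Out-of-chain positions are zero-padded by default
(edge replication is available); zero-padding keeps the windowed feature of
a terminus distinguishable from an interior residue with identical local
features, which matters because termini are systematically more flexible.
Windowing is strictly chain-local.

# Genetic-algorithm feature selection

Selection operates on binary chromosomes with one gene per (windowed)
feature column. Fitness of a mask is the cross-validated performance of a
gradient-boosted tree regressor trained on the masked columns, summarised
by the objective

$$\mathrm{objfit} = 1 - \mathrm{MAE} + \mathrm{PCC},$$

computed on out-of-fold predictions pooled across a chain-level k-fold
split (default 3 folds inside the fitness, a pragmatic trade-off between
variance and the cost of refitting the regressor hundreds of times). The
fitness regressor uses the selection-stage settings: depth 6, learning
rate 0.1, 100 rounds, minimum child weight 5, row subsample 0.9, histogram
trees with 500 bins. An empty mask scores −Inf and can never propagate.

The evolutionary loop is generational: the top `elite_count` chromosomes
are copied unchanged (making the best-so-far fitness provably
non-decreasing), and the remainder come from fitness-proportional
(roulette) parent selection, single-point crossover, and per-gene bit-flip
mutation. Because objfit values for reasonable masks occupy a narrow band
(roughly 1.3–1.7 on realistic data), raw roulette weights would barely
differentiate parents; weights are therefore windowed by the generation
minimum (plus 10% of the range) before sampling, a standard fitness-scaling
device that preserves the proportional scheme while keeping selection
pressure meaningful. Defaults — population 50, 30 generations, 2 elites,
crossover 0.9, mutation 1/D — are conventional GA settings for
feature-selection problems of a few hundred genes; none of them is dictated
by the underlying method, which specifies only the operator families.
Fitness evaluations are cached by mask, and the entire run is reproducible
from one seed.

On the planted-signal study (10 chains × 50 residues, 5 informative
columns of 50 with equal weights summing to 1, label noise SD 0.1), a
desk-scale run (population 24, 15 generations) reliably recovers the
informative set; the test suite and the acceptance script both perform
this recovery and check the elitism monotonicity invariant on every
generation.

# Regression and evaluation

The final predictor is a gradient-boosted decision-tree regressor (one
model per angle — phi and psi are evaluated separately throughout, so
separate models are the natural fit). The package's default configuration
is the tuned optimum for this task: learning rate 0.014, 2561 rounds,
maximum depth 19, 380 leaves, 138 histogram bins, feature fraction 0.52.
Those defaults are sized for a corpus of several hundred chains; the test
suite and examples use much lighter settings matched to their simulation
sizes.

Evaluation is chain-level 10-fold cross-validation: chains (never residues)
are shuffled by seed and partitioned, so all residues of a chain share a
fold and no chain ever contributes to both training and test — the
assignment is asserted structurally on every run. MAE and PCC are computed
on the pooled out-of-fold predictions within each fold and then averaged
across folds (the pooled-then-averaged convention; per-chain averaging
would up-weight short chains). The comparison-table utility reports
percentage improvements as `(base−new)/base` for MAE, `(new−base)/base`
for PCC, and their mean — note that averaging a pair of printed,
already-rounded improvements can differ in the second decimal from
improvements recomputed from rounded MAE/PCC values; the utility is defined
on the values supplied to it.

The window-size sweep re-windows the base features at each candidate ws,
cross-validates, and reports objfit per ws with the argmax flagged. On
synthetic labels constructed from the ±1 neighbours only, ws = 3 wins, and
on purely central signal ws = 1 is within noise of the best — mirroring the
behaviour that fixed the production window at 3.

# The synthetic-data generator

`synth_ensemble()` plants per-residue angular noise: for each model,
phi/psi are drawn from a wrapped normal around per-residue base angles with
per-residue SDs (sigma), and coordinates are rebuilt by natural extension.
The generator emulates exactly the property the labels measure —
per-residue circular dispersion — so the end-to-end check is parameter
recovery: labels from a sigma-profile ensemble converge to sigma/180 as M
grows (verified on the grid 0°/9°/18°/36° at M = 200 to within 5%
relative; the sigma = 0 case recovers exactly 0). The default base
conformation is an extended chain (phi = −120°, psi = 135°); base angles
are irrelevant to the dispersion statistic, which is location-invariant on
the circle.

`synth_features()` plants a linear signal: features are U(0, 1), labels are
`clip01(intercept + Σ coeff · X[i+offset, c] + ε)`. Offsets give the labels
a known windowed structure (the ground truth is recorded on the returned
object), which drives both the GA-recovery and window-sweep checks. The
defaults (10 chains × 50 residues, 5 informative of 50 columns, equal
coefficients summing to 1 so labels rarely clip, noise SD 0.1) define the
selection study; the theoretical-ceiling CV check uses a single informative
column scaled as `y = 0.25 + 0.5X + ε` with the noise SD solved from a
target population correlation of 0.8, keeping labels strictly inside
`[0, 1]` so clipping cannot distort the ceiling.

What the generator does *not* emulate: sequence-dependent noise (real
flexibility correlates with residue identity and local structure),
correlated phi/psi fluctuations within a residue beyond what a shared
sigma profile induces, model-to-model correlations within a deposition,
and any relationship between the feature profiles and true dynamics.
Passing tests therefore demonstrate that the machinery — geometry, circular
statistics, windowing, selection, validated regression — is correct and
unbiased on data with known ground truth, not that any particular accuracy
will be attained on real ensembles, which additionally require the
third-party per-residue feature programs whose outputs this package treats
as inputs.

# Numerical choices and problem sizes

* Angles are wrapped into (−180°, 180°], with −180 mapped to +180.
* A circular mean is declared undefined when the resultant length falls
  below 1e−12 (e.g. an antipodal pair); the affected residue's label is
  undefined, not zero.
* Dihedrals are undefined for coincident consecutive points or collinear
  triples (tolerance 1e−10 on the relevant norms).
* Cross-validation folds differ in size by at most one chain; the GA and
  the booster are single-threaded and explicitly seeded, so every result
  in the package is reproducible from one integer.
* The test suite and the acceptance script run their simulations at
  desk scale — 500-row selection problems, 3 000-row CV checks, M = 200
  ensembles — chosen so the full suite completes in a few minutes on one
  core while keeping the Monte-Carlo error of each check several times
  smaller than its tolerance.

For the full-scale tuning problem the package deliberately ships only a
plain grid utility (`grid_search()`): it crosses the supplied parameter
values under the same chain-level cross-validation and ranks them by
objfit, with no sampling or pruning heuristics.

# Known limitations

* Real multi-model depositions occasionally vary atom counts between
  models; the parser flags residues whose backbone is incomplete and
  excludes them from labels, but it assumes models agree on the residues
  present.
* The dispersion statistic treats models as an unordered sample; it does
  not weight models or account for within-deposition correlation.
* The 77-column default layout is one defensible reading of the published
  feature description; users reproducing a specific published model should
  verify the layout against that model's documentation and adjust the
  config.
* GA selection is stochastic; different seeds can select slightly
  different masks of equivalent fitness. The recovery guarantees tested
  here are statements about planted signal, not about uniqueness.
* The flexibility profile includes dphi/dpsi predictions from an earlier
  upstream predictor as input features. When labels derive from the same
  ensembles that trained that upstream predictor, this can import
  information about the target; users concerned about such leakage should
  disable the `flexibility` group (or those two columns) in the layout and
  compare.
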