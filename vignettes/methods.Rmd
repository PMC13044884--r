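---
title: "Semi-quantification from structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-quantification from structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Broad-scope LC-HRMS screening of whole blood routinely flags compounds for
which no reference standard is at hand — newly emerging psychoactive
substances, drugs not marketed locally, rare pesticides. Deciding whether
such a finding is toxicologically relevant requires at least a rough
concentration, but a calibration curve cannot be built without the
standard. `graphquant` implements the alternative: learn a molecule's
*response factor* from its structure, then invert the measured signal.

For a molecule $m$ spiked at concentration $c_m$ (mg/kg), the instrument
yields a peak area $s_m$, normalized by the internal-standard area of the
same run to $\bar{s}_m = s_m / s_\mathrm{ISTD}$. The signal-to-concentration
ratio and its log form are

$$\alpha_m = \frac{\bar{s}_m}{c_m}, \qquad \beta_m = \ln \alpha_m .$$

$\alpha_m$ spans roughly three orders of magnitude across drug-like
molecules; the log transform makes it a tractable regression target. A
model $\hat\beta(\text{structure})$ turns a measured $\bar s$ of an unknown
into $\hat c = \bar{s} / e^{\hat\beta}$. An error of at most $\ln 2$ in
$\hat\beta$ bounds $\hat c$ between 50% and 200% of the truth, which is the
package's headline accuracy criterion:

$$A = \frac{1}{N}\,\#\{\,m : |\hat\beta_m - \beta_m| < t\,\}, \qquad
t = \ln 2 .$$

The strict inequality is deliberate: a deviation exactly equal to $t$
counts as incorrect. $t=\ln 2$ equals the spacing of a two-fold serial
dilution, the smallest interval between adjacent spiking levels in the
targeted acquisition design.

## Preprocessing

`preprocess_measurements()` turns a measurement table into one $\beta$ per
molecule:

1. user-supplied exclusions are dropped first and logged (manual removals
   — e.g. compounds with matrix interference — are an input, never
   inferred);
2. $\alpha$ is computed per measurement and averaged per molecule;
3. values deviating from that mean by more than $0.5\,\bar\alpha_m$
   (strictly) are flagged, removed, and the mean recomputed **once**.

The filter is single-pass by design: the flagging mean includes the
outliers, and the mean is recomputed once after removal rather than
iterated to a fixed point. Both the pre- and post-removal means are
reported (`mean_alpha_all`, `mean_alpha`); the post-removal mean is
canonical. If every value of a molecule would be flagged, all are kept and
a warning raised. Zero-area rows produce $\alpha = 0$, violate the
positivity invariant, and are routed to the rejects table with a reason
code instead of silently vanishing.

## Featurization

`featurize_molecules()` builds, per molecule, a heavy-atom graph (edges =
bonds, no bond-type attributes — only connectivity) and a 16-column node
feature matrix. Chemistry perception is OpenBabel's (via ChemmineOB);
node order follows the SMILES parse order, which the positional readout
modes below rely on.

Local columns 1–12, in fixed order: atomic number; hydrogen count;
valence-electron count of the element; radical-electron count; formal
charge; hybridization as a single small-integer code (0 unspecified, 1 sp,
2 sp², 3 sp³, 4 sp³d, 5 sp³d², 6 other — one integer rather than a one-hot
block keeps exactly twelve local columns); heavy-atom degree; in-ring
flag; aromatic flag; and van der Waals radius, atomic mass and covalent
radius, each divided by a fixed constant (the maximum tabulated value over
H–Rn: 2.20 Å, 222.0 u, 1.50 Å) so the three columns lie in (0, 1].
Ring membership is the 2-core of the heavy-atom graph; an atom is aromatic
when it is in a ring and carries an OpenBabel aromatic bond (the ring
guard keeps carboxylate oxygens, which OpenBabel also types with `ar`
bonds, non-aromatic).

Global columns 13–16 are the molecule's 3D volume, width, length and
height, copied identically onto every node so the network reads molecular
size directly instead of having to infer it through message passing. One
conformer is embedded per molecule (OpenBabel `gen3d`, a deterministic
distance-geometry + force-field protocol); extents are ranges along the
principal axes of the heavy-atom coordinate cloud, sorted descending. The
volume is the sum of atomic vdW spheres minus pairwise overlap lenses — a
closed form chosen over a grid estimate because it is *exactly* invariant
under rigid rotation (a grid is not). It ignores triple-sphere overlaps
and therefore underestimates slightly; as a size feature this bias is
irrelevant. Disconnected SMILES (salts, mixtures) keep their largest
fragment, with the dropped atom count recorded.

Descriptor-based models consume a molecule × descriptor table instead.
The canonical path is importing a precomputed table (PaDEL export
dialect) with `load_descriptor_table()` — external engines' values are
version-dependent, so the package does not recompute them — plus the
transparent in-package `count_descriptors()` set derived from the graph
alone. NA cells are column-median imputed and flagged; constant columns
are kept but listed. `select_main_features()` reduces a large table to the
`k` (default 11) descriptors with the largest random-forest impurity
decrease, ties broken by name.

## The GAT regressor

`train_gnn()` fits a graph attention network: 4 GAT layers for the blood
β task (5 recommended for the logIE ionization-efficiency benchmark), 28
channels per hidden layer, one attention head, tanh between layers, and a
single-channel final GAT layer with identity activation — β spans roughly
[0, 7], so a bounded output nonlinearity would be wrong. Undirected bonds
are presented to the attention mechanism as both directed edges plus
self-loops (the standard message-passing contract). The per-node scalar
outputs are reduced to one molecular value by a readout: `average`
(arithmetic mean, the default) or the output at the `first_node`,
`second_node` or `last_node` of the SMILES atom order; `second_node` on a
one-atom molecule falls back to the first node with a warning.

Training minimizes full-batch mean squared error with RMSprop
(smoothing 0.99, epsilon 1e-8). Learning rate 1e-3 and 2000 epochs are the
defaults — chosen for stable convergence on small (order 10²) data sets —
and are exposed in `gnn_config()` together with everything else. Node
features are standardized to zero mean/unit variance with training-set
statistics stored in the model; targets are never standardized. Weights
are Glorot-uniform from a dedicated RNG, so a fixed seed reproduces the
trajectory exactly on a given machine. A non-finite loss aborts with the
epoch index. The repeated-run protocol retrains with `n_repeats` distinct
seeds and reports mean ± sample standard deviation of each metric.

The implementation (forward, analytic backward, RMSprop loop) is compact
RcppArmadillo with all graphs of a dataset stacked into one node batch;
training 200 drug-sized molecules for 2000 epochs takes seconds on one
CPU core.

## Baselines

Three descriptor-based regressors with fixed configurations:
MLP with hidden sizes (500, 400, 300, 200, 100), ReLU, MSE, Adam,
standardized inputs (trained by the package's own full-batch Adam loop);
decision tree (rpart, depth 4, minimum split 2, squared-error criterion);
random forest (ranger, 500 trees, depth 4, impurity importances). Tree
and forest see raw features — depth-limited trees are scale-invariant, so
standardization is immaterial and omitted. A fourth, intercept-only
"mean" model exists purely as a harness diagnostic and chance-level
reference.

With `feature_set = "main"`, descriptor selection is re-run inside each
training fold by default (strict no-leakage); passing `selected_features`
reuses one global list instead, which is what a fixed published
11-descriptor table implies. Both modes are recorded in the report.

## Cross-validation

`run_cv()` supports LOOCV, non-stratified k-fold (default k = 5, split
seed 42, folds fixed across repeats) and subset-LOOCV (a fresh random
subset of the stated fraction per repeat, for learning-curve studies; each
repeat draws with its own seed). Metrics are computed on the pooled
out-of-fold predictions of each repeat — LOOCV forces pooling, so k-fold
pools too for comparability — and summarized as mean ± sd over repeats.
Every fold records the training molecule ids and an md5 fingerprint of the
exact training inputs (ids, feature matrix, targets), so test-fold
isolation is checkable after the fact; the test suite verifies that the
held-out molecule never enters them, including through standardization or
feature selection.

## The synthetic study generator

Real training data requires spiked whole-blood acquisitions, so the
package ships a generator that emulates the acquisition design end to
end and makes every stage testable offline:

* molecules come from a fixed deterministic SMILES grammar (linear
  alkanes/alcohols/amines, benzene/pyridine/naphthalene scaffolds with
  alkyl chains, halogenated variants; 240 distinct strings, all valid by
  construction);
* the ground-truth rule
  $\beta = 0.4\,n_\text{heavy} - 0.1\,n_\text{aromatic} +
  0.8\,\mathbf{1}\{\text{contains N}\} + \varepsilon$,
  $\varepsilon \sim N(0, \sigma_\beta^2)$ (default $\sigma_\beta = 0.1$),
  is computable from the graph alone and spans about three orders of
  magnitude in $\alpha$ over the grammar — learnable by both the GAT and
  the count-descriptor baselines, and verifiable;
* each molecule gets a seven-level two-fold dilution series
  (0.0016–0.1 mg/kg), area
  $s = e^{\beta}\, c\, s_\mathrm{ISTD} (1 + \delta)$ with multiplicative
  noise $\delta \sim N(0, \text{cv}^2)$ (default cv 0.05) and a fixed
  internal-standard area;
* an optional fraction of rows is perturbed one-sidedly by
  $(1 + \text{offset})$, offset > 0.5 so every injected outlier violates
  the $\pm 0.5\bar\alpha$ filter. Injection is limited to one row per
  molecule: two same-signed multiplicative outliers in one seven-row
  series at offset 0.8 would shift the flagging mean enough that neither
  exceeds the threshold, so the one-per-molecule layout is what makes
  "flagged set = injected set" a provable property rather than a
  probabilistic one.

What the generator does **not** emulate: matrix effects, adduct
chemistry, isotope patterns, retention-time behaviour, heteroscedastic
detector noise, or any real relationship between structure and ionization
beyond the planted linear rule. Passing tests therefore demonstrate that
the machinery — preprocessing algebra, filter semantics, featurization,
training, validation hygiene — is correct and that the models can recover
a structure-determined response factor at realistic noise levels; they do
not certify predictive accuracy on real casework, which must come from
real spiked-blood training data.

## Numerical and design notes

* **Accuracy direction.** The thresholded score is implemented as the
  fraction of *correct* predictions (higher is better), with strict
  inequality at the boundary.
* **Problem sizes.** The shipped test suite and the acceptance script
  work at 200 synthetic molecules, 5-fold × 5 seeds — large enough for
  stable estimates of the recovery properties, small enough to run
  comfortably on one CPU core.
* **Readout default.** Average pooling is the default readout; the three
  positional modes are retained because they are cheap to compare and
  occasionally competitive on small data sets.
* **Determinism.** Everything stochastic (grammar sampling, noise draws,
  weight init, fold splits, subset draws) flows from explicit integer
  seeds; OpenBabel's 3D embedding is deterministic, and `conformer_seed`
  is recorded with each shape for provenance.
* **Degenerate inputs.** One-atom molecules: zero extents, positive
  volume, `second_node` fallback. All-flagged α records: kept with a
  warning. Constant descriptor columns: retained but flagged. Constant
  targets: warned, still fitted.
* **Checkpoints.** Model checkpoints are JSON (config + weights +
  standardization statistics + training-data fingerprint): text-only,
  diffable, and robust to serialization-format drift.

## Limitations

The GAT is a single-head, edge-feature-free architecture; bond orders are
deliberately not encoded. No hyperparameter search, GPU path, uncertainty
quantification, or significance testing between models is provided. The
application domain of any model trained with this package is bounded by
its training chemistry — predictions for molecule classes absent from
training (or compounds that ionize as adducts other than [M+H]⁺, or
fragment in-source) should be treated as unreliable.
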