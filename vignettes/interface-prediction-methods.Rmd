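---
title: "Predicting protein-protein interface residues under class imbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interface residues under class imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppisite)
```

## The problem

Residues that mediate protein-protein interactions are a small minority of a
protein's surface. A typical curated set of transient complexes yields
roughly one interface residue for every 3.5 non-interface surface residues,
and a classifier trained naively on such data maximises accuracy by calling
almost everything non-interface: its sensitivity collapses towards zero while
its specificity approaches one. `ppisite` implements a complete pipeline for
this prediction task whose central ingredient is *imbalance-aware
undersampling of the majority class*, targeted at the regions of feature
space where the two classes overlap.

## Geometric labelling

Ground-truth labels come from the complex structure itself.

* **Surface.** Each chain is considered in isolation (monomer state) and the
  solvent-accessible surface area of every residue is computed by the
  Shrake-Rupley method: each atom is inflated by a probe radius (default
  1.4 Å, a water molecule) and covered with a deterministic golden-angle
  spiral of test points (default 960); the accessible fraction of points
  gives the area. Absolute ASA is normalised by a residue-type maximum (the
  Tien et al. 2013 theoretical values, shipped as a replaceable table) to
  give relative ASA (RASA). A residue is *surface* when RASA strictly
  exceeds 0.16. Monomer-state ASA matters: interface residues are buried in
  the complex, so surface labelling on the assembled complex would exclude
  the very residues we want to find.

* **Interface.** A surface residue is an *interface* residue when its
  distance to some residue of the partner chain is at most 1.2 nm, and
  *non-interface* otherwise; the boundary value counts as interface because
  the non-interface class is defined by strictly exceeding the cutoff. The
  distance is taken between Cα atoms by default (`ca_ca`); a stricter
  reading — the minimum over all carbon-atom pairs — is available as
  `min_carbon`. Both are exposed because "the distance between two residue
  carbon atoms" admits either reading; output headers record which was used.

Numerical notes: residues are keyed by (chain, residue number, insertion
code); alternate locations resolve to the highest-occupancy conformer; only
the first model of a multi-model file is used; MSE is remapped to MET, other
heteroatoms are ignored. Shrake-Rupley areas are exactly translation
invariant but only rotation invariant up to the point-sampling error
(about 1–2% at 960 points), because the spiral directions are fixed in the
laboratory frame; tests assert rotation invariance at that sampling
tolerance rather than at machine precision.

## Feature encoding

Each residue carries a 24-dimensional evolutionary-conservation descriptor:
a 20-component sequence profile (non-negative, summing to 1), a sequence
information entropy, a relative entropy, a sequence weight, and a
conservation score. The package does not compute these from alignments —
they arrive as a tab-separated table (the kind of per-residue output
produced by conservation databases and servers) with declared column names,
so alternative layouts remain loadable.

A surface residue is encoded by a spatial window: its own descriptor
followed by those of its 10 nearest surface residues of the same chain (Cα
Euclidean distance, ordered by increasing distance, ties broken by ascending
residue number for determinism), giving 11 × 24 = 264 columns. Spatial
rather than sequence neighbourhoods are used because interface patches are
contiguous on the surface, not in the sequence. Chains with fewer than 11
surface residues are zero-padded and the pad count is recorded per row so
downstream users can filter. Raw feature values are preserved in the sample
matrix; z-scoring happens inside the resampling procedures, where Euclidean
geometry matters, and is unnecessary for the tree classifier, which is
invariant to monotone per-feature transforms.

## Re-balancing the classes

Both methods remove majority-class (non-interface) samples; neither invents
synthetic minority samples.

**RENN (repeated edited nearest neighbours).** In each sweep, every
removable sample looks up its three nearest neighbours (Euclidean distance
in z-scored feature space, excluding itself); if at least two of the three
carry a different label, the sample is marked. All marked samples are
removed *simultaneously* at the end of the sweep — batch removal makes the
result independent of the order in which samples are visited, which a
sequential reading of the editing loop would not be. Sweeps repeat until
nothing is removed. Z-scores are re-fitted on the current set at each sweep,
which makes a converged set an exact fixed point of the whole procedure: a
property the test suite asserts. The default restricts removal to the
negative class (the majority), which keeps every interface example; an
`all` mode implements the unrestricted textbook editing rule.

**IHT (instance hardness threshold).** The hardness of a sample is
IH = 1 − p(own label | features, estimator): the probability mass the
estimator puts *against* the sample's own label. Hard samples sit on class
boundaries, in overlap regions, or are mislabelled. Probabilities come from
a logistic-regression estimator evaluated *out of fold* (5 stratified folds,
fixed seed): each sample is scored by a model that never saw it, since
in-sample probabilities from a flexible estimator would be optimistically
small for exactly the noisy points the method must find. The hardest
negatives are then removed — ties broken by provenance key for determinism —
until the classes reach the target ratio (default exactly 1:1). If the
estimator fails to converge the final iterate is used and a message is
logged; with several hundred correlated columns the fit is routinely
rank-deficient, which is harmless for prediction.

## Classification and validation

The classifier is a gradient-boosted ensemble of regression trees under a
binary logistic objective with L2 leaf-weight regularisation and an optional
per-leaf penalty: the prediction margin of a sample is the *sum of its leaf
scores across all trees*, mapped through the logistic link, with class
assigned at a 0.5 threshold. Training delegates to the xgboost engine
(single-threaded, fixed seed, prior margin pinned at zero so the additive
contract is exact); the test suite verifies the contract by walking the
dumped trees. No hyperparameter search is performed; the defaults (200
trees, learning rate 0.1, depth 4, λ = 1, γ = 0) are ordinary values for
tabular problems of this size and live in a configuration object.

Evaluation uses stratified 10-fold cross-validation with the confusion
matrix pooled over held-out folds (a per-fold metric list is also returned).
Two orderings of resampling and splitting are provided because published
comparisons often balance the whole dataset before cross-validating, which
leaks edited-set information across folds and evaluates on an easier,
already-cleaned sample:

* `split_then_resample` (default, recommended): the resampler edits each
  training split only; every original sample is predicted exactly once by a
  model that never saw an edited version of it.
* `resample_then_split`: the resampler runs once on the full set before
  folding; a leakage warning is emitted. This mode exists to reproduce the
  whole-dataset-first protocol when comparing against numbers produced that
  way.

From a pooled confusion matrix the six standard measures are computed:
accuracy, sensitivity, precision, specificity, F-measure (harmonic mean of
precision and sensitivity) and the Matthews correlation coefficient. A
measure with a zero denominator — routine in degenerate folds of heavily
imbalanced data — is reported as a flagged sentinel 0 rather than an error,
so a cross-validation run never aborts on arithmetic.

## What the synthetic generator emulates

Real inputs (structures plus conservation tables) require external databases,
so the package ships a generator for every fixture the pipeline needs.

* **Structures:** two-chain poly-alanine systems with Cα traces on parallel
  lines, where requested contact pairs are placed at 11.5 Å — inside the
  12 Å cutoff but far enough that no unintended Cα pair crosses it — giving
  exact, enumerable interface ground truth.
* **Feature tables:** Dirichlet-like profiles with their actual Shannon and
  relative entropies, plus uniform weights and conservation scores.
* **Sample clouds:** the default overlap scenario draws 300 positives and
  1100 negatives in 24 dimensions (one descriptor block; 264 is available
  where the full pipeline width matters), with the two class means separated
  by 4.5 units at unit within-class spread — and, crucially, 100 of the
  negatives drawn from the *positive* distribution. These planted overlap
  negatives make the class-overlap hypothesis literal and exactly known:
  resampler evaluation becomes a parameter-recovery problem (how many
  planted negatives are removed? how many clean ones are collateral?) with
  no appeal to real data. The separation is chosen so that the clean classes
  are nearly separable and essentially all class overlap is the planted set;
  the imbalance ratio (3.67:1) matches the surface-residue regime the
  pipeline targets. The profile block is mapped through a per-block softmax
  so the generated matrices satisfy the descriptor invariants.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring windows (real windows share 10 of 11 residues with their
neighbours), chain-level block structure in cross-validation, realistic
profile covariance from actual alignments, and label noise from the hard
geometric cutoffs. Passing tests on this generator therefore demonstrate
correctness of the algorithms and the direction and rough magnitude of the
balancing effect, not field performance on curated complex sets.

With the default scenario and five repeats of the 10-fold protocol, per-fold
IHT balancing raises pooled sensitivity by roughly 0.2–0.25 while pooled
specificity shifts by less than 0.15 — the qualitative signature that
motivates the whole pipeline. RENN in `all` mode removes the large majority
of planted overlap negatives while touching only a few percent of the clean
ones. Both statements are recomputed, not quoted: the test suite and
`scripts/acceptance.R` measure them at these exact problem sizes (1400
samples, 24 dimensions, 5 seeds), which keep the default run in the tens of
seconds.

## Design choices on genuinely open points

* **Distance mode** for interface labelling defaults to Cα–Cα with
  `min_carbon` as the documented alternative; neither is asserted to be the
  uniquely correct reading of a carbon-distance rule.
* **The 24-dimensional layout** is declared, not assumed: readers check the
  exact column set so a different decomposition of the descriptor can be
  loaded by renaming columns.
* **Neighbour windows never cross chains**: surface geometry is only
  meaningful within a chain, and padding is preferred over borrowing
  residues from a partner chain.
* **Pooled versus averaged metrics:** the pooled confusion matrix is the
  primary report (it composes exactly across folds and reproduces worked
  confusion-matrix arithmetic); per-fold metrics are returned alongside for
  dispersion checks.
* **RENN removal target** defaults to negatives-only, so re-balancing never
  discards scarce interface examples; `all` preserves the unrestricted
  editing rule for users who want symmetric noise removal.

## Limitations

An isolated residue's RASA exceeds 1 by construction (the reference maxima
are tripeptide-context values), so RASA is treated as lying in [0, 1+ε]
rather than clamped. The ASA implementation is quadratic in atoms per chain
and intended for single complexes, not proteome scans. Logistic hardness
estimation on hundreds of collinear columns relies on rank-deficient fits;
a regularised estimator would be a reasonable extension. Cross-validation
folds are stratified by class only, not grouped by chain — on real
multi-chain datasets, chain-grouped folds would be the stricter protocol.
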