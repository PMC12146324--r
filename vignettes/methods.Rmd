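---
title: "Methods: sequence descriptors, labelling and the evaluation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence descriptors, labelling and the evaluation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnclocr)
```

## The model

`lnclocr` treats lncRNA subcellular localization as a per-cell-line
binary classification problem. The response is derived from the
cytoplasmic/nuclear relative concentration index,
$\mathrm{CNRCI} = \log_2(\mathrm{FPKM}_{cyt} / \mathrm{FPKM}_{nuc})$:
strictly positive values are labelled cytoplasm, strictly negative
nucleus. The predictors are 1,223 fixed-length sequence descriptors, so
any classical classifier can be used and the same lncRNA can receive
different models (and labels) in different cell lines.

The key assumptions are (i) that localization signal is encoded in
sequence composition and short-range physicochemical structure, not in
expression level or secondary structure, and (ii) that the CNRCI sign is
a faithful label — boundary (exactly 0) and undefined ratios (zero FPKM
in either compartment) carry no signal and are dropped rather than
assigned to a side.

## Dataset construction and its tunables

* **Length filter** (`max_length`, default 10,000 nt, inclusive): very
  long transcripts mislead the models and dominate the descriptor
  statistics; "up to 10,000" is read as $\le 10{,}000$.
* **Redundancy reduction** (`identity_threshold`, default 0.90):
  a greedy incremental clusterer visits sequences longest-first (ties
  broken by id) and assigns each to the first cluster whose founder
  shares at least the threshold fraction of the shorter sequence's
  12-mers, else it founds a new cluster. This containment estimate is a
  deliberately simple, dependency-free identity proxy; it is
  deterministic, idempotent (founders were mutually below threshold, so
  re-reducing reproduces them) and conservative for near-duplicates.
  Note that k-mer containment decays quickly with divergence: at k = 12
  even 1% point mutations remove roughly $1-(1-0.01)^{12} \approx 11\%$
  of shared words, so 0.90 corresponds to substantially less than 10%
  sequence-level divergence.
* **Stratified split** (`test_fraction`, default 0.2): total validation
  size is $\lceil f N \rceil$ and per-class counts follow proportional
  allocation with largest-remainder rounding (remainder ties to the
  larger class). This rounding scheme reproduces published
  per-cell-line train/validation counts exactly (e.g. 2,552 → 511 =
  307 + 204; 703 → 141 = 118 + 23); membership is randomized by an
  explicit integer seed while sizes are seed-independent.

## Descriptor families

Two descriptor groups cover content and arrangement:

**Composition (123).** Dinucleotide composition; reverse-complement
pooled dinucleotides (16 → 10 classes); nucleotide repeat index;
entropy; distance distribution; and Type-I pseudo k-mer composition for
k = 2 and 3. Where only the family name and dimension are fixed by
convention, this package adopts: repeat index = longest homopolymer run
of each base divided by sequence length (a monotone repeat measure);
distance distribution = mean gap between consecutive occurrences of a
base, normalized by length, 0 for bases seen fewer than twice. Both are
isolated in single functions so alternative formulas can be swapped in
without touching dimensions or names. Pseudo-composition tier counts
are λ = 3 (k = 2, dimension 19) and λ = 1 (k = 3, dimension 65) with
weight w = 0.05, the standard choice in the pseudo-composition
literature.

**Correlation (1,100).** All families share one kernel: the profile of
a standardized physicochemical property along the sequence's
overlapping k-mers. With 12 properties and lags 1–2 the dimensions are
fixed: cross-covariance over ordered property pairs (12·11·2 = 264 for
trinucleotides), auto-cross correlation (12·12·2 = 288, both k),
per-property autocorrelation (12·2 = 24) under four schemes (plain
covariance, Moran, Geary, Moreau–Broto), and pseudo correlation in
parallel (Type-I) and serial (Type-II, one designated property, λ = 1)
form with dimensions 17 (k = 2) and 65 (k = 3). Zero-variance profiles
(homopolymer-rich inputs) define the centred schemes as 0 instead of
erroring, so every valid sequence featurizes. Descriptors are computed
on the given strand only; no strand canonicalization is applied.

**Property tables.** The bundled dinucleotide table holds 12 standard
helical/thermodynamic properties (base-step twist, tilt, roll, shift,
slide, rise; nearest-neighbour enthalpy, entropy and free energy;
melting temperature; stacking energy; hydrophilicity), standardized to
mean 0, sd 1 over the 16 dinucleotides at load. The trinucleotide table
is *derived*: each trinucleotide property is the mean of its two
constituent dinucleotide steps. This is a documented construction, not
a measured dataset; because every correlation descriptor standardizes
its inputs, results are invariant to affine rescaling of raw property
values, and users can substitute measured tables via
`load_property_table(k, path = ...)` (delimited text, rows = k-mers,
columns `p1..p12`). The p-index naming follows the bundled sidecar
(`dinucleotide_property_names.tsv`); any replacement table redefines
that mapping.

## Feature selection

`mrmr_rank()` is greedy forward mRMR: relevance is the one-way ANOVA
F statistic of a feature against the class, redundancy the mean
absolute Pearson correlation with already-selected features, and the
criterion their difference (quotient available via `variant`). A raw F
is unbounded and would swamp a correlation-scale redundancy term — an
exact duplicate of a strong feature would be re-picked immediately — so
the relevance entering the criterion is the bounded variance-explained
transform $\eta^2 = F(g-1)/(F(g-1) + n - g) \in [0,1]$, monotone in F
(the raw F is reported alongside). Exact ties break lexicographically
by descriptor name, making the ranking deterministic and prefix-stable.
The conventional evaluation grid for subset sizes is
`mrmr_k_grid()` = 10, 50, 100, 500, 1000, 1500, 2000.

## Evaluation harness

Metrics use the standard confusion-matrix definitions (positive class =
cytoplasm), with all 0/0 cases reported as 0 — this matches the
behaviour of degenerate all-negative classifiers on imbalanced
validation sets (sens 0, spec 1, prec 0, MCC 0). AUC is the rank-based
Mann–Whitney statistic with midrank ties. The decision threshold for
label metrics is 0.5 on the positive-class score.

Cross-validation is stratified five-fold with seeded fold assignment;
the reported CV performance is the arithmetic mean over folds.
Hold-out evaluation standardizes features by training means/sds (stored
in the model, so prediction is self-contained) and the best model per
cell line is the validation-AUC argmax, ties broken by MCC then
registry order. The registry backs each classifier family with the
field-standard R implementation; two deliberate exceptions are
AdaBoost.M1, implemented in-package over depth-1 `rpart` stumps (with a
perfect weak learner kept at a capped weight), and the two boosting
presets ("gradient boosting" = eta 0.1 / depth 3, "extreme gradient
boosting" = eta 0.3 / depth 6) that share the xgboost backend.
Gaussian generative models (naive Bayes, QDA) drop features that are
constant within a class before fitting.

## The synthetic benchmark

The generator emulates the statistical structure the method assumes
while staying fully self-contained. Sequences are drawn from
class-tilted first-order Markov chains: the cytoplasm class raises C/G
mononucleotide probability and boosts the CG transition, the nucleus
class raises T and boosts TG — so composition *and* correlation
families carry signal, mirroring the observed chemistry that
cytosine-rich k-mers associate with cytoplasmic and thymine-rich k-mers
with nuclear localization. CNRCI is
$\beta \cdot z(f_{CG} - f_{TG}) + \mathcal{N}(0, \sigma)$, with the sign
forced to the latent class whenever $|\mathrm{CNRCI}| > \sigma$.
Additional cell lines flip the CNRCI sign for a configurable fraction
of genes, emulating cross-cell-line variability.

Defaults are n = 1,000 sequences of 200–2,000 nt, β = 3, σ = 0.5,
mononucleotide tilts 0.15, cytoplasm proportion 0.4 (nucleus-majority,
as in real per-cell-line datasets), two cell lines with 10% sign flips,
seed 42. The length range keeps the default benchmark fast while the
full 200–10,000 nt range remains supported. These defaults give near
separability by construction: passing tests demonstrate that the
pipeline recovers a planted composition signal end to end, not that
real lncRNA localization is this predictable — real sequences carry
weaker, confounded signal, isoform ambiguity and expression noise that
the generator deliberately omits (no secondary structure, splicing or
expression model).

## Numerical choices and degenerate inputs

* All descriptor arithmetic is double precision; implementation and
  independent brute-force oracles agree to well below 1e-10 relative
  tolerance in the test suite.
* Too-short sequences fail with an error naming the descriptor family
  and its minimum length (the binding constraints are
  length > k + max_lag for correlation families and
  length ≥ k + λ + 1 for pseudo composition).
* Ambiguous bases: strict rejection by default; a `drop-ambiguous`
  policy removes them instead, configurable because conventions differ
  between sources.
* Every stochastic operation takes an explicit integer seed; identical
  seeds give identical folds, splits, simulations and reports, and each
  written report carries its config hash and seed.

## Problem sizes used in the test suite

The suite exercises the oracle comparisons on 100 random sequences of
50–2,000 nt, the signal-recovery property on the default n = 1,000
benchmark with an 80/20 split, and the pipeline tests on 100–300
simulated genes across one or two cell lines — sizes chosen so the full
method (including five-fold CV across the registry) runs comfortably on
one CPU while keeping every statistical property testable.

## Known limitations

* The bundled trinucleotide property table is derived from dinucleotide
  steps, not measured; conclusions that depend on specific trinucleotide
  chemistry should substitute a measured table.
* The greedy k-mer-containment clusterer is a stand-in for
  alignment-based redundancy removal; at 0.90 it is stricter than a 90%
  alignment identity.
* The serial pseudo-correlation family uses a single designated
  property (p1); the choice is conventional and configurable.
* No calibration of predicted scores is attempted; the 0.5 threshold is
  a convention, not an optimum.
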