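---
title: "Methods: cellulase screening and optimum-class prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cellulase screening and optimum-class prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`cellopt` couples two procedures that are useful together when mining
assembled metagenomes for cellulose-degrading enzymes:

* a **translated homology screen** that flags contigs carrying
  cellulase-like genes, and
* a **descriptor-based classifier** that assigns a cellulase amino-acid
  sequence to an optimum-temperature class (mesophilic < 50 °C,
  thermophilic [50, 75) °C, hyper-thermophilic ≥ 75 °C) and an optimum-pH
  class (acidic < 5, neutral [5, 8), alkaline ≥ 8).

The classifier's core assumption is that thermal and pH adaptation leave a
signal in sequence composition — e.g. thermostable proteins tend to be
enriched in the IVYWREL residues, acid-adapted ones shift their
charged-residue balance.  Everything downstream (descriptors, selection,
ensemble) is machinery for extracting that compositional signal from a
small labeled training set.

## Class thresholds

The published temperature and pH inequalities are strict on both sides,
which leaves the boundary values 50, 75, 5 and 8 unassigned.  We close the
lower bound of each upper class — [50, 75), [75, ∞), [5, 8), [8, 14] — so
`label_temperature()` and `label_ph()` are total functions.  This is a
convention, not a claim about the source data; fixture optima are generated
strictly inside class interiors so no test depends on it accidentally.

# Descriptors

`featurize()` concatenates, in fixed order: AAC (20), DPC (400), grouped
AAC/DPC over five physicochemical groups (5 + 25), CTD over seven
attributes × three groups (21 composition + 21 transition + 105
distribution), conjoint triads over the classic seven residue classes
(343), type-1 pseudo-AAC with standardized hydrophobicity, hydrophilicity
and side-chain-mass scales (20 + λ), and atom/bond composition (5 + 4) —
973 columns at the default λ = 4.  The original tool chain produced 6524
descriptors from the union of two feature generators after deduplication;
that inventory is not enumerable from the publication, so this package
defines its own documented default covering the same descriptor families.
Counts are the published ones where they exist (e.g. every composition
block sums to 1 per sequence, a tested invariant).

Numerical conventions worth knowing:

* **CTD distribution**: the q-quantile occurrence of a group with `count`
  occurrences is occurrence index `max(1, ceiling(q * count))`; positions
  are reported as `100 * position / length` (1-based).  Absent groups give
  0 across all five quantiles.
* **PAAC** requires `length > λ`; shorter sequences are rejected with an
  instruction to drop the block or lower λ, never silently padded.  Scales
  are standardized with the population (÷20) standard deviation, the
  classic convention.
* **Atom/bond block**: atoms come from the free amino-acid molecular
  formulas; bonds use the convention total bonds = atoms − 1 + rings,
  localized double bonds = backbone carboxyl plus side-chain C=O / C=N
  (D, E, N, Q, R), aromatic rings F/Y/H = 1, W = 2.  The published work
  only names "composition of atoms, bonds"; the lookup here is this
  package's documented choice.
* **Duplicate columns** are removed per training set (dataset-dependent,
  as in the source pipeline) and recorded in the matrix provenance; at
  prediction time vectors are projected onto the stored training columns.
* **Min–max scaling** maps training min/max to [0, 1]; columns constant in
  training map to 0 (a defined choice), and out-of-range test values are
  *not* clipped, so they may fall outside [0, 1].

# Selection, balancing, ensemble

Columns are scored by one-way ANOVA F against the class labels
(`F = (SSB/(g−1))/(SSW/(n−g))`, upper-tail p from `F(g−1, n−g)`), with the
degenerate contracts `SSB = 0 → F = 0, p = 1` and
`SSW = 0, SSB > 0 → F = ∞, p = 0` (detected with a relative tolerance of
`eps^0.5` on the sums of squares).  P-values are Benjamini–Hochberg
adjusted by an explicit step-up implementation; `select_k_best(K =
"auto")` keeps as many columns as are BH-significant at α = 0.05, floored
at 10 so a null fold never produces an empty model, ties in F broken by
column order.  The published K values (253 temperature, 93 pH) arose from
the same rule on the original data and are dataset-specific; they are
configuration values here, not targets.

SMOTE rebalances every class to the majority count: a minority row is
drawn uniformly, one of its k = 5 nearest same-class neighbours (Euclidean;
k shrinks to class size − 1) is drawn, and the synthetic row is the convex
combination `x + u(nn − x)`, `u ~ U(0, 1)`.  A single-member class is a
hard error — it cannot be interpolated and should not be trained on.
Balancing to exact parity is a choice; the source only states balance.

The ensemble fits three learners on identical (scaled, selected, resampled)
data with the published hyperparameters as defaults: MLP with two hidden
layers of 200 ReLU units trained full-batch with Adam (lr 1e-3, L2 1e-4,
≤ 500 epochs with early stopping on a stratified 10 % split, patience 25 —
the published epoch budget is unstated, so these are documented defaults,
not claimed as theirs); a 200-tree random forest with information-gain
splits, `floor(sqrt(p))` candidate features per node, grown to purity; an
RBF-kernel C-SVC (C = 1, γ = 1/(p·var), the "scale" convention) solved
exactly as a QP (quadprog, ridge 1e-8 on the kernel diagonal for
definiteness), one-vs-one with Platt sigmoid calibration on the training
decision values and probability coupling by pairwise averaging.  Soft
voting averages the three probability vectors with configurable weights
(default equal — the published "weighted" weights were never stated) and
takes the argmax, ties toward the lowest class index.  All three fits are
deterministic given a seed (the RF consumes R's RNG from C++).

# Evaluation

`repeated_cv()` repeats stratified six-fold cross-validation (default 100
iterations; tests use 5–10 for runtime).  *Stratified* deviates knowingly
from the published "randomly split into six equal subsamples": with a
seven-member minority class, unstratified splits can leave a class absent
from a training fold, making per-class recall undefined; an unstratified
mode remains available.  Every data-dependent state — duplicate-column
removal, scaler, selection (auto-K recomputed per fold), SMOTE — is fitted
on the training part of each fold only; the test suite enforces this by
intercepting the fit calls and checking the row sets.

Metrics: accuracy = trace/total, per-class recall `TP/(TP+FN)` and
precision `TP/(TP+FP)`, macro scores unweighted over classes, F1 the
harmonic mean.  The source's printed precision formula (`TN/(TN+FP)`) is
specificity, contradicting both its name and standard tooling; the
standard definition is implemented.  Classes never predicted get precision
0 (and F1 0).

# Screening

BLASTx is replaced by exact Smith–Waterman on the stop-split six-frame
peptides: slower but dependency-free and checkable against brute-force
oracles.  Gap convention: a length-L gap costs `open + (L−1)·extend`
(defaults 11/1); DP ties resolve to the first-encountered cell in
row-major order so reported spans are deterministic.  Bit scores use the
gapped BLOSUM62 Karlin–Altschul constants λ = 0.267, K = 0.041.  Scores
will not numerically equal NCBI BLASTx (no SEG masking or composition
adjustment); the 50-bit homology cut-off is preserved in spirit.  Contigs
shorter than 300 nt (the usual assembly minimum) are skipped, peptides
shorter than 20 aa are not aligned (noise floor; the source is silent),
and one best hit per contig is reported.

The cloning shortlist keeps hits with bit score ≥ 300 whose contig
coverage reaches the 75th percentile of the supplied coverages.  "Top 25 %
of the mapped reads" is ambiguous; we filter contigs by a coverage
quantile computed with the **upper nearest-rank** convention
`k = floor(q·n) + 1` (capped at n), under which coverages {10, 20, 30, 40}
give threshold 40 — i.e. the filter keeps strictly the top quarter,
consistent with the package's worked example and tests.

CD-Hit-style redundancy removal (`greedy_cluster`) sorts by descending
length and assigns each sequence to the first representative it matches at
≥ 0.9 identity, where identity = identical positions in the optimal global
alignment (match +1, mismatch 0, linear gap −1) divided by the shorter
length — CD-Hit's convention, implemented exactly rather than with word
filtering, which is affordable at desk scale.

# Synthetic data: what a green test establishes

The generator emulates exactly two things: (i) labeled protein sets whose
classes differ by multiplicative residue-composition biases — thermophilic
sequences weight IVYWREL by `s`, hyper-thermophilic by `s²`; acidic/alkaline
weight D,E / K,R by `s²` — with optima drawn uniformly from class
interiors; and (ii) contigs of uniform background DNA with
reverse-translated reference genes planted at random offsets, a configured
fraction on the reverse strand.  The default `s = 2` is fixed once so that
the default dataset realizes the strongly separable regime the acceptance
scenarios are defined on (at `s = 1` the same machinery yields the null);
it was raised from an initial 1.6, which produced an intermediate rather
than strongly separable signal.

Real data differ in every other respect: phylogenetic correlation between
sequences, domain structure, codon usage, uneven coverage, sequencing
error.  A green power test therefore establishes that the pipeline can
recover a compositional class signal without leaking test information —
not that it attains any particular accuracy on real cellulases.  The
published CV numbers (accuracy 0.75/0.71 for temperature/pH) depend on an
unpublished training corpus and cannot be reproduced here; the package
accordingly makes no claim about them.

# Known limitations

* Smith–Waterman screening is exact but O(mn) per pair; for millions of
  contigs a seeded heuristic (BLAST/DIAMOND) in front of it would be the
  practical choice.
* The SVM's Platt calibration is fitted on training decision values
  (no internal CV), which can be optimistic on tiny folds.
* The descriptor set is a documented 973-column default, not the original
  6524-column inventory; the block registry is extensible.
* Single-member classes, sequences shorter than λ + 1, and contigs under
  300 nt are rejected or skipped by design rather than imputed.
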