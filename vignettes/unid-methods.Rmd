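---
title: "uniD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{uniD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
open design choices were made the way they were. The companion README shows
a worked run; the test suite and `scripts/acceptance.R` compute every
empirical number referred to here.

## The data model

Infinium methylation arrays report, per CpG probe and sample, a beta value
β ∈ [0,1]: the fraction of methylated signal. Beta values are bounded and
heteroscedastic near 0 and 1, so all penalized modeling in this package
runs on M-values, M = log2((β + ε)/(1 − β + ε)), which are unbounded and
closer to homoscedastic. The offset ε (default 1e-6) exists only to keep
the transform finite on clamped betas; at β = 0.5 it changes M by nothing
and in the mid-range by well under 1e-5. The inverse transform uses the
ε = 0 convention, so a round trip on finite M-values is exact to 1e-12.

Matrices are stored probes-in-rows, samples-in-columns (the heatmap
convention for this data type); readers accept a `transpose` flag. The
missing-token set for delimited input is exactly {"NA", "NaN", ""},
case-sensitive. Whether beta or M values feed the subtype model is a
genuinely open choice — only the binary branch is explicitly M-valued —
so the default is M-values everywhere, with a `--scale beta` switch on the
CLI and the equivalent argument in code.

## Quality control

The cascade runs in a fixed order: static manifest filters → cell masking
→ probe-missingness drop → sample-missingness drop → KNN imputation.
Ordering matters and is deliberate: masking precedes the missingness
accounting, so a cell failed for beadcount ≤ 3 or detection p > 0.05
counts toward the 10% probe and 5% sample thresholds. Both drop rules use
strict inequality ("more than 10%"), so a probe missing exactly 10% of
samples survives; the tests pin this boundary.

KNN imputation is the one QC step whose reference leaves real freedom:

* neighbourhood over **probe rows**, not samples — the established
  convention for omics matrices, where thousands of correlated features
  support a missing cell far better than tens of samples;
* k = 10, unweighted mean, and only neighbours observed in the target
  sample are eligible (fewer than k eligible → use them all);
* distance between probe rows is Euclidean over mutually observed samples,
  rescaled by sqrt(total/observed) so that probes with many shared
  coordinates are not spuriously close; probe pairs with no shared samples
  are at infinite distance;
* ties in distance break by probe index, making the result exactly
  reproducible — the test suite holds the implementation equal to a
  brute-force all-pairs oracle on instances up to 20 × 20, with zero
  tolerance.

## Binary-alteration classifiers

Samples are apportioned 60/20/20 into training/development/test within each
class (cumulative-rounding rule, seeded shuffle). Stability selection then
runs entirely inside the training set:

1. For each mixing weight α ∈ {0.1, …, 1.0}: draw 200 random penalties λ
   log-uniformly from [λ_max·1e-4, λ_max], where λ_max is the smallest
   penalty that zeroes every coefficient at that α (the standard
   regularization-path range; the reference for this step states only that
   the values are "randomly generated"). The grid seed is keyed to the α
   *value*, so results are invariant to the order in which alphas are
   listed.
2. Score the grid by stratified 5-fold CV accuracy and fix the winning λ;
   accuracy ties break toward the larger λ (sparser model). Whether λ is
   chosen once on whole-training CV (done here) or re-chosen inside each
   fold is underdetermined; the former matches the step-wise narrative of
   the workflow and makes the per-fold refits comparable.
3. Refit on each fold's training portion at that λ and record, per probe,
   the non-zero indicator (|coef| > 1e-10, absorbing coordinate-descent
   noise). The per-α selection percentage is the fraction of folds
   selecting the probe; the overall percentage is the mean over alphas.
   With a common fold count this equals the pooled fraction over all 50
   fits, so the `pooled` flag is a documented synonym rather than a second
   code path.

Probes rank by overall percentage descending, ties by probe id — fully
deterministic. Candidate probe sets (top 100, 200, …) are re-tuned on the
printed 10 × 101 grid (α 0.1–1 step 0.1, λ 0–5 step 0.05) by CV accuracy,
the development set picks among candidate sizes (ties → fewer probes), and
the test set is touched exactly once.

Numerical choices worth knowing:

* **Standardization.** Features are standardized to mean 0, sd 1 on the
  training samples before any penalized fit; penalties are scale-sensitive
  and the reference is silent on scaling. The parameters are stored in the
  model, so prediction is self-contained. Zero-variance probes get scale 1
  and therefore coefficient 0.
* **λ = 0.** The printed refit grid includes 0 (an unpenalized fit); a tiny
  ridge floor of 1e-8 keeps the optimizer bounded on separable data. On
  chance-separable null cohorts even that can fail to converge at the
  path's end, in which case the smallest converged λ on the path stands in
  for the affected grid points.
* **Decision threshold** is probability 0.5 (configurable); "positive"
  means mutant/co-deleted.
* **AUC** is the Mann–Whitney probability with 0.5 credit for ties,
  computed from midranks and tested against an exhaustive pairwise oracle.
* **Paper mode** pins the published final configurations (100/1000/500/100
  probes; α = 0; λ = 1 for IDH/TERTp/ATRX, λ = 0.1 for the co-deletion);
  auto mode re-derives hyperparameters by the stated search.

## Expression-subtype engine

Reference probabilities come from per-subtype empirical p-values:
Prob_s = (1 − p_s) / Σ_t (1 − p_t). If every p-value is 1 the denominator
vanishes; the package returns the uniform distribution — no evidence
favours any subtype, and a hard error would make batch processing fragile
for a well-defined limiting case.

Probe ranking uses three entropy metrics on equal-frequency-binned values
(10 bins by default): information gain IG = H(Y) − H(Y|X) in bits, gain
ratio IG/H(X), and symmetrical uncertainty 2·IG/(H(X)+H(Y)). Equal-
frequency binning was chosen over equal-width because beta distributions
are strongly bimodal and skewed; it also makes all three metrics invariant
under monotone transforms of the probe values (so beta vs M is immaterial
here). Constant probes have H(X) = 0; gain ratio and SU are defined as 0
for them rather than NaN. Probes get a per-metric rank (1 = highest, ties
take the minimum rank), the three ranks are summed, and the final order is
ascending rank sum with probe-id tie-break.

The evaluation harness accepts any learner exposing `fit(X, y)` and
`predictProb(model, X)`; five ship (random forest, ridge multinomial
logistic, k-NN, naive Bayes, linear discriminant) and the remaining
algorithms of the 21-learner reference design are the interface's job, not
reimplementation targets. Each (learner, probe subset, repeat) cell runs
stratified 5-fold CV with every sample scored by the fold holding it out;
metrics are the misclassification rate and the mean per-sample sum of
squared probability deviations against the reference probabilities. A
failing learner leaves NA cells and the run continues. The final model is
a 500-tree random forest with √p features per split, seeded, trained on
training + development samples over the full retained probe set (the
harness shows deviations shrink with probe count while accuracy is flat,
which is why the released configuration keeps all ranked probes).

## Platform harmonization harness

Consensus NMF: multiplicative-update Frobenius factorization, 200
iterations or 1e-6 relative objective change, 30 restarts by default from
seeded random initializations; per run each sample joins the basis
component with the largest (norm-weighted) coefficient; the consensus
matrix accumulates co-clustering frequencies; the final membership is an
average-linkage hierarchical cut of 1 − consensus. Beta values are already
non-negative, which is what makes NMF natural here.

The three-step admixture evaluation mirrors the reference design: cluster
a single-platform dataset on its top-MAD probes for the gold standard
(computed at two probe counts, default 1000 and 2000, and required to
agree before use); build admixtures in which each individual is
contributed by exactly one platform at fractions 25/50/75%; cluster each
admixture with and without a batch-adjustment callable and report
membership concordance (maximum agreement over label permutations —
exhaustive, k ≤ 7). BMIQ/SWAN/PBC are deliberately not reimplemented: the
harness takes any `function(BetaMatrix, platform)` and ships a transparent
per-probe moment-matching adjustment as the built-in baseline. The
gold-standard cluster count k is an explicit argument, never inferred
silently.

## Signature analytics

The "proportional test" for genomic-context enrichment is realized twice:
an exact binomial two-sided test (point-probability rule) as the default
and testing oracle, and the chi-square one-sample proportion test with
continuity correction as the classical flavour. Normalized proportions are
(signature/background per category), renormalized to sum to 1 across
categories. Multi-annotation probes count their first-listed category and
first-listed gene only. The nine-group molecular grouping is configuration,
not hard-coded biology: by default realized (IDH, 1p/19q, ATRX, TERTp)
tuples are enumerated and labelled Grp1..K, and an editable tuple-to-group
table (an example ships in `inst/extdata/group_config_example.tsv`) pins
fixed definitions.

## Synthetic cohorts: what they emulate, and what they do not

Generators are first-class, seeded, and return a truth object sufficient
to score any recovery metric.

* Baselines are a 50/50 mixture of Beta(2,8) and Beta(8,2) probe means —
  bimodal and methylation-like. Planted differential probes shift their
  mean by Δβ **on the beta scale** (Δβ is a beta-scale quantity; a logit-
  scale shift of equal nominal size would compress to far less than Δβ at
  the extremes). Informative baselines are kept in a central band so the
  planted gap survives clamping to (0.001, 0.999).
* Default binary study conditions: n = 300 samples, 2000 probes, 50
  informative, Δβ = 0.3, per-cell Gaussian noise sd 0.05, 1% detection
  artifacts (failing cells draw detection p ~ U(0.05, 1), passing cells
  ~ U(0, 0.01)), 0.2% low-beadcount cells.
* Subtype cohorts (default 150 × 600, 30 informative probes per class)
  draw the true class's empirical p-value from U(0, 0.05) and the wrong
  classes' from U(0.6, 1). The latter choice is deliberate: permutation
  tests on a clearly separable cohort confidently reject the wrong
  subtypes, and it is what makes the reference probabilities peaked enough
  that a well-calibrated classifier can reach a small sum of squared
  deviations. With wrong-class p-values uniform on (0,1) the reference
  probabilities centre near 0.5 and even a perfect classifier is left with
  an expected deviation of ≈ 0.375 — a floor set by the generator, not by
  any model.
* The platform-bias simulator compresses type-II probes on platform B:
  β' = 0.5 + c·(β − 0.5), c ∈ (0,1], plus independent noise — mirroring
  the reduced dynamic range of Infinium II chemistry. The harness tests
  use c = 0.25 over 72% of probes: a worst-case divergence chosen so the
  platform signal demonstrably dominates a Δβ = 0.4 biological signal at
  n = 90, which is the phenomenon the harness exists to expose.

What the generators do **not** emulate: per-probe marginal distributions of
real arrays, spatial/chip batch structure, correlated probe blocks within
CpG islands, copy-number-driven intensity shifts, or tumor purity mixtures.
Passing the recovery tests therefore demonstrates correctness of the
machinery under the stated statistical structure, not clinical performance;
the published cohort-level accuracies live on access-restricted data and
are out of scope by design.

## Problem sizes and determinism

The test suite and acceptance script run, per seed, a full binary pipeline
at the default 300 × 2000 conditions (about 1–2 minutes each on one CPU),
a 10-seed null-cohort leakage guard at 160 × 400 with a reduced candidate
size, the 150 × 600 subtype path, and the 90-sample harness — sizes chosen
as the package's study conditions at desk scale. Every stochastic step
(splits, folds, lambda grids, forest, NMF restarts, generators) derives
from one integer seed; CLI reruns with the same seed and config are
byte-identical, which the tests assert via file digests.

## Known limitations

* IDAT parsing, detection-p computation from control probes, and raw-
  intensity normalization (BMIQ/SWAN/PBC internals) are out of scope; the
  package starts from beta matrices and optional detection/beadcount
  matrices.
* The exhaustive permutation matching in membership concordance is
  factorial in k and guarded at k ≤ 7.
* `evaluateLearners` at the full reference scale (21 learners × 10 subsets
  × 100 repeats) is a long-running batch job; the shipped defaults are
  sized for interactive use and the tests run reduced repeats.
* The elastic-net path solver's unpenalized limit is approximated by a
  1e-8 ridge floor; truly unpenalized fits on separable data are not a
  well-posed target.
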