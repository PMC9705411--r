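---
title: "Methylation-array class discovery and calibrated classification with methclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-array class discovery and calibrated classification with methclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methclass)
```

# The problem

Genome-wide DNA methylation profiles measured on Illumina 450k/EPIC arrays
are a robust molecular fingerprint of tumor type: epigenetic classes often
resolve entities that look identical under the microscope. `methclass`
implements a complete workflow for building such a classifier from
beta-value matrices (per-CpG methylation fractions in [0, 1], probes ×
samples):

1. **Quality filtering** — remove sex-chromosomal, SNP-associated and
   cross-reactive probes; drop samples whose fraction of failed
   detection-p calls exceeds 5%; merge 450k and EPIC data on their shared
   probe set.
2. **Unsupervised class discovery** — rank CpGs by variance, keep the top
   20,000, embed samples in 2-D with t-SNE (perplexity 20, 4000
   iterations), cluster the embedding with DBSCAN (minPts 6), exclude
   noise points, and quantify robustness with a downsampling stability
   statistic.
3. **Supervised classification with an Unknown class** — train SVM or
   random-forest models on the discovered classes plus an explicit outlier
   class drawn from a diverse pool of out-of-scope tumors, selecting
   hyperparameters by class-balanced multinomial cross-entropy in
   stratified 5-fold cross-validation with per-fold feature selection.
4. **Calibration** — map raw scores to probabilities with ridge-penalized
   multinomial logistic regression fitted on out-of-fold scores.
5. **Evaluation** — outlier-detection sensitivity/specificity after
   collapsing all in-scope predictions, per-category specificity,
   conditional accuracy on classifiable in-scope samples, and ROC/AUC of
   the binary outlier score.

A seeded synthetic-cohort simulator generates realistic multi-class beta
matrices so that every stage is testable without any external download.

# The models and their assumptions

## Class discovery

Discovery operates on the `k = 20000` most variant CpGs (sample variance
with denominator $n-1$, computed on beta values directly; ties broken by
input probe order so results are deterministic). The 2-D embedding is
exact t-SNE: per-sample Gaussian bandwidths are calibrated by binary
search to a target perplexity of 20, the symmetrized affinities are
optimized for 4000 gradient-descent iterations (early exaggeration 12 for
250 iterations, learning rate 200, momentum 0.5 → 0.8) — the conventional
parameterization for methylation cohorts of a few hundred samples. The
implementation is exact ($O(n^2)$ per iteration) rather than
Barnes–Hut-approximate, which at cohort scale (hundreds to a few thousand
samples) is both affordable and free of approximation artifacts.

DBSCAN then labels the embedding with canonical core/border/noise
semantics: a sample is a core point when at least `min_pts = 6` samples
(itself included) lie within `eps`; clusters grow by core-point
expansion; unreachable samples are `NOISE` and are excluded from the
reference set. The test suite pins these semantics to an independent
brute-force implementation on random instances.

**Choosing eps.** The radius is the one genuinely open parameter. The
classical recipe — the maximum-curvature knee of the sorted
minPts-nearest-neighbor distance curve — turned out to be systematically
too tight on t-SNE coordinates: the curve is smooth, the knee lands in
the middle of the within-cluster distance range, and genuine classes
fragment. On t-SNE output the scales are strongly separated
(within-cluster single-link gaps ≈ 1–1.5 units, between-cluster distances
tens of units), so the default `eps = "auto"` instead uses the Tukey
far-out fence of the minPts-NN distances, `Q3 + 3·IQR`, capped at the
curve maximum: samples whose neighborhood is wider than the fence are
density outliers, everything below stays core. The knee remains available
(`estimate_eps(method = "knee")`), and `eps` is always overridable.

## Downsampling stability

`stability_downsample()` draws a fraction (default 0.8) of the samples
without replacement, re-embeds them, and records the Pearson correlation
between the concatenated (x, y) reference coordinates and the
re-embedded coordinates of the retained samples; default 300 iterations.
Raw t-SNE is rotation- and sign-unidentifiable, so a coordinate
correlation across independent runs would be meaningless. Re-embeddings
are therefore warm-started at the reference coordinates of the retained
samples, which fixes the frame; it also means a converged reference
embedding re-converges in a few hundred iterations, so the per-iteration
cost stays low. The correlation is computed on the concatenated axes (one
r per iteration) rather than per-axis-and-averaged; with a shared frame
the two conventions differ negligibly.

## Class-balanced grid search

"Class balance" is implemented as inverse-class-frequency weights
normalized to mean one: with $N$ samples in $K$ classes, class $c$ of
size $n_c$ receives $w_c = N/(K n_c)$, and

$$L = \frac{\sum_i w_{y_i}\,(-\log \max(p_{i,y_i}, \varepsilon))}{\sum_i w_{y_i}},
\qquad \varepsilon = 10^{-15},$$

which reduces to the unweighted mean cross-entropy for equal class sizes
and to $\log K$ for uniform predictions. The $\varepsilon$ floor keeps
the loss finite when a model assigns a true class probability of zero.

The default grids follow standard practice for methylation classifiers:
SVM with linear and RBF kernels, cost $C = 2^0,\dots,2^5$ and (RBF only)
$\gamma = 2^{-3},\dots,2^3 / 20000$; random forest with
$\mathrm{ntree} \in \{500, 1000\}$ and
$\mathrm{mtry} = \mathrm{round}(2^{-5},\dots,2^5 \cdot \sqrt{20000})$,
clipped to $[1, p]$ at fit time. Enumeration order (kernel → cost →
gamma; ntree → mtry) is the documented argmin tie-break. SVM per-class
scores are one-vs-one decision values converted via Platt scaling and
pairwise coupling (rows sum to 1 within coupling tolerance ~1e-6); RF
scores are tree-vote fractions and sum to 1 exactly.

Cross-validation is stratified by exact class label with seeded,
order-invariant fold construction (samples are id-sorted within class
before the permutation, so shuffling the input cannot change folds).
Feature selection runs inside each fold on the training 4/5 only; the
held-out fold is projected onto that feature list. The suite verifies
this with a poisoning check: a probe made extreme-variance by a single
held-out sample can never enter that fold's feature set.

## Calibration

Raw scores are calibrated with ridge-penalized multinomial logistic
regression fitted (via `glmnet`) on the winner's *out-of-fold* scores —
resubstitution scores would make the calibration overconfident. The
symmetric multinomial parameterization (one penalized coefficient vector
per class, no reference class) makes calibration equivariant under class
permutation. The penalty path is the conventional 100-value auto-scaled
descending grid; $\lambda$ is chosen by minimum mean cross-validated
multinomial deviance over 10 internal folds. Prediction applies
`softmax(raw %*% B + b)` using the extracted coefficients, so calibrated
rows sum to one within 1e-9 by construction, and the final call is the
argmax (exact ties go to the first class in canonical order — in-scope
classes alphabetically, `Unknown` always last — with a warning).

## The Unknown class and evaluation

Open-set recognition is handled supervised: a fraction (default 5%) of
every category of a diverse out-of-scope pool is drawn (at least one per
non-empty category, nearest-integer rounding) and trained as a single
`Unknown` class. At evaluation time all in-scope predictions are
collapsed into one outcome: *sensitivity* is the fraction of truly
in-scope samples given any in-scope class, *specificity* the fraction of
out-of-scope samples sent to `Unknown`; both are reported rounded
half-up to 3 decimals, as are the per-category specificities and the
conditional accuracy (accuracy over in-scope samples the classifier was
willing to classify). The ROC for the binary outlier problem uses the
score $1 - P(\mathrm{Unknown})$ — the only monotone function of the
calibrated output that treats all in-scope classes symmetrically — with
a threshold sweep over unique scores and trapezoid integration, which
equals the Mann–Whitney concordance probability with ties counted ½
(pinned to a pair-counting oracle and to `pROC` in the tests).

# The simulator

`sim_config()` / `simulate_cohort()` / `simulate_split()` generate
synthetic studies with a known answer:

* **Background**: each probe's baseline mean is drawn from an equal
  mixture of Beta(2, 10) (unmethylated) and Beta(10, 2) (methylated)
  archetypes — the classic bimodal beta-value landscape.
* **Classes**: each class owns a disjoint set of informative CpGs
  (default 300) whose mean is shifted on the logit scale toward the
  farther boundary; the shift is calibrated so a background mean of 0.5
  moves by `effect` (default 0.45), and the logistic squashing keeps all
  means inside (0, 1) without clipping.
* **Noise**: observed betas are Beta($\mu\nu$, $(1-\mu)\nu$) draws around
  the mean with concentration $\nu$ = 50, reproducing the
  mean-dependent variance of array data.
* **Purity**: each sample's tumor fraction is uniform on
  `purity_range` and mixes the class profile with a shared normal
  profile before sampling. The default range is [0.6, 1]: curated
  diagnostic reference cohorts have predominantly high tumor content,
  and at dilutions toward 0.3 the diluted samples genuinely migrate away
  from their class core (they are mostly normal tissue), so classes
  bifurcate in any faithful embedding — that regime is available through
  the knob but is not the default study condition.
* **Outlier categories**: out-of-scope classes carry both
  category-specific informative CpGs and a *shared out-of-scope
  signature* (default 300 CpGs shifted in every outlier class). The
  shared component models the tissue-compartment signal that
  out-of-scope tumors have in common; it is what allows an Unknown class
  trained on a few categories to reject categories never seen in
  training. With fully disjoint outlier sets, an unseen category is
  geometrically unrelated to the Unknown pool and no classifier could
  flag it.
* **Platforms and manifest**: a configurable share of probes is flagged
  sex-chromosomal/SNP/cross-reactive (never informative, so filtering
  preserves planted structure), and samples can be tagged EPIC with a
  probe-subset mask to exercise the merge path.

`simulate_split()` partitions one probe-world into a reference cohort,
an in-scope test set, an outlier pool of "seen" categories, and an
outlier test set in which `n_unseen_outlier` categories appear
exclusively — mirroring the situation where most exact diagnoses in a
large test cohort were never part of classifier training.

**What the simulator does not emulate**: genome-wide correlation
structure between CpGs, copy-number-induced beta shifts, batch effects,
and CpG-island hypermethylator phenotypes. Passing the synthetic
recovery suite therefore demonstrates that the pipeline's machinery is
correct and leak-free, not that any particular accuracy will transfer to
real cohorts.

# Numerical and design choices

* Beta matrices are validated on load: any value outside [0, 1] is an
  error, never a silent clip. The QC boundary is a strict inequality
  (remove only when the failing fraction *exceeds* 5%).
* Probe/sample order is preserved by filtering and projection, making
  variance tie-breaks and all downstream output deterministic.
* All stochastic operations take explicit seeds (embedding default 42)
  and are reproducible to the byte in exported TSVs.
* t-SNE enforces `n_samples > 3 × perplexity`; the stability loop lowers
  the perplexity automatically when a subsample would violate it.
* Degenerate inputs error early with specific messages: single-sample
  variance, empty probe intersection on merge, missing probes at
  prediction (named), a class absent from calibration labels, all-Unknown
  predictions in conditional accuracy.
* The classifier archive is a documented directory bundle (feature list
  TSV, calibration coefficients TSV, class order + hyperparameters +
  schema version in JSON, fitted model object); `load_classifier()`
  refuses archives with a newer schema number.

# Problem sizes used by the tests and the acceptance script

The synthetic acceptance study uses the default `sim_config()`: 5 classes
× 40 reference samples on a 30,000-probe array, 10 in-scope test samples
per class, 4 outlier categories of 100 samples (2 unseen), 5% Unknown
draw, effect 0.45. Discovery runs on the full top-20,000 feature set with
t-SNE at 1500 iterations (the embedding is converged at this scale;
the 4000-iteration default is kept for larger cohorts), the stability
statistic uses 50 downsampling iterations with 250-iteration
warm-started re-embeddings, and the grid is a compact SVM grid (linear
and RBF; C ∈ {1, 32}; γ = 2⁰/20000) — large enough to make the selection
non-trivial, small enough that the whole study runs in a few minutes on
one CPU. Unit fixtures use smaller arrays (hundreds to a few thousand
probes) with proportionally scaled informative sets.

# Known limitations

* Exact t-SNE scales quadratically; beyond roughly 5,000 samples a
  Barnes–Hut or interpolation-based implementation would be preferable.
* The discovered class count is sensitive to perplexity, iteration
  count and eps in ways no automatic rule fully removes; the stability
  statistic and the overridable `eps` are the intended diagnostics.
* The Unknown-class mechanism requires the outlier pool to share signal
  with future out-of-scope samples; it cannot reject samples unrelated
  to anything seen in training with any guarantee.
* Calibration is global (one multinomial map); per-class isotonic or
  temperature alternatives are out of scope.
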