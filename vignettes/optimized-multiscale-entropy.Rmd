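---
title: "Optimized multiscale entropy for two-group regional time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimized multiscale entropy for two-group regional time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

entroscan analyzes cohorts of regional physiological time series — the
motivating case is resting-state fMRI BOLD signals averaged within the 90
regions of the AAL atlas — in which each subject carries a binary label
(0 = poor, 1 = excellent, e.g. two cognitive-performance groups). The
question it answers is: *at which entropy parameters do the two groups
differ most, in which regions, and how well do those regional entropies
classify subjects?*

```{r, eval = FALSE}
library(entroscan)
cohort <- generate_cohort(n0 = 43, n1 = 55, seed = 17)
run <- run_pipeline(cohort, seed = 17)
glance(run)
```

## The model

### Sample entropy and coarse-graining

For a series $x_1, \dots, x_N$, coarse-graining at scale factor $\tau$
replaces non-overlapping blocks of $\tau$ consecutive points by their mean,

$$y_j^{(\tau)} = \frac{1}{\tau} \sum_{i=(j-1)\tau+1}^{j\tau} x_i,
\qquad 1 \le j \le \lfloor N/\tau \rfloor,$$

discarding the trailing remainder. Sample entropy of the coarse series with
embedding dimension $m$ and similarity factor (tolerance) $r$ is

$$\mathrm{SampEn}(m, r) = -\ln \frac{C^{m+1}(r)}{C^m(r)},$$

the negative log conditional probability that two templates of $m$
consecutive points that match (Chebyshev distance strictly below $r$,
self-matches excluded) still match when extended by one point. Low values
mean a regular, predictable signal; the "complexity loss" hypothesis is
that poorer physiological status shows lower entropy. The multiscale
entropy (MSE) curve is SampEn evaluated at $\tau = 1, 2, \dots$.

Counting conventions matter for exactness, so they are fixed package-wide
and shared with the brute-force test oracle:

* templates run over $i = 1 .. L-m$, so that every $m$-template extends to
  an $(m{+}1)$-template and the ratio is a proper conditional probability
  (the standard Richman–Moorman convention; published presentations of the
  estimator differ in whether denominators use $L-m$ or $L-m+1$, and this
  choice resolves that ambiguity);
* matches are strict ($d < r$) and self-matches excluded;
* a zero match count at either dimension makes the estimate *undefined*:
  the value is `NA` with a `defined` flag, never $\pm\infty$, and
  downstream statistics exclude and count such subjects.

### r in SD units, normalized once

Each regional series is z-scored once at scale 1 (population SD) and never
re-normalized per scale. $r$ is then an absolute threshold in units of the
original signal's SD. This is the dominant MSE convention: coarse-graining
genuinely removes variance from white-noise-like signals, and keeping the
scale-1 normalization lets entropy fall with $\tau$ accordingly, which is
exactly the cross-scale structure the method exploits. Consequences: the
entropy is invariant under affine rescaling of the raw signal (tested),
and a constant series is exactly 0 at every scale.

Series-length guidance: SampEn needs roughly $10^m$–$20^m$ points. With
175 time points the usable embedding dimensions are $m \in \{1, 2\}$ and
scale factors up to $\tau = 6$ (coarse length 29). When a coarse series
falls below $10m$ points the package warns but proceeds; the warning is
captured in the pipeline's run record.

### Parameter optimization

The parameter grids default to $m \in \{1,2\}$, $r = 0.05$–$0.60$ in steps
of $0.05$, $\tau = 1$–$6$: 12,960 cells over 90 regions. Per cell the two
groups are compared by a Welch two-sample $t$-test (group sizes here are
unbalanced and variance equality unverified; a pooled-variance flag
exists) and by the ROC/AUC with group 1 (excellent) as the positive class
and higher entropy scoring toward it. The AUC equals the tie-corrected
Mann–Whitney statistic $U/(n_0 n_1)$ and is *not* folded: values below
0.5 are reported as-is and labeled "below-chance". P-values are
uncorrected across regions by default (an optional Benjamini–Hochberg
flag exists), matching how such grids are usually screened.

Selection is sequential, mirroring how the quantities are nested:

1. **m** — the dimension with the larger mean count of significant regions
   ($p < 0.05$) over all $(r, \tau)$ cells; ties go to the smaller $m$.
2. **robust r band** — the $r$ values with at least `min_regions`
   (default 1) significant regions at *every* scale factor; if empty, the
   single best worst-case $r$ with a warning.
3. **$\tau$, then r** — each cell is scored by the mean AUC over its
   significant regions; $\tau^\*$ maximizes the best in-band score, then
   $r^\*$ maximizes within the band at $\tau^\*$. Ties resolve to the
   smaller $\tau$ and to the $r$ nearest the band midpoint. Scoring by
   the mean AUC over significant regions formalizes "pick the cell where
   the sensitive regions discriminate best" without privileging a single
   exemplar region, which is the subjectivity the optimization is meant
   to remove; when one region dominates, it reduces to reading that
   region's AUC table. A `method = "joint"` argmax over all cells is
   available as a sensitivity check.

The whole optimization is a pure function of (cohort, grids, alpha); the
selection trace (count tables, band, score surface) is stored so every
choice can be replayed.

**Biomarkers and features.** At the selected $(m, r, \tau)$, regions with
$p < 0.05$ form the biomarker set, sorted by p-value. The feature matrix
is one row per subject, one column per biomarker region, entries the
subject's entropy at the optimum; subjects with any undefined feature are
dropped and listed.

### The PNN classifier

The probabilistic neural network is a Parzen-window Bayes classifier with
four conceptual layers and no iterative training: the pattern layer holds
the training exemplars verbatim, one Gaussian kernel
$\exp(-\lVert x - w_k \rVert^2 / 2\sigma^2)$ per exemplar; the summation
layer averages kernels per class; the decision layer takes the argmax,
with an exact tie resolving deterministically to class 0.

Choices where the method description is silent:

* **class priors** — kernel sums are normalized by class size (uniform
  priors), because the 43/55 imbalance reflects sampling, not prevalence;
  `prior = "proportional"` switches to prevalence weighting.
* **feature standardization** — columns are z-scored with training-fold
  statistics only (one $\sigma$ must be meaningful across features, and
  test folds must not leak into the scaling).
* **numerics** — kernels are evaluated after subtracting the smallest
  squared distance; the shift cancels in the posterior normalization but
  keeps the $\sigma \to 0^+$ limit equal to nearest-exemplar
  classification instead of a 0/0 tie. Both limits ($\sigma \to 0$:
  nearest exemplar; $\sigma \to \infty$: scores converge) are tested
  numerically.

The smoothing factor is tuned over $0.1$–$2$ in steps of $0.1$ by
stratified cross-validated accuracy on the training data (ties to the
smaller $\sigma$). Evaluation offers both a stratified holdout split
(e.g. 9 of 43 poor and 11 of 55 excellent held out) and stratified,
shuffled N-fold cross-validation (default $N = 10$); folds are stratified
because small unbalanced samples make unstratified folds degenerate.
With `sigma = NULL`, cross-validation re-tunes $\sigma$ inside each
training fold so the held-out fold never influences tuning. All
randomness flows through one explicit seed recorded in every report.

## The synthetic-cohort generator

`generate_cohort()` emulates the *output* of an rfMRI preprocessing
pipeline: two groups of region-by-time matrices in which a chosen subset
of regions differs in temporal regularity. Each regional series is a
stationary AR(1) process $x_t = \phi x_{t-1} + \varepsilon_t$ with 500
burn-in samples discarded. Background regions use $\phi = 0.2$ everywhere
(weak autocorrelation, plausible for band-passed BOLD); in the nine
planted regions of group 0 the coefficient rises by $\Delta\phi = 0.5$,
making the signal more regular and its sample entropy lower — complexity
loss in the poorer group. Defaults mirror the study layout: 43 + 55
subjects, 90 AAL-labeled regions (the planted nine sit at the AAL indices
of the default-mode-network-adjacent biomarkers a cognitive-aging study
would flag), 175 time points.

AR(1) was chosen over fractional Gaussian noise as the complexity knob:
one parameter, closed-form autocorrelation (validated in tests against
$3/\sqrt{T}$ at $T = 10^4$), and a cheap independent oracle (long-run
Monte-Carlo entropy of the same process). What the generator does *not*
emulate: hemodynamic response shape, spatial correlation between regions,
scanner noise spectra, motion artifacts. Passing tests therefore show the
statistical machinery is correct and well calibrated — not that any
particular empirical effect in real BOLD data will reproduce.

## Numerical and computational choices

* The match counting is compiled (Rcpp). Two exact algorithms return
  identical counts: all-pairs enumeration with every tolerance of the $r$
  grid binned in one pass (short series; any $m$), and, for $m = 1$ on
  long series, an $O(n \log n)$ sweep (series sorted by value, two-pointer
  window for $|y_i - y_j| < r$, Fenwick tree over successor-value ranks to
  count extensions). The sweep makes the $10^5$-point white-noise
  validation run in under a second; agreement of the two paths is itself
  a test.
* Grid statistics are vectorized Welch formulas, asserted equal to
  `stats::t.test(var.equal = FALSE)` in tests; the AUC is the rank-based
  tie-corrected Mann–Whitney form, asserted equal to exhaustive pair
  counting and to pROC.
* Reports round-trip losslessly: doubles are written with 17 significant
  digits and read back with base R's correctly rounded parser, so every
  numeric field survives write/read bit-identically.
* Degenerate inputs: zero-variance series z-score to all zeros (flagged)
  and give entropy exactly 0; cells whose entropies are all undefined are
  recorded as excluded, never silently dropped; an empty biomarker set is
  an error carrying a table of nearest misses.

## Problem sizes used in validation

The test suite validates at the study's own scale where the property
demands it, and smaller where it does not: oracle equivalence on 200
random series up to length 60 across the full $(m, r, \tau)$ box; the
analytic white-noise limit $-\ln\,\mathrm{erf}(r/2)$ at $10^5$ points
(tolerance 0.02); null calibration by 6 label permutations of a 60-subject,
90-region cohort (~39,000 grid cells; significance rate $0.05 \pm 0.02$,
AUC centered on 0.5); and parameter/biomarker recovery on 20 seeded
planted cohorts of 30 + 30 subjects, 90 regions and 175 time points, full
default grids. `scripts/acceptance.R` re-runs the complete pipeline on a
fresh synthetic cohort in the 43/55 layout and writes the selected
parameters, recovery counts and classification accuracies as JSON.

## Known limitations

* The optimization searches $m \le 2$ only; longer series would justify
  more, but 175 points do not.
* Uncorrected per-region p-values replicate common screening practice;
  with 90 regions expect a handful of false-positive biomarkers at
  $\alpha = 0.05$ (the planted-recovery tests bound this behavior).
* The AUC orientation (higher entropy ⇒ excellent) is a convention; it is
  recorded in every ROC result so a folded reading can be audited.
* The generator's planted effect is broad-band regularity; it localizes
  the group difference in *regions*, not sharply in scale, so the
  selected $\tau^\*$ is validated against the scale of maximal planted
  separation measured by Monte-Carlo rather than against a nominal target
  scale.
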