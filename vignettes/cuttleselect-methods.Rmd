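---
title: "Hybrid cuttlefish/simulated-annealing wrapper feature selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid cuttlefish/simulated-annealing wrapper feature selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuttleselect)
```

## The problem

Clinical tabular datasets — thyroid screening panels are the motivating
example — mix a handful of genuinely diagnostic attributes (hormone levels
such as TSH, T3, TT4) with many weakly informative or irrelevant ones
(history flags, measurement indicators). Wrapper feature selection searches
the space of feature subsets directly, scoring each candidate subset by the
cross-validated performance of a classifier trained on exactly those
columns. The subset space is exponential ($2^d - 1$ non-empty subsets), so
the search needs a global optimizer; this package couples the cuttlefish
optimization algorithm (CFA), a population metaheuristic, with a
simulated-annealing (SA) local refinement.

## Encoding subsets as continuous positions

Every candidate subset is a point in $[0,1]^d$. A component above the decode
threshold (default 0.5, the midpoint of the unit cube) selects the
corresponding feature. The CFA's update equations are continuous, while the
objective needs a discrete mask, and thresholding is the simplest bridge
between the two. Two conventions complete the contract:

* **Repair.** If no component clears the threshold, the largest component is
  forced on (argmax, ties to the lowest index). The wrapper objective is
  undefined on an empty subset, so repair is silent rather than an error.
* **Boundary handling.** All optimizer moves clamp out-of-range components
  to the box (`clip_to_bounds()`), which is idempotent and keeps move
  geometry simple; reflecting or wrapping would add behaviour that nothing
  in the method requires.

Transfer-function binarizations (sigmoid/V-shaped) are deliberately out of
scope: thresholding at the box midpoint is the encoding this method defines.

## The cuttlefish algorithm

The CFA mimics how three cell layers in cuttlefish skin (chromatophores,
iridophores, leucophores) combine to produce matching patterns. Each new
candidate is the sum of a *reflection* term (a scaled existing position) and
a *visibility* term (a scaled difference toward the best solution). The
population of $N$ solutions is split round-robin into four groups of
near-equal size, each group with its own move:

* **Group 1 (stretch/shrink):** $x' = R\,x + (best - x)$, with the
  visibility coefficient fixed at 1 and $R \sim U(r_2, r_1)$.
* **Group 2 (mirror):** $x' = best + V\,(best - x)$, reflection locked to
  the best with coefficient 1 and $V \sim U(v_2, v_1)$.
* **Group 3 (interval about the best):** $x' = best + V\,(best -
  \mathrm{AVtop})$, where AVtop is the scalar mean of the best position's
  components, recomputed each outer iteration.
* **Group 4 (random matching):** a fresh uniform draw in the box, identical
  in law to an initial population member.

The reference constants are $r_1 = 0.5$, $r_2 = -2$, $v_1 = 1$, $v_2 = -1$,
giving $R \in [-2, 0.5]$ and $V \in [-1, 1]$. $R$ and $V$ are redrawn per
member per iteration (the alternative — per component — is not what the
scalar-coefficient equations suggest). A proposal replaces the member it was
derived from only when strictly fitter (greedy replacement), and the global
best is updated whenever any evaluated solution beats it; fitness is
maximized throughout. Both choices — greedy replacement and the scalar
reading of AVtop as the mean over dimensions of the single stored best — are
design decisions where the method description is silent or ambiguous; the
plural "average of the best solutions" could also mean an archive of
historical bests, but only one best is ever stored, so the scalar reading is
the consistent one.

## Simulated annealing refinement

Groups 2 and 3 exploit the neighbourhood of the best solution, and each of
their proposals is refined by an SA loop before the greedy comparison: the
hybrid keeps the better of the raw CFA proposal and its SA-refined version.
The annealer perturbs the *continuous* position (each component by an
independent $U(-0.1, 0.1)$ draw, then clamp), re-decodes the mask, and
accepts with the Metropolis rule

$$P(\Delta c, t) = \begin{cases} 1 & \Delta c \le 0 \\ e^{-\Delta c / t} & \Delta c > 0 \end{cases}$$

where cost is negative fitness and the temperature follows the geometric
schedule $t \leftarrow \alpha t$ from $t_0 = 9$ with $\alpha = 0.95$, one
cooling step per iteration. The exponent is the standard sign: a positive
exponent would exceed 1 for worsening moves and not be a probability. The
refinement returns the best-ever solution visited rather than the final
accepted state, so the "keep the better" merge is well defined even when
the annealer ends in a worse accepted state, and refinement can never make
a solution worse.

The reference iteration count of 100 sits beside the temperature and
cooling-rate settings, so it is assigned to the SA inner loop; the outer CFA
budget is an independent knob (default 100, configurable). Setting the SA
budget to zero (`sa_params(n_iter = 0)`, or `mode = "cfa_only"`) reduces the
hybrid exactly to plain CFA — the test suite asserts the trajectories
coincide.

## The wrapper objective

The fitness of a mask $m$ is

$$f(m) = w\,\overline{acc}_{CV}(m) + (1 - w)\left(1 - \frac{|m|}{d}\right)$$

with stratified $k$-fold CV accuracy (default $k = 5$) of the chosen
classifier on the masked columns. The default is $w = 1$ (pure accuracy);
the parsimony term is available because subset-size pressure is often wanted
in clinical screening panels, and it is what makes size-tie-breaking
meaningful. The CV fold assignment and any classifier randomness are seeded
from `cv_seed` *inside* the evaluation (the global RNG stream is saved and
restored), so the objective is a deterministic function of the mask —
without this, comparisons between optimizer variants would be incoherent and
memoisation unsound. Masks are memoised by bit-string key within a run;
wrapper CV dominates the cost and masks recur constantly, so the number of
distinct evaluations (logged in the run history) is the honest budget
measure for oracle comparisons.

The default search-time classifier is kNN ($k = 5$): it has no training
phase, and its distance metric degrades visibly when irrelevant columns are
included, which is precisely the signal a wrapper needs. Any of kNN, SVM
(RBF), random forest, gradient boosting or a decision tree can drive either
the search or the final evaluation. No resampling or imbalance correction is
applied during search.

## The exhaustive oracle

For $d \le 15$ (configurable guard), `exhaustive_select()` evaluates all
$2^d - 1$ masks with the identical objective and returns the maximum, with
ties broken toward fewer features and then toward the subset whose sorted
index list is lexicographically smallest. This is the ground truth the
optimizer is certified against: on the synthetic benchmark below the hybrid
attains the exhaustive optimum in at least 16 of 20 seeded runs.

## The synthetic generator

`generate_synthetic()` emulates the statistical structure the selection
experiment assumes: labels Bernoulli with minority-positive balance
(default 0.3); *informative* features $N(0,1)$ in the negative class and
$N(\text{effect},1)$ in the positive; *redundant* features
$\rho \cdot \text{source} + \sqrt{1 - \rho^2}\,\varepsilon$; *noise*
features $N(0,1)$ independent of the label; optional missing cells planted
uniformly and imputed through the same path the file readers use. Because
the redundant construction uses the realized (class-shifted) source, the
achieved correlation sits slightly above $\rho$; the tests account for this.

What it does **not** emulate about real clinical tables: mixed measurement
scales, structured missingness (labs ordered only when clinically
indicated — the `*_measured` flags of real thyroid data), label noise, and
feature interactions. Passing recovery tests on this generator therefore
demonstrates that the optimizer finds planted signal under clean conditions,
not that it resolves the harder identifiability questions real data pose.

## Problem sizes and experiment settings

The package's own benchmark experiments use, as fixed study conditions:

* **Oracle equivalence:** $n = 300$, $d = 8$, two informative features at
  effect size 3; hybrid with the reference constants ($r_1 = 0.5$,
  $r_2 = -2$, $v_1 = 1$, $v_2 = -1$, $t_0 = 9$, $\alpha = 0.95$, SA budget
  100), population 12, outer budget 25; twenty optimizer seeds against the
  exhaustive optimum over all 255 masks.
* **Recovery:** $n = 500$, $d = 20$, five informative features at effect
  size 2, ten generator/optimizer seeds; mean informative recall and noise
  false-positive rate are reported. This experiment uses $w = 0.9$: the
  marginal penalty per extra feature, $(1 - w)/d = 0.005$, is below the CV
  noise band of a truly informative feature but enough to prune pure noise.

Population 12 (four groups of 3) and outer budget 25 are this package's
defaults for these benchmark runs: with memoisation, the $d = 8$ problem's
distinct-evaluation count approaches the 255-mask oracle cost, which is the
regime where an optimizer-vs-oracle comparison is meaningful.

## Numerical conventions and degenerate cases

* Metrics with zero denominators (nothing predicted positive, empty class)
  are reported as 0 with a logged warning — degenerate CV folds must not
  crash a search.
* Multiclass metrics use macro averaging (unweighted one-vs-rest mean);
  binary metrics take the second factor level as positive unless told
  otherwise.
* AUC is computed as the Mann–Whitney pair statistic via midranks, which
  equals the trapezoidal area under the step ROC; the tests verify the two
  routes agree to $10^{-12}$ and match an independent reference
  implementation.
* Fold counts are reduced (with a warning) when the rarest class has fewer
  members than folds.
* Imputation (median/mode) is applied once, before CV, not per fold. This
  leaks a small amount of information across folds; it is the simpler
  contract, and selection-time comparisons between masks are unaffected
  because all masks share the same imputed matrix.

## Known limitations

* CV accuracy estimated on the same data that drives selection is an
  optimistically biased estimate of generalization; an unbiased estimate
  would need nested CV or a held-out set, both out of scope here.
* The wrapper objective under pure accuracy ($w = 1$) is plateau-rich:
  many masks tie, and the tie structure — not the optimizer — decides which
  of them is reported. The exhaustive oracle's deterministic tie-break makes
  this reproducible at small $d$.
* Stationary tabular data only: no temporal structure, no population shift,
  no calibration of predicted probabilities.
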