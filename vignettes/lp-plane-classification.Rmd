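---
title: "Pairwise LP separating-hyperplane classification of expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise LP separating-hyperplane classification of expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpgx)
```

## The method

`lpgx` classifies multiclass expression profiles with one separating
hyperplane per class pair.  The pipeline is: affine min–max
normalization, margin-based feature filtering, an L1-slack linear
program per class pair, threshold calibration of each plane, and
one-vs-one voting (or a decision list).  The core modelling assumption
is that, after restriction to a small set of informative probes, the
class groups are (nearly) *linearly separable* — a plausible regime for
well-curated microarray subtype panels, where n is tiny relative to the
probe count and a few strongly differential probes dominate.

### Normalization

Each feature is rescaled by
$z = \alpha\,(y - y_{\min})/(y_{\max} - y_{\min}) - \beta$ with
$\alpha > \beta \ge 0$.  The constants are tunable but their specific
values only set the working range; we default to $\alpha = 2$,
$\beta = 1$, giving the symmetric range $[-1, 1]$, which keeps the LP
well scaled against its unit margins.  `fitMinmax()` learns
$y_{\min}, y_{\max}$ on the training samples by default; fitting on the
complete dataset (`fittedOn = "all"`) is available for workflows that
normalize before splitting.  Constant (degenerate) features carry no
information; they map to the midpoint $\alpha/2 - \beta$ and always
score zero in selection.

### Feature scoring: margin versus literal mode

After normalization, samples are split by class and each class block is
mean-centered (`centerByClass()`); centering twice equals centering
once, and block column means vanish to machine precision.  The selection
measure is computed by `scoreFeatures()` in one of two modes:

* **margin** (default): the largest one-dimensional inter-class gap
  $d_i = \max_{(a,b)} \max(0, \min_{s\in a} z_{si} - \max_{s\in b} z_{si})$
  on the *normalized* values.  $d_i > 0$ iff some class pair is
  perfectly split by a threshold on feature $i$ alone — the property the
  selection step exists to find, and the one our tests verify against an
  exhaustive threshold-scan oracle.
* **literal**: the floor-at-zero column minimum
  $d_i = \max(0, \min_j x_{ji})$ applied to the centered concatenated
  matrix.  This formula is degenerate by construction: per-class mean
  removal forces every non-constant centered column to have a
  nonpositive minimum, so the measure is identically zero there.  The
  mode is retained for fidelity and for the degenerate-input tests, but
  the margin interpretation — which actually realizes "select the
  features that make the data separable" — is the default.  For the same
  reason margin scores are computed on normalized rather than centered
  values: class centering removes exactly the between-class offsets that
  the gap measures.

Ranking is by descending score with ties broken by ascending feature
index (determinism); `selectTopK()` keeps the first $k$, default 25.
Whether a fixed $k$ or a score threshold is used upstream is a free
choice; $k$ is exposed as the single selection parameter.  Reports
number features 1-based in file order, matching how probe columns are
usually cited.

### The pairwise LP

For classes $i, j$ with restricted matrices $D_i$ ($n_i \times k$) and
$D_j$, `buildPairLP()` assembles

$$\min_{w, b, y, z}\ \tfrac1{n_i}\textstyle\sum_u y_u +
  \tfrac1{n_j}\sum_v z_v
  \quad\text{s.t.}\quad
  w\cdot d_u - b + y_u \ge 1,\;
  -w\cdot d_v + b + z_v \ge 1,\; y, z \ge 0,$$

with $w, b$ free.  The optimal value is $0$ iff the sets are strictly
linearly separable (then the unit-margin plane exists after scaling);
identical singleton classes give exactly $2$.  The class-size
normalization $1/n_i, 1/n_j$ keeps unbalanced pairs from being dominated
by the larger class.  We always solve the slack program — when the
classes are separable its solution set coincides with the slackless
feasibility problem at objective 0, so nothing is lost by not refitting
without slacks.

Numerical choices: the program is solved by a dense two-phase tableau
simplex with Bland's anti-cycling rule implemented in the package; the
instances here are tiny (tens of rows), where a plain deterministic
tableau is both adequate and exactly reproducible.  Free variables are
split into nonnegative parts before solving ($w = w^+ - w^-$), which
leaves the optimum and the recovered plane unchanged.  Separability is
declared at objective $\le 10^{-6}$ — far below the unit margin scale,
far above the solver's residual.  The contract is *optimality of the
stated LP*, never a particular vertex: with separable data many optimal
planes exist, so tests assert objective values and constraint
satisfaction, not coordinates.

### Threshold calibration and classification

At decision time the LP bias is deliberately discarded: each plane's
projection $w\cdot x$ receives a re-learned threshold $Q^*$
(`optimalThreshold()`) maximizing correct binary decisions on the
calibration samples, so the threshold *is* the bias — using $b$ plus an
offset would double-count.  Among accuracy-maximizing cuts we take the
midpoint of the widest gap between adjacent distinct projections (ties:
the smallest threshold); the outer cuts sit one unit beyond the
extremes, which also handles the all-one-label degenerate case by always
voting the present class.  Calibration uses the training samples of the
plane's two classes by default; calibrating on the whole dataset is a
flag (`calibrateOn = "all"`) for workflows that thresholded on all
available data.

`classifyVote()` runs one-vs-one voting; vote ties are broken by the
largest summed distance $|w\cdot x - Q^*|$ over the tied classes'
planes, then by the smallest class code — a fixed, documented rule that
our three-plane cycle fixture exercises.  `classifyDecisionList()`
instead descends an ordered list of (plane, threshold) tests from the
full class set to a singleton; branch sets may overlap, so a class
ambiguous at one node can be resolved on either branch.  Published
threshold tables for this style of classifier give no construction
algorithm, so the list is pluggable: user-supplied nodes or a greedy
builder (`greedyDecisionList()`) that picks, per node, the calibrated
plane whose majority sides explain the node's samples best.

### Evaluation

`classificationMetrics()` computes standard row=actual metrics: recall
as diag/rowsum, precision as diag/colsum, F1 their harmonic mean,
accuracy as percent trace.  Two conventions from published metric
tables are reproduced as explicit options rather than silently:
`roundingMode = "paper"` rounds each per-class metric to 2 decimals
*before* macro-averaging (on the worked four-group example this gives
macro F1 0.9875 versus 0.9881 unrounded), and
`paperOrientation = TRUE` swaps the precision/recall column placement
(such tables sometimes label row-normalized diagonals "precision"); F1
is symmetric in the two fractions and unaffected.  An empty predicted
column yields precision 1 (vacuously no false positives); an empty
actual row is an error.  `pairwisePrecision()` scores each calibrated
plane on the samples of its own two groups, with denominators
$n_i + n_j$ by contract.

## The synthetic generator

`simulateExpression()` emulates the shape of a five-group leukemia
microarray panel: 64 samples in classes of 8/10/26/10/10, a small
planted set of separating probes among many nulls.  It draws from a
Gaussian class-conditional model with shared diagonal covariance: null
probes are baseline (default 7, a typical log2 intensity) plus
$N(0, \sigma^2)$ noise; each informative probe assigns the classes
distinct mean offsets — a seeded permutation of $0..c{-}1$ scaled by
$\delta\sigma$ (default $\delta = 6$, $\sigma = 1$) — so every class
pair is separated on every informative probe.  This makes linear
separability controllable through the single ratio $\delta/\sigma$,
which is what the method's contracts need to be testable.  The default
500 probes are a desk-scale stand-in for the 22,283-probe array; the
full shape is one argument away and changes nothing structurally.

What the generator does *not* emulate: probe-specific effects and
saturation, heavy-tailed and correlated noise, batch structure, or
classes that are separable only in combination of features.  Passing
tests on this model therefore demonstrate the pipeline's correctness
and its behavior under controlled separability — not classifier
performance on real microarray noise.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: 64 x 500
synthetic matrices, 25 selected features, LP instances up to ~40
constraints, 200-instance threshold-oracle sweeps, and complete
enumerations of 6-point two-dimensional separability instances — chosen
so each contract is exercised exhaustively where enumeration is
possible and by seeded sampling elsewhere.  Every stochastic step
(splitting, simulation) takes an explicit integer seed and restores the
caller's RNG state, so identical configurations reproduce byte-identical
artifacts.

## Known limitations

* The LP has no norm penalty, so with separable data the solver returns
  an arbitrary optimal vertex; training reproduction is guaranteed
  (objective 0 for all pairs implies 100% training-vote accuracy) but
  held-out accuracy can vary between seeds, and no margin-maximization
  claim is made.
* Margin-mode selection only detects features that split a class pair
  *individually*; jointly-separating feature combinations are invisible
  to it (by design — it mirrors the one-dimensional gap goal).
* The evaluation battery offers no cross-validation harness or
  statistical comparison between classifiers; it reports the metrics of
  a single configured run.
* Merged-group schemes relabel before splitting and fitting; metrics of
  merged runs are reported on the merged group set.
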