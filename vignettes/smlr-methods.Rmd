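---
title: "Stacked linear regression on chromatographic fingerprints: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked linear regression on chromatographic fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlr)
```

## The problem and the model

A chromatographic fingerprint is the complete detector trace of one
sample: intensity (mAU) against retention time (minutes), typically
thousands of points per run. Predicting a scalar bioactivity capacity
(here a CD80-expression-type readout) from such traces is an n ≪ p
regression with heavy multicollinearity, and with the added twist that
bioactive constituents need not produce tall peaks — so the whole trace,
not a peak table, is the predictor vector.

`smlr` stacks four linear base learners that all tolerate n ≪ p:

* **PCR** regresses the response on the leading principal-component scores
  of centered X — directions of maximal X-variance, blind to y;
* **PLSR** (single-response NIPALS) extracts components maximising
  covariance with the current response residual, deflating X only;
* **OPLS** first strips components of X-variation orthogonal to y, then
  fits a one-component PLS on the filtered matrix. For a single response
  this is a re-parameterisation of PLSR: OPLS with 1 predictive + k
  orthogonal components reproduces PLSR(k + 1) predictions, a property the
  test suite asserts numerically;
* **EN** minimises `RSS/(2n) + l1*||b||_1 + l2*||b||_2^2/2` by coordinate
  descent, favouring sparse solutions.

Their diversity is the point of the ensemble: PCR and EN behave very
differently from the covariance-driven PLS family, and stacking gains most
when base learners disagree.

The meta-learner is a **non-negative ridge regression without intercept**
on the out-of-fold base predictions. The training set is split into ten
folds; for each fold, all four learners are refitted on the other nine and
predict the held-out fold, so every meta-training row reflects honest
generalisation rather than training fit. The weights solve

$$\min_{\alpha \ge 0}\; \sum_i \Big(y_i - \sum_k \alpha_k v_k(x_i)\Big)^2 + \lambda \sum_k \alpha_k^2,$$

computed exactly as non-negative least squares on the design augmented
with $\sqrt{\lambda} I$ rows — no iterative projected gradient, hence no
convergence-tolerance ambiguity. Omitting the intercept keeps the
$\alpha_k$ interpretable as model weights. The non-negativity constraint
matters because the four base predictions are strongly correlated:
unconstrained least squares would produce large cancelling weights.

Finally the four learners are refitted on the whole training set and the
stack is collapsed into original-space coefficients,
$\beta = \sum_k \alpha_k \beta_k$ with the intercepts combined by the same
weights. Both prediction routes (combine base predictions, or apply the
combined coefficients) are exposed and agree to numerical precision.

Two open choices were resolved as follows. The weights are **not**
renormalised to sum to one by default — the ridge objective is taken
literally — but `fit_smlr(normalize_alpha = TRUE)` rescales them post hoc,
which buys the guarantee that every stacked prediction lies within the
range of the base-learner predictions. And the meta-penalty λ is selected
by cross-validation over `{0, 1e-4, 1e-3, 1e-2, 1e-1, 1}` with ties going
to the largest λ (favouring shrinkage under collinearity), since no
principled fixed value presents itself.

## Hyperparameters of the base learners

No reference values exist for component counts or EN penalties in this
problem family, so they are selected by internal 10-fold cross-validation
on each training set: component counts over `1 .. min(15, n - 2)` with
ties to the fewest components, and EN over l1 fractions {0.1, 0.5, 0.9}
crossed with a 10-point logarithmic penalty-strength path descending from
the smallest penalty that zeroes all coefficients, ties to the strongest
penalty. The selection runs once per training set and the chosen
configurations are reused inside the ten meta-training folds — refitting
the search inside every fold would also be defensible but is considerably
more expensive and no less arbitrary; callers can do it explicitly by
passing per-fold configurations.

One implementation subtlety is worth recording: the EN solver is backed by
`glmnet`, which standardises the response internally. As a consequence its
effective ridge penalty is scaled by `1/sd(y)` relative to its l1 penalty.
The mapping from this package's `(en_l1, en_l2)` objective to glmnet's
`(alpha, lambda)` compensates for that factor, and the tests verify the
stated objective directly against an independent coordinate-descent oracle
and the KKT conditions (to 1e-6 at every coordinate).

## Preprocessing chain

Three steps condition raw fingerprints before any regression.

**airPLS baseline removal** (`lam = 1e5`, `max_iter = 30`, `tol = 1e-3`):
iteratively reweighted Whittaker smoothing with a second-difference
penalty; points above the running baseline lose weight exponentially with
the iteration counter, so peaks drop out of the fit while drifts remain.
The defaults were chosen against the synthetic generator's peak widths
(σ of 0.15–0.5 min on a 70-min run): a pure linear ramp is recovered
essentially exactly (it lies in the penalty nullspace), and the area of a
Gaussian peak riding on a ramp is preserved to within 2 %. The penalty is
dimensionless; larger values stiffen the baseline.

**COW alignment** (`segment_length = 100` points, `slack = 5` points):
the reference axis is cut into ~100-point segments (about one peak width);
interior segment boundaries on the sample may shift by up to ±5 points;
each candidate warp linearly interpolates the sample segment onto the
reference grid and scores it by Pearson correlation; dynamic programming
maximises the summed score. Ties break toward the smaller absolute shift,
which makes self-alignment and zero slack *exact* identities (asserted
bitwise in the tests). The reference is the sample with maximal mean
correlation to all others — a deterministic rule requiring no operator
choice. Constant (detector-floor) segments are scored zero; their
correlation is numerically meaningless, and naive variance products
underflow for such segments, which is handled explicitly in the kernel.

**Autoscaling**: per-column centering and unit-variance scaling using the
population (divisor n) standard deviation, fitted on training data only
and stored in the serialized model, so test data can never leak into the
scaler. Zero-variance columns are flagged and mapped to zero rather than
dropped, preserving the p-point indexing of all coefficient vectors. The
response is mean-centered inside each learner (and restored in the
intercept), never unit-scaled.

Baseline removal and alignment are sample-wise operations that involve no
response, so they may be applied to a full dataset before splitting; the
scaler is refitted per training set inside the evaluation harness.

## Evaluation protocol

Model comparison uses bootstrap out-of-bag resampling: a training set is
drawn as n samples with replacement, the out-of-bag complement (≈ 36.8 %
of samples on average) is the test set, and the procedure repeats ten
times from a master seed that spawns ten recorded child seeds. Per split
and model the harness reports test MSE, training MSE and the mean absolute
percent difference between predicted and observed bioactivity; percent
differences grade as Excellent (≤ 10 %), Good (≤ 20 %), Acceptable
(≤ 30 %), Poor (> 30 %) — thresholds anchored to an assay replicate
variability of about 2 % of the mean. One-way ANOVA compares the five
models' test-MSE columns, and the percent differences are analysed on the
proportion scale (F is scale-invariant; only the displayed sums of squares
change). A degenerate ANOVA (zero within-group variance, as with a
constant response) is reported as a flagged summary rather than an
infinite F.

The package also ships the per-split benchmark tables of the original
72-fingerprint *Astragali Radix* / CD80 study as plain-text fixtures; the
raw chromatograms were never deposited, so these tables are the only
exactly recomputable reference. `reference_summary()` reproduces their
column means and both ANOVA summaries with the package's own machinery.

## The synthetic generator

`generate_dataset()` emulates the statistical structure of an HPLC-DAD
fingerprint study with known ground truth. Defaults — fixed once, as the
package's study conditions — are 72 samples on a 2101-point, 70-minute
grid (a `full_scale` switch restores the 10,501-point geometry), a shared
library of 30 Gaussian peaks with σ between 0.15 and 0.5 min and
log-normal heights, log-normal per-sample concentrations (positive and
right-skewed, as extraction-condition variation produces), a per-sample
retention jitter of 2 grid points, random cubic baselines of 30 mAU scale,
and a heteroscedastic noise floor of 1 mAU whose standard deviation
doubles at 100 mAU of signal. The response is a sparse positive linear
function of 5 of the 30 true concentrations plus assay noise of 2 % of the
mean response; the lowest peak of the library is always active, so at
least one bioactive component is of below-median intensity — exactly the
regime in which whole-fingerprint regression earns its keep. Under these
conditions single-model out-of-bag R² sits around 0.7 and the stacked
model tracks the best base learner; the acceptance suite asserts the
comparative claims (the stack beats PCR and ranks in the top three of
five) over 20 seeded replicates of this generator with ten bootstrap
splits each.

What the generator does **not** emulate: non-Gaussian (tailing) peak
shapes, co-elution requiring curve resolution, wavelength structure of
the diode-array dimension, and nonlinear detector saturation. Passing
tests therefore demonstrate correctness of the algorithms and sane
behaviour under realistic n/p, collinearity, drift and noise — not
performance claims for any particular laboratory dataset.

## Numerical choices and degenerate inputs

* PLS1 needs no inner iteration (the weight vector is closed-form per
  component); a 1e-12 threshold detects degenerate (zero-covariance)
  directions, which stop the component sequence early and record the
  achieved count. A response with no X-covariance at all (e.g. constant y)
  yields the null model — zero coefficients, intercept `mean(y)` — from
  every learner, so the evaluation harness degrades gracefully.
* PCR caps the component count at the numerical rank of centered X (with a
  warning); an all-equal-rows X is an error.
* The Whittaker solve inside airPLS and the COW dynamic program are small
  C++ kernels (banded Cholesky, O(p); and O(segments × slack² ×
  segment_length)); chemometric packages conventionally compile exactly
  these loops, and the pure-R equivalents are two to three orders of
  magnitude slower.
* Serialization is versioned JSON at full precision; a round trip changes
  predictions by less than 1e-12, and unknown schema versions or missing
  fields are errors, not guesses.
* All randomness (fold plans, bootstrap draws, the generator) flows from
  explicit integer seeds through isolated RNG scopes, so every fitted
  object and report is bitwise reproducible from its recorded seeds.

## Known limitations

The meta-learner is linear with four fixed base learners; adding learners
or nonlinear combiners is deliberately out of scope. COW assumes a single
trace per sample on a shared grid and piecewise-linear warps within a
small slack; gross retention shifts need coarser alignment first.
Hyperparameter selection reuses one search per training set rather than
nesting it inside every meta-fold, a pragmatic (and common) shortcut that
slightly favours optimism in the meta-training matrix. And the packaged
benchmark tables permit exact recomputation of summary statistics only —
without the original chromatograms, per-split values cannot be
regenerated from raw data.
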