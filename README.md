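# smlr — stacked multivariate linear regression for chromatographic fingerprints

`smlr` predicts the bioactivity capacity of complex mixtures — typically
aqueous herbal extracts such as *Astragali Radix*, with CD80 expression on
dendritic cells as the activity readout — directly from HPLC-DAD
chromatographic fingerprints. A fingerprint is the full intensity trace of
one sample (thousands of retention-time points, mAU), so the regression
problem is extreme: n samples in the tens against p predictors in the
thousands, with strong multicollinearity and bioactive constituents that
need not be the tallest peaks.

## The method

Four linear base learners that all survive n ≪ p are fitted to a training
set T = {(xᵢ, yᵢ)}: principal component regression (PCR), partial least
squares regression (PLSR), orthogonal projections to latent structures
(OPLS), and the elastic net (EN). Their out-of-fold predictions
v_k^{(j)}(xᵢ) — from 10-fold refits that never saw sample i — form an
n × 4 meta-training matrix, and the stacking weights α solve the
non-negative ridge problem

    min_{α ≥ 0}  Σᵢ ( yᵢ − Σ_k α_k v_k(xᵢ) )²  +  λ Σ_k α_k² ,

solved exactly as non-negative least squares on the √λ-augmented design.
A new sample is predicted as ŷ₀ = Σ_k α_k v_k(x₀), and because every base
learner is affine the stack collapses to a single interpretable
coefficient vector

    β_SMLR = α_PCR β_PCR + α_PLSR β_PLSR + α_OPLS β_OPLS + α_EN β_EN ,

whose large entries point at bioactive retention-time regions.

Around the core the package provides the standard chemometric conditioning
chain — airPLS baseline removal (iteratively reweighted Whittaker
smoothing), correlation optimized warping (COW) alignment by dynamic
programming, per-column autoscaling fitted on training data only — plus a
bootstrap out-of-bag evaluation harness (test MSE, training MSE, percent
difference with an Excellent/Good/Acceptable/Poor grading at
10/20/30 %, one-way ANOVA across models) and a synthetic fingerprint
generator with known ground truth.

## Worked example

```r
library(smlr)

# synthetic 72 x 2101 dataset emulating an HPLC fingerprint study
d  <- generate_dataset(synthetic_config(seed = 101))
pp <- preprocess_fingerprints(d$fm)          # airPLS + COW + scaler
pd <- pair_dataset(pp$fm, d$rv)

Z  <- standardise_apply(pd$X, pp$scaler)
m  <- fit_smlr(Z, pd$y, seed = 101)
print(m)
#> stacked multivariate linear regression model
#>   stacking weights (lambda = 0 ):
#>     PCR   0.00000
#>     PLSR  0.00000
#>     OPLS  0.00000
#>     EN    1.00464
#>   p = 2101 predictors

rep <- run_experiment(pd$X, pd$y, n_splits = 10, seed = 101)
round(rep$column_means$mse_test, 4)
#>    PCR   PLSR   OPLS     EN   SMLR
#> 0.4964 0.3055 0.3055 0.1883 0.2125
```

On this dataset the meta-learner puts essentially all its weight on EN
(the planted truth is sparse, which is EN's regime); the experiment table
shows the stacked model tracking the best base learner and clearly beating
PCR, on data whose response variance is about 0.99.

A command-line front end (`exec/smlr`) wraps the same functions:
`simulate`, `preprocess`, `fit`, `predict`, `experiment` and
`benchmark-check` subcommands operate on the package's CSV/JSON formats.

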