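# dualscreen

Dual-branch neural networks for cost-sensitive dementia-risk screening on
community health records.

## The problem

Community elderly-care services routinely collect two kinds of tabular data
per client: a **profile** (demographics, bio-measurements, medical history)
and **health assessment** questionnaire results (pain, mobility, depression,
nutrition, daily-living independence, …). Cognitive impairment is normally
screened with the Mini-Mental State Examination (MMSE, 0–30; a score below
24 indicates impairment), but the MMSE is administered only after symptoms
appear, and repeating it induces a practice effect. Predicting the MMSE
outcome from the routinely collected data instead gives health-care staff an
early, questionnaire-free signal of high dementia risk.

Two pathologies dominate such data: heavy column-wise **missingness**
(especially in the assessment features) and **class imbalance** (normal
cases outnumber high-risk cases roughly 4.4 : 1). `dualscreen` packages the
complete pipeline around them.

## The model

The dual network learns separate latent representations for the two feature
groups. With profile vector *pᵢ* and assessment vector *qᵢ*:

```
h_i^p(1) = ReLU(p_i W^p(1) + b^p(1)),   h_i^p(2) = ReLU(h_i^p(1) W^p(2) + b^p(2))
h_i^q(1) = ReLU(q_i W^q(1) + b^q(1)),   h_i^q(2) = ReLU(h_i^q(1) W^q(2) + b^q(2))
h_i = [h_i^p(2), h_i^q(2)]              ŷ_i = sigmoid(h_i W^y + b^y)
```

with per-branch hidden widths d₁ = 128, d₂ = 32, trained by mini-batch SGD
with momentum 0.9 on the cost-sensitive cross-entropy

```
L = (1/m_r) Σᵢ −[ wᵢ yᵢ log ŷᵢ + (1 − yᵢ) log(1 − ŷᵢ) ],
wᵢ = m_rⁿ / m_r^d  if yᵢ = 1 (high risk),  wᵢ = 1 otherwise,
```

where the cost ratio is the normal-to-high-risk count ratio of the training
samples (≈ 4.4 at the emulated imbalance). Missing entries are filled
beforehand by column means or by k-nearest-neighbour imputation anchored on
the fully observed columns (inverse-distance-weighted average over the k
nearest records that observe the cell; k = 5, Euclidean by default).

The package also provides the comparison grid (logistic regression, decision
tree, random forest with 100 depth-≤3 trees, three SVM kernels, and a
capacity-matched single network — each plain and cost-sensitive, 16 entries),
a 10-fold cross-validation harness with AUC / average precision /
sensitivity / specificity, paired one-sided t-tests against a reference
algorithm, and a synthetic generator emulating the target data's structure
(2299 × 567, 96 complete columns, binned missing rates up to ~70%, 1 : 4.4
imbalance, complementary group signal).

## Worked example

```r
library(dualscreen)

d <- generate_health_data(synth_config(m = 300, n_p = 10, n_q = 20,
                                       n_complete = 7, seed = 1))
d
#> <synth_health_data: 300 records x 30 features (10 profile, 20 assessment)>
#>   complete columns: 7; high-risk: 56 / 300

filled <- impute_knn(d$data, d$groups, k = 5)
imputation_report(filled)
#> # A tibble: 1 × 5
#>   method     k metric    filled_cell_count fallback_cell_count
#>   <chr>  <int> <chr>                 <int>               <int>
#> 1 knn        5 euclidean              3259                   0

cfg <- dualnet_config(d1 = 32, d2 = 8, epochs = 40, seed = 1)
cv <- cross_validate(
  d$data, d$groups, d$labels,
  algorithms = dplyr::filter(baseline_grid(),
                             label %in% c("DNN", "DNN+CSL", "RF", "RF+CSL")),
  n_folds = 3, seed = 1, imputation = "knn", net_config = cfg
)
summary(cv)
#> # A tibble: 16 × 6
#>    label   algorithm cost_sensitive metric       mean      sd
#>  1 DNN     DNN       FALSE          ap          0.328 0.0703
#>  2 DNN     DNN       FALSE          auc         0.645 0.0166
#>  3 DNN     DNN       FALSE          sensitivity 0.239 0.0669
#>  4 DNN     DNN       FALSE          specificity 0.890 0.0510
#>  5 DNN+CSL DNN       TRUE           ap          0.345 0.0341
#>  6 DNN+CSL DNN       TRUE           auc         0.697 0.00904
#>  7 DNN+CSL DNN       TRUE           sensitivity 0.454 0.130
#>  8 DNN+CSL DNN       TRUE           specificity 0.770 0.0350
#>  9 RF      RF        FALSE          ap          0.456 0.0298
#> 10 RF      RF        FALSE          auc         0.770 0.0272
#> 11 RF      RF        FALSE          sensitivity 0     0
#> 12 RF      RF        FALSE          specificity 1     0
#> 13 RF+CSL  RF        TRUE           ap          0.473 0.0761
#> 14 RF+CSL  RF        TRUE           auc         0.763 0.0445
#> 15 RF+CSL  RF        TRUE           sensitivity 0.589 0.117
#> 16 RF+CSL  RF        TRUE           specificity 0.804 0.0416
```

Reading the output: per algorithm and metric, the mean and SD over the
cross-validation folds. The characteristic patterns are visible even at this
small scale — turning on the cost-sensitive loss (`+CSL`) buys sensitivity
(DNN 0.24 → 0.45; RF 0.00 → 0.59) at a moderate specificity cost, and the
plain random forest ignores the minority class entirely (sensitivity 0 at
specificity 1) despite a good AUC, which is exactly why a screening tool
needs cost sensitivity. `compare_to_reference(cv)` adds fold-paired
one-sided t-tests against `DNN+CSL`, mirroring the benchmark-table layout of
screening studies.

The vignette (`vignettes/dual-network-screening.Rmd`) documents the model,
its assumptions, the generator's design, and all numerical choices. A thin
command-line wrapper over the same functions lives at
`inst/cli/dualscreen-cli.R` (subcommands `synth`, `impute`, `bench`,
`sweep`).

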