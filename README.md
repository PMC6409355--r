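# peakcourse

Quantifying how transcription-factor binding in gene promoters predicts
gene expression across a developmental time course.

During somatic-cell reprogramming, the pluripotency factor Oct4 binds gene
promoters with an intensity that changes day by day, and that binding
shapes the expression of its target genes. peakcourse implements a complete
analysis pipeline for this question, aimed at regulatory-genomics analysts
who have ChIP-seq signal (bedGraph or narrowPeak), gene annotations
(BED6/GTF) and a per-gene, per-day expression table: it extracts the three
peak characteristics in each promoter, fits a family of
temporal-interaction regression models with full inference, and evaluates a
derived high/low-expression classifier.

## The model

Each promoter-binding peak is summarized by its **height** *H* (maximum
signal), **distance** *D* (bp from peak midpoint to the TSS) and **width**
*W* (peak length in bp), observed at days
*t* ∈ {0, 1, 3, 5, 7, 11, 15, 18}. Expression is modelled with
time-modulated products of these features:

    Exp = β₁·H·eᵗ + β₂·D·f(t) + β₃·W·log₁₀(t+1) + ε

where *f(t)* ∈ {*t*, *t*², *t*³, 0.5ᵗ} defines Models 1–4 (Model 4 uses
0.5ᵗ) and the normal disturbance ε is reported as a fitted intercept plus a
residual standard deviation. Coefficients are estimated by least squares on
an internally standardized design (QR with one step of iterative
refinement, so the enormous dynamic range of eᵗ cannot destroy
conditioning). Inference follows the classical decomposition
TSS = ESS + RSS: R², adjusted R̄² = 1 − (1−R²)(n−1)/(n−k−1), the
whole-model F test with F = (ESS/k)/(RSS/(n−k−1)) ~ F(k, n−k−1), and
two-sided t tests per coefficient. Bidirectional stepwise selection over
the 18 candidate products of {H, D, W} × {t, t², t³, eᵗ, 0.5ᵗ, log₁₀(t+1)}
identifies the active terms. For classification, samples are split into
high/low expression groups at the 30% quantiles, model predictions are
thresholded at the minimum high-group value, and performance (Acc, Sn, Sp,
Mcc) is assessed by seeded 10-fold cross-validation against a small
back-propagation neural network (one hidden layer, two sigmoid units).

A synthetic-data module generates matched expression tables, bedGraph
tracks and BED6 annotations from the known generative model, so the whole
pipeline — file parsing, promoter windows, peak extraction, joining,
fitting, classification — is testable end to end without any external
download.

## Worked example

```r
library(peakcourse)

# simulate a 8-gene time course and fit Model 4
sim <- generate_timecourse(generative_config(n_genes = 8, seed = 42))
fit <- fit_expression_model(sim$records, model = 4)
tidy(fit)
#> # A tibble: 4 × 5
#>   term         estimate std_error    statistic   p_value
#>   <chr>           <dbl>     <dbl>        <dbl>     <dbl>
#> 1 (Intercept)    0.0976  2.92e- 3         33.4 1.87e- 40
#> 2 H*exp(t)       0.500   1.26e-10 3962132721.  0
#> 3 D*0.5^t       -0.300   4.68e- 6     -64065.  9.09e-237
#> 4 W*log10(t+1)   1.20    6.95e- 6     172673.  1.32e-262
```

The generative coefficients β = (0.5, −0.3, 1.2) and intercept 0.1 are
recovered to the noise level (sd 0.01), each with a tiny standard error and
a vanishing p-value; `glance(fit)` reports R̄² = 1 at this noise level.
Stepwise selection from all 18 candidates finds the three active terms:

```r
stepwise_select(sim$records)
#> [1] "H*exp(t)"     "W*log10(t+1)" "D*0.5^t"
```

A classification set whose high and low expression bands are separated by
ten noise standard deviations is classified perfectly by the Model-4
threshold rule, while the network baseline lags on the balanced
high/low groups:

```r
cs <- generate_classification_set(generative_config(seed = 42), separation = 10)
compare_classifiers(cs$records, k = 10, seed = 42, evaluate = "extremes")
#> # A tibble: 2 × 6
#>   method   acc    sn    sp   mcc mcc_degenerate
#>   <chr>  <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1 model4 1     1         1 1     FALSE
#> 2 bp     0.714 0.429     1 0.522 FALSE
```

For file-based workflows, `run_config()` + `run_all()` (or the thin CLI at
`inst/cli/peakcourse.R`) drive extraction (`features.tsv`, `records.tsv`),
fitting (`fits.tsv`, `inference.tsv`, `model_comparison.tsv`) and
classification (`cv.tsv`, `metrics.tsv`) with JSON manifests for exact
reruns. See the vignette in `vignettes/temporal-interaction-models.Rmd` for
the methods account.

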