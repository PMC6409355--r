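---
title: "Temporal-interaction regression of expression on binding-peak features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-interaction regression of expression on binding-peak features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcourse)
```

## The model

During somatic-cell reprogramming the pluripotency factor Oct4 binds gene
promoters with an intensity that changes over developmental time, and that
binding is thought to shape target-gene expression. peakcourse quantifies
this with a small family of linear models in which each promoter-binding
peak is summarized by three characteristics:

* **height** `H` — the maximum signal of the peak,
* **distance** `D` — the unsigned bp separation between the geometric
  midpoint of the peak interval and the gene's transcription start site,
* **width** `W` — the length of the peak interval in bp,

observed at the eight developmental days `t ∈ {0, 1, 3, 5, 7, 11, 15, 18}`.
Because expression correlates with time more strongly than with any single
peak characteristic, the explanatory variables are *derived combination
variables*: products of `H`, `D`, `W` with a function of time. The model
family is

```
Exp = β₁·H·eᵗ + β₂·D·f(t) + β₃·W·log₁₀(t+1) + ε ,
```

with `f(t)` one of `t`, `t²`, `t³`, `0.5ᵗ` (Models 1–4; Model 4 uses
`0.5ᵗ`). The random disturbance `ε` is normal; its location is estimated as
the fitted intercept (one reportable number per fit) and its dispersion as
the residual standard deviation. Coefficients are estimated by least
squares, and the full candidate set for stepwise selection is all 18
products of `{H, D, W}` with `{t, t², t³, eᵗ, 0.5ᵗ, log₁₀(t+1)}`.

## Conventions for the genomic layer

All coordinates are 0-based and half-open, the native bedGraph/BED
convention, so file content maps to internal values bit-exactly. The
promoter is the strand-aware window from 1.5 kb upstream to 0.5 kb
downstream of the TSS; windows that would cross the chromosome origin are
clipped with a warning. Distance is unsigned: the wording "distance between
the midpoint of the peak and the TSS" admits a signed reading, but the
unsigned one is minimal and keeps `D ≥ 0` in every `D·f(t)` term. "Midpoint"
is read as the geometric center of the peak interval, `⌊(start+end)/2⌋`, not
the summit; the summit is retained on peak objects for diagnostics only.
When only a signal track is available, peaks are derived as maximal runs of
contiguous intervals at or above `min_height` (default 1 signal unit — the
source analysis starts from called peaks and states no threshold, so this
is a configurable package default). Within a promoter the strongest peak is
kept, with deterministic tie-breaks (height, then smaller distance, then
leftmost start), and genes with no qualifying peak at a timepoint are
dropped from that timepoint with a warning.

## Numerical choices in the fitter

`exp(t)` spans eight orders of magnitude between day 0 and day 18, so the
design matrix is badly scaled by construction. `fit_lsm()` therefore
standardizes the columns internally, solves by QR decomposition (never the
normal equations), applies one step of iterative refinement — re-solving on
the residual, which restores the precision that cancellation removes when
response magnitudes span many orders — and back-transforms the coefficients
and their covariance to the raw scale. This is why reported `β₁` values can
be meaningful at magnitudes like `1e-8` while the fit stays
well-conditioned. Rank deficiency is a fatal error that names the offending
column; fits with `n < k + 2` are allowed but report no inference, with a
warning. A no-intercept mode exists but warns that the `TSS = ESS + RSS`
decomposition is no longer guaranteed.

## Inference

The variance decomposition uses centered sums of squares
(`TSS = Σ(Yᵢ−Ȳ)²`, `ESS = Σ(Ŷᵢ−Ȳ)²`, `RSS = Σ(Yᵢ−Ŷᵢ)²`); the whole-model F
statistic is `(ESS/k)/(RSS/(n−k−1))` against `F(k, n−k−1)`. A variant that
divides by `TSS/(n−k−1)` instead is available via
`f_test(..., literal = TRUE)` for comparison, but it is reported without a
p-value because that ratio does not follow the F reference distribution
under the null; only the RSS form is consistent with the `F(k, n−k−1)`
reference the method cites. Coefficient t tests are two-sided. A perfect
fit reports `F = ∞`, `p = 0`; a null fit reports `F = 0`, `p = 1`.

## Stepwise selection

`stepwise_select()` is bidirectional from the intercept-only model and
deterministic: candidates are screened in alphabetical order and ties go to
the alphabetically first term. Two criteria are offered.

* **AIC** (default): compares `n·log(RSS/n) + 2p`. Fits whose relative RSS
  falls below `1e-12` are treated as numerically perfect; a perfect fit
  dominates any imperfect one, and ties between perfect fits are broken
  toward the smaller model. Without this parsimony tie-break, exact
  generative recoveries would wander among `−∞` AIC values.
* **p-value** (`alpha_enter = 0.05`, `alpha_remove = 0.10`): because up to
  18 candidates are screened at each entry step, a raw 0.05 entry threshold
  admits a spurious term in roughly half of pure-noise datasets (the best of
  many uniform p-values is small). The entry threshold is therefore
  Bonferroni-adjusted for the number of candidates screened;
  `adjust = "none"` restores the raw behaviour for sensitivity checks.

Exact recovery of the generative term pair is a property of the noiseless
limit: at any positive noise level the probability that some spurious term
clears a fixed raw threshold is scale-free, so the package's recovery checks
run at `noise_sd = 0` and separately verify that with noise the selection
still contains the active pair.

## Classification protocol

The classification unit is one (gene, day) record: the per-fold coefficient
table requires pooled fits, which would be impossible with one fit per
gene. Following the application protocol, the pipeline min-max normalizes
records (each of `H`, `D`, `W`, `Exp` to `[0, 1]`) before classification.
One consequence worth knowing: normalizing a feature shifts its basis term
by a pure function of time (`(W − min)/span · log₁₀(t+1)` differs from
`W·log₁₀(t+1)` by `min·log₁₀(t+1)`, which is not in the basis), so the
normalized model is mildly misspecified whenever the feature minimum is far
from zero. This is inherited from the protocol, not introduced by the
implementation; `kfold_cv()` itself takes whatever records it is given, and
the package's separability benchmarks run on the generator's raw scale. Samples are ranked by expression; the top
30% form the high group, the bottom 30% the low group, and the smallest
high-group value is the classification threshold. Every sample is labelled
by the `value ≥ threshold` rule; `evaluate = "extremes"` restricts scoring
to the balanced high/low groups.

In 10-fold cross-validation the model is refitted on each training fold and
held-out predictions are compared with the threshold. By default the
threshold is the single one defined on the full data
(`threshold_rule = "global"`), which is the protocol the grouping rule
describes — the threshold is fixed before validation. The alternative
`threshold_rule = "training"` recomputes it per training fold to avoid any
leakage; it is noisier because each fold's 30%-quantile jitters by a few
order statistics, so boundary samples can flip even for a perfect
predictor. Confusion counts are pooled over folds before metrics are
computed (the stabler convention at these sample sizes); Acc, Sn, Sp and
Mcc follow the standard confusion identities, with a degenerate-marginal
Mcc reported as 0 and flagged.

Two evaluation subtleties matter when reading chance-level results. Under
the 30/70 threshold labelling, a constant predictor scores accuracy 0.70 on
all samples simply by calling everything negative; chance level is 0.5 only
on the balanced extreme groups, which is why the package's null-calibration
checks use `evaluate = "extremes"`.

The baseline is a one-hidden-layer feedforward network with two sigmoid
units trained by full-batch gradient descent (learning rate 0.1, 2000
epochs, mean-squared-error loss, seeded uniform `[-0.5, 0.5]` weight
initialization) on the three normalized Model-4 basis terms, evaluated
under identical folds. Training hyperparameters are package choices,
recorded in each run's configuration; training is deterministic given the
seed, and non-convergence is reported, never fatal.

## The synthetic-data generator

`generate_timecourse()` emulates the joined product of a ChIP-seq feature
table and an expression table: per gene, a baseline height `H₀ ~ U[1, 10]`
decaying exponentially at 0.15/day (binding weakens as reprogramming
proceeds), a baseline width `W₀ ~ U[50, 500]` growing as
`W₀(1 + 0.3·log₁₀(t+1))` (width effects are logarithmic in time), and a
fresh `D ~ U[0, 1500]` per record (the distance time course is
disorganized). Expression follows the Model-4 equation with
`β = (0.5, −0.3, 1.2)`, intercept 0.1 and Gaussian noise sd 0.01 by
default. These marginals and rates are generator choices — the underlying
study publishes no feature distributions — and are recorded in each
dataset's truth metadata so no test treats them as an external claim.
Distances are integer bp and widths even integer bp, so the written
bedGraph peak (height `H`, width `W`, midpoint `D` bp upstream of the TSS,
clamped into the 2-kb promoter window with the clamp recorded) reproduces
`(H, D, W)` exactly after extraction: heights are serialized with 17
significant digits and survive the round trip bit-exactly.

What the generator does *not* emulate: background signal and noise peaks in
the tracks, read-level sampling, replicate structure, mapping artifacts,
or genes missing at some timepoints. Passing round-trip and recovery tests
therefore demonstrates correctness of the pipeline's bookkeeping and
estimation, not robustness to real ChIP-seq noise.

`generate_classification_set()` controls separability directly. Its
`separation` parameter is the gap, in noise-sd units, between a high band
(30% of genes) and a low band of noiseless expression values centred on a
base level of 100 expression units; targets are realized exactly through
the width channel (`W` solved per record from `β₃·W·log₁₀(t+1)`), with days
`{1, 3, 5, 7, 11, 15, 18}` so the log term never vanishes, and height and
distance drawn at random as uninformative features. A quarter of each band
sits exactly on the band's inner edge so that the empirical 30%-quantile
threshold concentrates inside the gap rather than on a band interior. With
`separation = 0` the construction degenerates to the null model — all
coefficients zero, expression equal to base level plus noise — because any
nonzero feature signal would remain predictable and classification could
not fall to chance.

## Problem sizes used by the checks

The package's own verification uses 50 random n = 8 instances for the
least-squares oracle comparison; 200 replicates (30 genes × 8 days) for
coefficient recovery and 500 for interval coverage; 2000 n = 8 null
simulations for F-test calibration; 100 noiseless datasets for stepwise
recovery; and 20 seeds for each cross-validation benchmark. These sizes
give the binomial margins needed to distinguish the tested rates from their
bounds while keeping the default check run short.

## Known limitations

* Models are linear in the derived terms; no regularized or non-linear
  variants, and no per-gene random effects.
* Per-gene fits use n = 8 observations against k = 3 terms, so per-gene
  inference rests on 4 residual degrees of freedom; pooled fits are
  provided and used for classification.
* The pooling rule behind stage-wise coefficient summaries in the source
  analysis is unstated; peakcourse exposes per-gene and pooled fits and
  does not guess further.
* No multiple-testing correction across genes, and no ROC/AUC analysis;
  the classifier is the fixed-threshold rule described above.
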