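---
title: "Harvest-readiness from image time series: model, attribution and acquisition-day selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harvest-readiness from image time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(harvshap)
```

This vignette is the package's account of its own methods: the data model,
the classifier, the grouped Shapley attribution, the acquisition-day
selection loop, the synthetic-field generator that makes everything
testable, and the numerical and design decisions taken where more than one
reasonable choice existed.

## The data model

A field trial observes every plant on a common grid of acquisition days,
indexed by days after planting (DAP). The default grid has eleven days,
`{22, 27, 35, 44, 50, 57, 65, 69, 71, 76, 80}`, and four potential harvest
days whose *basic images* — the last acquisition before each potential
harvest — are the last four grid days (DAP 69, 71, 76, 80). Every plant
becomes Ready at exactly one harvest day; a plant that never reaches
maturity is cleared with the final harvest and labelled Ready there.

A plant with readiness day $k$ contributes $k$ time series: one anchored at
each harvest day $j \le k$, labelled Ready iff $j = k$. The series anchored
at harvest day $j$ is a *trailing window*: the basic image at that anchor
plus the $T-1$ chronologically preceding acquisition days. Two consequences
shape everything downstream:

* **Windows differ across harvest days.** At the same $T$, a series
  anchored at the first harvest day reaches further back into the season
  than one anchored at the last; the day sets overlap but are not equal.
* **The feasible initial length is bounded by the first anchor.** On an
  eleven-day grid whose first anchor sits at position 8, every harvest day
  supports windows up to $T = 8$; that is where the selection experiments
  start. After the four middle days have been excluded the shortest series
  length is $T = 4$.

`build_series()` errors rather than silently padding when $T$ exceeds an
anchor's history, and `subset_series()` refuses to drop an anchoring day:
the last image of a series is the reference immediately before the
potential harvest, without which the label is undefined.

## The classifier

Each image is mapped by one shared encoder to a 32-dimensional embedding.
The packaged backbone (`"tiny"`) is a compact fully connected encoder on
pooled grayscale input (`input_size` 16, hidden width 32); it honours the
image-to-32-dimensions contract at desk scale, and the configuration keeps
the backbone a switch. A fixed sinusoidal positional encoding of the raw
DAP is added to the embedding, giving the time point embedding (TPE); the
$T$ TPEs are concatenated into the time series embedding (TSE), and a
two-layer head with hidden size $\lfloor T\cdot 32/\lambda\rfloor$ and a
ReLU in between produces the two class scores.

Design decisions that were genuinely open:

* **Positional encoding form.** A fixed (non-learned) sinusoid over the raw
  DAP value, added elementwise to the embedding. It is parameter-free,
  deterministic, pairwise distinct across any realistic grid, and
  extrapolates to unseen ages; the dimension is configurable.
* **Head nonlinearity.** Without a nonlinearity the two linear layers
  collapse into one map, so a ReLU sits between them.
* **Loss.** Cross-entropy on the two scores; the loss of a series is
  accumulated over all of its images through the shared encoder and one
  optimizer step is taken per batch of series.
* **Learning rate.** The optimizer protocol is Adam with weight decay
  $\alpha$, batch 16, a step schedule (step 20, factor 0.1), at least 60
  epochs and patience 10. The default step size is $10^{-3}$: a compact
  randomly initialised encoder needs a larger rate than the $10^{-5}$
  customary for fine-tuning a large pretrained backbone, which within the
  epoch budget would leave the small encoder's weights essentially at their
  initialisation. The rate is a plain configuration field.
* **Early stopping and checkpointing.** "No significant improvement" is
  quantified as no gain above $10^{-4}$ in validation overall accuracy for
  `patience` epochs, counted only after `min_epochs`. The returned
  checkpoint is the one with the highest validation accuracy; among
  equally-accurate epochs the latest is kept, because attribution is run on
  this checkpoint and the later model is the better-converged one.
* **Tuning.** `tune_hyperparameters()` walks the grid
  $\alpha \in \{10^{-3}, 10^{-2}, 10^{-1}\}$, $\lambda \in \{2,3,4\}$ and
  breaks ties toward smaller $\lambda$, then smaller $\alpha$ —
  deterministic and biased toward the simpler head.

All randomness flows from a single integer seed through named substreams
(a 32-bit FNV-1a hash of a tag string combined with the seed), so weight
initialisation, batch shuffling and every simulation stream are independent
of evaluation order and fully reproducible; two runs with the same
configuration produce identical histories and identical artifacts on disk.

## Grouped Shapley attribution

The players are whole time points: group $t$ is the 32-feature block of
TPE $t$ inside the TSE. The value of a coalition $S$ is the model's Ready
output when the groups in $S$ keep their observed values and the absent
groups are imputed from training-set series, averaged over the imputation
draws (default 10; if the background is no larger than the number of draws
the whole background is used). The attribution of group $t$ is the
classical weighted sum of coalition differences; `group_shap_exact()`
enumerates all $2^M$ coalitions ($M \le 15$), and `group_shap_sampled()`
solves the Shapley-kernel weighted least-squares system
(weights $(M-1)/\binom{M}{s}s(M-s)$) with the full and empty coalitions
pinned — the infinite-weight limit that gives the all-fixed and all-free
coalitions the highest weight — so local accuracy
$\phi_0 + \sum_t \phi_t = f(x)$ holds by construction in both modes. With
the complete coalition set the sampled estimator reproduces the exact
values; a single imputation draw per call, shared across coalitions, makes
the two routes comparable at machine precision under the same seed.

Two further decisions matter in practice:

* **Anchor-matched imputation.** Because windows differ across harvest
  days, position $t$ of a series anchored at harvest day 1 shows a
  different acquisition day than position $t$ of a series anchored at
  harvest day 4. Imputing across anchors would therefore replace a time
  point with a *different day's* embedding — including its positional
  encoding — and inflate the apparent contribution of days the model
  ignores. `compute_group_shap()` consequently imputes each series only
  from background series of the same harvest day, so "the same entity"
  always means the same acquisition day.
* **Value function.** The softmax probability of Ready by default (the
  class the distributions are reported for); a logit mode is available.
  With a two-class softmax the attributions for Not-ready are exactly the
  negated Ready attributions.

`summarize_contributions()` aggregates $|\phi|$ per acquisition day —
combined across harvest days, which is the field-wide quantity the
selection loop uses, plus per-harvest-day quantiles for violin-style
plots — and reports the day with the lowest combined mean $|\phi|$.

## The selection loop

`run_selection()` iterates: train from scratch, attribute the validation
split, exclude the eligible acquisition day with the lowest combined mean
$|\phi|$, rebuild all series without it, repeat. Eligibility requires a day
to be (a) outside the fixed set — by default the first three and last four
grid days, the latter being the anchoring basic images — and (b) present in
the current window of *every* harvest day, since a field flight can only be
dropped for the whole field. Ties break toward the earlier day. Retraining
is always from scratch with the same model seed, never fine-tuned, so each
step's model is a function of (manifest, configuration, seed) alone and the
whole trace is reproducible. The loop stops at `min_T`, at
`max_iterations`, or when no eligible day remains; fixing the entire grid
yields an empty trace rather than an error. Excluded days are annotated
with the developmental-stage codes implied by the reference head-size table
(`stage_lookup()`), which maps head diameters to BBCH-style codes: at or
below 1 cm the main shoot is still developing ("3x"), above that the micro
stage follows the fraction of the expected final head diameter (30%, 50%,
70%, 80%, 95% thresholds), taking each harvest day's final observed mean
head size as its expected diameter.

## The synthetic-field generator

The generator exists so that every downstream stage has known ground
truth. Per plant, head growth is logistic in time,
$\mathrm{size}(d) = K/(1+e^{-r(d-t_0)})$ with asymptotic diameter
$K \sim \mathcal N(13, 0.5^2)$ cm and rate
$r \sim \mathcal N(0.18, 0.01^2)$ per day — magnitudes consistent with
heads that cross a 10 cm readiness threshold shortly before the harvest
dates. A plant is Ready at the first harvest day whose anchoring
acquisition shows a head at or above the threshold.

**Readiness-day spread.** The within-field developmental spread is not a
quantity the reference trial pins down, so the generator parametrises it
directly: the maturity midpoint $t_0$ is drawn by inverse CDF from a
piecewise-uniform distribution whose breakpoints are each plant's own
threshold-crossing offsets from the four anchors, with segment masses
following a constant per-harvest-day hazard (default 0.5). Two properties
motivated this choice, made before any experiment was run: each harvest
day matures about half of the still-standing field regardless of the
uneven anchor spacing, which keeps the Ready/Not-ready decision hard at
every date; and it minimises the label information carried by the anchor
identity alone. The second point deserves emphasis: the anchoring harvest
day of a series is identifiable from its day set (via the positional
encoding), and all series anchored at the last harvest day are Ready by
construction, so a generator with lopsided readiness hazards would let a
classifier beat chance *without any image signal* purely from per-anchor
base rates. With balanced hazards that leak is confined to the small
last-anchor stratum (about 6% of series), and a signal-free field scores
statistically at chance on an independent test split.

**Informative days.** Images render soil (with per-day brightness and tone
nuisance shared across plants, mimicking weather between flights), a leaf
rosette growing with plant age, and a central pale disc whose radius and
brightness track the head size. At *informative* days the disc tracks the
plant's own latent size; at all other days the sizes are permuted across
plants with a seeded per-day permutation, which preserves each day's image
statistics while destroying the association with the plant's own
trajectory. An empty informative set (the negative control) must be
requested explicitly with `signal_free = TRUE`.

**What the generator does not emulate.** Real canopy occlusion, orthophoto
blur and registration error, radiometric drift, pests, and cultivar
differences are all absent, and the rendered signal is deliberately
low-dimensional. Passing the recovery and negative-control experiments
therefore shows that the pipeline's machinery — series bookkeeping,
training, attribution, exclusion — behaves correctly on data with known
structure; it does not certify accuracy levels on real imagery.

## Problem sizes and numerical choices

The packaged experiments run at desk scale, chosen as the package's own
study conditions: fields of 24–120 plants, 32-pixel images, validation
fractions of 0.2–0.3, training schedules of at least 20 epochs in unit
tests and the full 60-epoch protocol in the recovery and negative-control
experiments; the selection experiments use 80-plant fields and start at
$T = 8$. Exact attribution at these sizes enumerates at most $2^8$
coalitions per series. Tolerances: Shapley oracle agreement and the
dummy/symmetry axioms at $10^{-6}$; local accuracy at machine precision in
exact mode; the early-stopping improvement threshold at $10^{-4}$ absolute
validation accuracy. Degenerate inputs error loudly: empty splits, missing
image records, series longer than an anchor's history, a dropped anchor
day, an absent head-size reference cell, a singular sampled-coalition
design, and a balanced accuracy with an absent class are all explicit
errors rather than silent defaults.

## Known limitations

* The encoder is intentionally small; with real orthophoto crops a deep
  pretrained backbone behind the same image-to-32 contract would be needed,
  and the learning-rate default would have to be revisited.
* Grouped Shapley assumes the imputation background spans the relevant
  variation; with very small training splits the per-anchor background
  strata can be thin (the implementation falls back to the full background
  when a stratum is empty).
* The selection loop is greedy, one day per step, as the field procedure
  requires; it does not search day subsets jointly, and a day excluded
  early is never reconsidered.
* Accuracies quoted anywhere in the package's documentation are produced
  by its own tests and scripts on synthetic fields; they are not estimates
  of real-field performance.
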