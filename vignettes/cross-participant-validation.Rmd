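---
title: "Why shuffled splits overestimate cross-participant model accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why shuffled splits overestimate cross-participant model accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lopocv)
```

## The problem

Biosignal classifiers — EEG being the canonical case — are usually built from
data collected on a handful of people, yet advertised as working on *anyone*.
Each person's feature distribution is shifted by stable individual differences
(electrode placement, anatomy, physiology), so a new user constitutes a
covariate shift: the input distribution changes while the conditional class
structure, relative to the person's own baseline, is preserved. If the data
are shuffled before splitting ("improper" partitioning), every participant
contributes observations to both the training and the evaluation side, the
shift disappears from the measurement, and the reported accuracy can vastly
overstate what the model achieves on an unseen person. The honest design holds
out whole participants: Leave-One-Participant-Out (LOPO) or
Leave-N-Participants-Out (LNPO) cross-validation.

`lopocv` packages this methodology so the size of the effect can be measured,
diagnosed and demonstrated end to end on synthetic data:

1. a generator of multi-participant datasets with controllable individual
   differences (`generate_feature_dataset`, `generate_raw_epochs`);
2. entropy and Morlet band-power feature extraction (`extract_feature_table`);
3. partition constructors for both policies and a leakage auditor
   (`improper_shuffled_kfold`, `lopo_partition`, `lnpo_partition`,
   `audit_partition`);
4. two variability-reducing oracle transformations (`shifted_heaviside`,
   `shift_to_median`);
5. covariate-shift diagnostics (`histogram_kl`, `pca2_project`,
   `weight_ratio_grid`, `embed_2d`, `participant_purity`);
6. a CV harness with pooled Wald intervals and comparison reports
   (`run_cv`, `compare_partitioning`, `run_demo_pipeline`).

## The generative model

Each participant $p$ receives an offset $o_p \sim \mathcal N(0,
\sigma_{\text{part}}^2 I_d)$. An observation of class $y \in \{0, 1\}$ is

$$x = o_p + y\,\delta\,u + \varepsilon, \qquad
\varepsilon \sim \mathcal N(0, \sigma_{\text{noise}}^2 I_d),$$

with $u$ a fixed unit direction (the first coordinate axis by default, for
reproducibility and closed-form checks). Two labelling modes cover the two
kinds of study designs:

* **state mode** — both classes occur within every participant (fatigue-style
  designs); the class effect is applied per observation;
* **condition mode** — the class is a participant-level attribute
  (diagnosis-style designs); the class effect is added to $o_p$ itself, so
  classifying a held-out participant is purely a between-participant problem.

This is the simplest structure that yields participant clustering in feature
space with a participant-invariant conditional class structure. What it does
*not* emulate: non-Gaussian or anisotropic individual differences, temporal
non-stationarity within a participant, artifacts, or 1/f spectra. Passing
tests on this generator show that the *methodology* behaves as claimed under
its stated premise, not that any particular real dataset has this geometry.

The raw-epoch generator produces band-limited sinusoids (random frequency
within each configured band, random phase) whose amplitudes depend on class
and on a per-participant log-normal multiplier, plus white noise — enough
structure for band-power features to carry both a class signal and individual
differences, and nothing more.

## Feature spaces

The entropy space computes approximate, sample and fuzzy entropy per channel
(3 features/channel, hence 90 features on 30 channels); the spectral space
computes mean Morlet band power per band and channel (60 features on 30
channels with an alpha 12–15 Hz and beta 16–22 Hz band pair). Parameter
defaults follow the dominant conventions, since such parameters are often
unstated in applied work: embedding dimension $m = 2$, tolerance $r = 0.2\,
\mathrm{sd}$, fuzzy exponent $2$; Morlet with 7 cycles, band power averaged
over 1 Hz-spaced centre frequencies. Sample entropy is undefined when no
template pair matches; we return a documented `NA` sentinel and impute the
table-wide maximum when building feature tables, keeping tables finite. All
three entropies are verified against $O(N^2)$ brute-force oracles to 1e-10.

## Partitioning and the audit

All three constructors produce exact CV plans (every observation evaluated
exactly once). The improper shuffle is unstratified by default, since typical
improper pipelines just shuffle; stratification is available as a flag. LNPO
deals shuffled participants round-robin into groups of size
$\lfloor P/k \rfloor$ or $\lceil P/k \rceil$. The auditor flags every (fold,
participant) pair that appears on both sides of a fold and infers the realised
policy; it is the programmatic form of the guideline that data from training
participants must never appear in validation or test sets.

## The oracle transformations

Both transformations are deliberately leaky and exist to *demonstrate* the
variability–accuracy relationship; the API requires
`leakage_acknowledged = TRUE` and they are not a preprocessing
recommendation.

* **shifted Heaviside** binarises each feature at the participant's own median
  (strictly above → 1, ties → 0).
* **shift to median** translates each (participant, class) block so its median
  lands on the pooled class median; per block it is an isometry, and it is
  idempotent.

One numerically interesting consequence, easy to miss: because shift-to-median
aligns every block median *exactly* onto the pooled class median in every
coordinate, the sampling differences between the two pooled class medians
become a spurious class signal present in all $d$ coordinates, of aggregate
size roughly $\sqrt{d}\,\sigma_{\text{mix}}/\sqrt{N}$ standard units. In high
dimension this can push post-transform accuracies *above* the single-direction
Bayes level. It is a property of the oracle construction (the transform
consults test labels), and one more reason these transformations must not be
mistaken for legitimate preprocessing.

## Diagnostics

KL divergence is estimated on shared histograms with $\varepsilon$-smoothing
of both distributions (the standard orientation
$D(P_{TR}\Vert P_{TE}) = \sum p_{TR} \log (p_{TR}/p_{TE})$, which is
non-negative). Density-ratio weight grids follow the importance-weighting view
of covariate shift: on a 7×7 histogram over the pooled 2-D PCA projection, the
per-bin weight $w = p_{TE}/p_{TR}$ is the factor that would rescale training
loss to approximate test loss. Heat maps show $\log_{10}(w + \varepsilon)$
with $\varepsilon = 10^{-5}$, so bins with training mass but no test mass sit
at exactly $-5$; bins with test mass but no training mass have no defined
weight (loss rescaling requires the training distribution to cover the test
support) and carry a sentinel. A proper split needs far more rescaling than an
improper one — quantified by the mean $|\log_{10} w|$ over occupied bins and
by the per-bin delta maps with their `=`, `v`, `+` labels (threshold
$\tau = 0.5$ log units by default; the choice only affects labelling, not the
deltas).

`embed_2d` is an exact t-SNE (quadratic cost, bisection-calibrated
perplexity, early exaggeration, seeded start), adequate for the sample sizes
used here. Because visual cluster inspection is not testable, the package
operationalises it as `participant_purity`: the fraction of observations whose
$k = 10$ nearest neighbours have a strict own-participant majority, with ties
counted against purity.

## Evaluation harness

Models plug in through a fit/predict contract; built-ins are a
ridge-regularised logistic regression (`glmnet`, fixed $\lambda = 0.01$) and a
single-hidden-layer network (`nnet`). Pooled accuracy is total correct over
total evaluated; the 95% interval is the Wald binomial interval on the pooled
count, clamped to $[0,1]$ — the convention used when CV accuracies of this
kind are reported. Comparisons always match fold counts (improper $k$ = number
of proper folds), so data quantities per fold agree across policies and the
only difference is where participants are allowed to appear.

**A limitation worth stating plainly:** the pooled Wald interval treats the
$n$ evaluated observations as independent Bernoulli trials. Under proper
partitioning with condition-mode labels, predictions are strongly correlated
within a held-out participant — in the extreme, each participant is classified
wholly right or wholly wrong, so the accuracy's true sampling spread is of
order $0.5/\sqrt{P}$, much wider than the Wald width of order
$0.5/\sqrt{P\,n_{\text{per}}}$. Pooled Wald CIs on clustered evaluations are
therefore anti-conservative; a participant-level interval would be the honest
alternative. The package reports pooled Wald because that is the convention
being studied, and its demonstration suite shows exactly this failure mode:
on condition-mode data the proper LOPO accuracy scatters around chance from
seed to seed far outside its own CI, while the improper accuracy sits above
0.9.

## Study conditions used by the demonstration suite

The spec-level parameters of the generator are free (no published estimate of
real EEG feature variability is implied); the suite fixes one set of
conditions and keeps it:

* gap demonstration (state mode): $P = 12$, $n_{\text{per}} = 50$, $d = 90$,
  $\delta = 2$, $\sigma_{\text{part}} = 2\delta = 4$,
  $\sigma_{\text{noise}} = 0.4$. The 90-feature dimension mirrors the entropy
  feature space; 12 participants mirror the LOPO = 12-fold design. The
  within-participant margin $\delta / 2\sigma_{\text{noise}} = 2.5$ puts the
  improper accuracy near 0.99 — the regime of the strongest published
  contrasts — and has a second, deliberate effect: at the accuracy ceiling,
  both the linear model's cost of cancelling participant offsets and the
  shift-to-median median-sampling artifact are compressed, so the improper
  accuracy is genuinely invariant under the transformation.
* null control: the same with $\sigma_{\text{part}} = 0$ (improper and proper
  agree within 0.03).
* transformation rescue: the same with $\sigma_{\text{part}} = 4\delta = 8$,
  large enough that untransformed proper accuracy sits near chance.
* condition-mode collapse: $P = 12$, $n_{\text{per}} = 100$, $d = 30$,
  $\delta = 0.5$, $\sigma_{\text{part}} = 3$, $\sigma_{\text{noise}} = 1$.

Two mechanisms worth knowing when reproducing the effect with a *linear*
model: improper overestimation requires $d > P$ (only then does a weight
vector exist that cancels the training participants' offsets while keeping a
component along the class direction — the geometry that generalises to seen
participants but not to unseen ones), and the gap grows with
$\sigma_{\text{part}}/\sigma_{\text{noise}}$. Flexible models show the effect
at smaller $d$ by memorising participant clusters instead.

Problem sizes throughout (hundreds to a few thousand observations, 100-seed
repetitions for the probabilistic properties) were chosen so the entire suite
runs in minutes on one core while keeping binomial counting margins
comfortable.

## A worked run

```{r demo, eval = FALSE}
cfg <- synthetic_config(P = 12, n_per = 50, d = 90, delta = 2,
                        sigma_participant = 4, sigma_noise = 0.4, seed = 1)
demo <- run_demo_pipeline(cfg, model_spec("linear", seed = 1))
print(demo)
```

The printed 6-row table is the {improper, proper} × {untransformed, shifted
Heaviside, shift to median} design: improper accuracy near 0.99 in all three
rows, proper accuracy collapsing on untransformed data and restored by shift
to median, purity 1 before and near chance after the transformation.

## Known limitations

* The generator's Gaussian isotropic structure is a premise, not an estimate;
  effect sizes measured here do not transfer numerically to any real dataset.
* Pooled Wald CIs understate uncertainty under participant-level clustering
  (see above).
* The exact t-SNE is quadratic in $n$; use it for inspection-scale samples.
* The built-in models are small by design; the harness accepts any
  fit/predict pair for larger architectures.
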