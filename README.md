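# lopocv

Tools for measuring how **dataset partitioning decisions** change the reported
accuracy of cross-participant biosignal (EEG-style) classifiers — and for
demonstrating, on controllable synthetic data, why shuffled ("improper")
splits overestimate what a model will achieve on an unseen person.

## Who this is for

Researchers building models that must generalise to *people not in the
training set* (EEG, EMG, wearables, any grouped biosignal data), reviewers
auditing such pipelines for participant leakage, and instructors who want a
reproducible demonstration of covariate shift caused by individual
differences.

## The core ideas

Every participant *p* has a stable offset in feature space, so each person is
a distinct input distribution while the class-conditional structure relative
to the person's baseline is shared:

```
x = o_p + y * delta * u + noise,     o_p ~ N(0, sigma_part^2 I)
```

* **Improper partitioning** shuffles all observations into k folds: every
  participant appears in both train and evaluation of every fold, the
  covariate shift vanishes from the measurement, and accuracy is inflated.
* **Proper partitioning** holds out whole participants
  (Leave-One-Participant-Out, Leave-N-Participants-Out); the evaluation then
  includes the shift a deployed model would face.
* **Pooled accuracy** is total correct over total evaluated, with the 95%
  Wald binomial interval `acc ± 1.96 sqrt(acc (1 - acc) / n)`.
* Comparisons are summarised by the **error ratio** `err_proper/err_improper`
  and the **percent error increase**
  `100 (err_proper − err_improper)/err_improper`.
* Covariate shift between a train/test pair is diagnosed by histogram KL
  divergence, by 7×7 **density-ratio weight grids**
  `w = p_test/p_train` on the 2-D PCA plane (displayed as
  `log10(w + 1e-5)`, so train-only bins sit at exactly −5), and by a
  neighbour-based **participant purity** statistic that operationalises
  visual cluster inspection of a t-SNE embedding.
* Two deliberately leaky "oracle" transformations — **shifted Heaviside**
  (binarise at the participant's median) and **shift to median** (re-centre
  each participant's class median onto the pooled class median) — reduce
  inter-participant variability to show that it, and nothing else, is what
  separates the two accuracy estimates.

## Worked example

```r
library(lopocv)

cfg <- synthetic_config(P = 12, n_per = 50, d = 90, delta = 2,
                        sigma_participant = 4, sigma_noise = 0.4, seed = 1)
demo <- run_demo_pipeline(cfg, model_spec("linear", seed = 1))
print(demo)
```

```
demo_result: {improper, proper} x {untransformed, shifted Heaviside, shift to median}
   policy         transform accuracy ci_low ci_high error_rate n_eval
 improper     untransformed    0.988  0.982   0.994      0.012   1200
   proper     untransformed    0.698  0.672   0.724      0.302   1200
 improper shifted_heaviside    0.993  0.989   0.998      0.007   1200
   proper shifted_heaviside    0.993  0.989   0.998      0.007   1200
 improper   shift_to_median    0.990  0.984   0.996      0.010   1200
   proper   shift_to_median    0.993  0.989   0.998      0.007   1200
participant purity: untransformed = 1, shifted_heaviside = 0.018, shift_to_median = 0.022
```

Reading it: with 12 participants whose offsets are twice the class effect,
the shuffled 12-fold estimate (0.988) overstates the honest LOPO estimate
(0.698) by 0.29; the proper error rate is ~26× the improper one. Purity 1
means the feature space is perfectly clustered by participant; after the
variability-reducing transformations purity drops to chance and the proper
accuracy is restored — the gap was individual differences, not model
capacity.

```r
print(demo$comparisons$untransformed)
#> comparison_report: improper vs proper partitioning
#>   improper: acc 0.988 (0.982, 0.994), err 0.012
#>   proper:   acc 0.698 (0.672, 0.724), err 0.302
#>   proper error is 25.86x the improper error (2485.7% increase)
#>   proper CI entirely below improper CI: TRUE
```

Any plan can be audited for participant leakage:

```r
ds <- generate_feature_dataset(cfg)
audit_partition(improper_shuffled_kfold(ds, 12, seed = 1), ds)
#> partition audit: declared improper_kfold, inferred improper
#>   violating (fold, participant) pairs: 144
```

See `vignettes/cross-participant-validation.Rmd` for the model, the
diagnostics, parameter defaults and known limitations.

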