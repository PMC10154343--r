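# mifcat

Auditory categorization of vocalizations by most-informative
spectrotemporal features, with adaptive mechanisms for noisy and
reverberant listening conditions.

## The problem

Animals recognize call categories despite two kinds of variability:
*production* variability (no two calls of a type are identical) and
*environmental* variability (background noise, room reverberation). A
biologically interpretable route to such robustness is a shallow
hierarchy: a dense cochlea-like time–frequency representation, a sparse
layer of intermediate-complexity feature detectors tuned to
category-diagnostic spectrotemporal fragments, and a weighted vote.
`mifcat` implements that model end to end for anyone studying auditory
categorization computationally — including a synthetic vocalization
generator, so every stage runs and is testable without recorded corpora.

## The model

* **Cochleagram**: log-spaced bandpass channels (0.1-octave steps),
  rectified, envelope-smoothed, sampled at 1 kHz; stimuli calibrated to
  65 dB SPL.
* **Feature detector (FD)**: a spectrotemporal patch Θ cut from a
  within-class cochleagram. Its response is the bandwidth-restricted
  sliding cross-correlation V&#x2098;(t); the binary output is
  1 iff max&#x209c; V&#x2098;(t) ≥ κ·θ. The threshold θ maximizes the
  mutual information I(output; class) in bits; the weight is the smoothed
  log-likelihood ratio w = log₂((hits+1)/(N&#x1D64;+2)) −
  log₂((fas+1)/(N&#x2092;+2)).
* **MIF set**: a greedy search admits candidates in MI order when they are
  not redundant (detection-pattern MI below half their class MI) and
  strictly improve the voting stage's hit rate without raising false
  alarms; at most 20 FDs, five non-overlapping instantiations per call
  type.
* **Evaluation**: rank-based AUC of the normalized votes and
  d′ = √2·Φ⁻¹(AUC); go/no-go behavior via a winner-take-all difference of
  normalized responses and a two-parameter logistic map
  F(x; k, λ) = λ + (1−2λ)/(1+e^(−kx)).
* **Adaptive mechanisms**: condition-specific training; contrast gain
  control (window- or cochleagram-level mean/SD normalization of the
  input); and top-down excitability modulation — one global scale κ on all
  FD thresholds, tuned per condition by confusion-matrix MI or driven
  per stimulus by the cochleagram μ/σ statistic, a biologically
  computable SNR proxy.

## Worked example

Train a one-vs-rest model for the tonal "wheek" class on a small synthetic
corpus and watch noise degrade it:

```r
library(mifcat)
classes <- default_call_classes()
corpus  <- make_corpus(classes, n_per_class = 20, rng_seed = 7)
sp      <- split_corpus(corpus, train_frac = 0.5, rng_seed = 7)
grid    <- make_cf_grid(200, 6400, 0.1)
train   <- corpus_cochleagrams(sp$train, grid)
test    <- corpus_cochleagrams(sp$test, grid)

fit <- mif_train(training_corpus(train$cochleagrams, train$labels, "wheek"),
                 n_candidates = 100, rng_seed = 3)
fit
#> <mif_model> call type 'wheek' (core, clean-trained), instantiation 1
#>   1 feature detector(s) (cap 20); training hit = 1.000, false alarm = 0.000
coef(fit)[, c("duration_ms", "center_frequency_hz", "bandwidth_oct", "weight")]
#>   duration_ms center_frequency_hz bandwidth_oct   weight
#> 1         278            2039.297           1.7 4.874469
```

One 278-ms detector centred near 2 kHz — the wheek's tonal ridge —
separates the training set perfectly (hit rate 1, false alarms 0), so the
greedy search stops after a single feature. On held-out calls:

```r
scores <- predict(fit, test$cochleagrams)$normalized
within <- test$labels == "wheek"
auc <- auc_from_scores(scores[within], scores[!within])
dprime_from_auc(auc, n_pairs = sum(within) * sum(!within))
#> clean test: AUC = 1.000, d-prime = 4.15

noisy <- corpus_cochleagrams(degrade_corpus(sp$test, snr_db = 0, rng_seed = 11), grid)
#> 0 dB SNR:   AUC = 0.900, d-prime = 1.81
```

Clean sensitivity is at ceiling (AUC 1 is clipped by the pair-count
resolution before the probit, giving d′ = 4.15); adding white noise at
0 dB SNR drops it to d′ = 1.81. The cochleagram μ/σ statistic meanwhile
rises from 1.25 (clean) to 6.52 (0 dB) — the signal the top-down mechanism
uses to lower detector thresholds adaptively.

The full study — training conditions × mechanisms × test conditions —
is one call:

```r
ex <- run_experiment_matrix(experiment_config(seed = 1))
ex$results      # tidy: train_condition, mechanism, condition, call_type,
                # instantiation, auc, dprime, benefit
```

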