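# moodtrf

EEG analysis of affective news listening: temporal response functions,
ERP-style component measures, factorial group statistics, and screening for
a depressed state.

## The problem

When people listen to running speech, the EEG responses to successive
content words overlap, so classical event-related averaging fails. The
temporal response function (TRF) framework instead models the continuous
EEG at channel *ch* as a convolution of the binary content-word onset train
*s(t)* with an unknown lag kernel:

```
r_ch(t) = Σ_τ w_ch(τ) · s(t − τ) + ε_ch(t),     τ ∈ [−100, 800] ms
```

Estimated by ridge regression on the lagged design, `w_ch(τ)` behaves like
a deconvolved word-locked evoked response, showing N1 (~130 ms, negative),
P2 (~200 ms, positive) and N400 (~300–600 ms, negative) components. Their
amplitudes index attentional resource allocation (N1/P2) and semantic
processing load (N400); comparing them between depressed and non-depressed
listeners (BDI-II ≥ 14) across negative/neutral/positive news quantifies
affective attentional bias, and feeding them to a classifier asks whether a
depressed state is detectable from EEG recorded during an everyday
activity.

`moodtrf` implements the complete chain for researchers in auditory
cognitive neuroscience and mental-state monitoring:

* **`generate_cohort()`** — synthetic labelled cohorts (EEG + word onsets +
  ratings) with configurable group×news effects embedded in component
  kernels over 1/f noise, providing ground truth for every stage;
* **`preprocess_trial()`** — zero-phase FIR band-passes (1–50 Hz order
  3300, then 1–8 Hz order 1320), polyphase resampling to 200 Hz, and a
  threshold-interpolation artifact cleaner;
* **`loocv_lambda_select()` / `estimate_subject_trfs()`** — ridge TRFs with
  leave-one-trial-out selection of λ over 2¹–2²¹ (per subject) and the
  population-mode λ;
* **`extract_component_measures()`** — fixed-window mean amplitudes
  (100–160 / 170–230 / 300–600 ms) and per-subject peak latencies via
  dynamic-time-warping alignment to the grand average;
* **`mixed_anova()` / `aligned_rank_transform()`** — two-way mixed ANOVA
  (Greenhouse–Geisser, Mauchly, partial η²), ART for ordinal ratings,
  Bonferroni post-hocs, χ²/Cramér's V, pooled t/Cohen's d;
* **`loocv_classify()` / `permutation_test()`** — class-weighted
  squared-hinge L2 linear SVM under leave-one-subject-out CV with in-fold
  standardisation, RFE to 6 features, grid-searched cost, AUC/TPR/TNR and
  1000-permutation significance.

## Worked example

A compact synthetic cohort (4 depressed / 6 non-depressed, 15 trials each,
SNR −10 dB) pushed through the full pipeline:

```r
library(moodtrf)

cfg <- cohort_config(n_depressed = 4, n_nondepressed = 6,
                     trial_duration_s = c(20, 26), fs_hz = 200,
                     snr_db = -10, effect_scale = 1, seed = 42)
cohort <- generate_cohort(cfg)
pipe <- run_trf_pipeline(cohort, lambda_grid = 2^seq(1, 21, by = 4))

# N1 latency at Fpz for positive news, by group
n1 <- subset(pipe$measures, component == "N1" & channel == "Fpz" &
                              condition == "positive")
n1$group <- cohort$subjects$group[match(n1$subject_id,
                                        cohort$subjects$subject_id)]
aggregate(peak_latency_ms ~ group, n1, mean)
#>           group peak_latency_ms
#> 1     depressed        140.6250
#> 2 non-depressed        117.0833
```

The depressed group's N1 to positive news is ~24 ms later — the generator
injected 21 ms, recovered through preprocessing, ridge deconvolution and
DTW latency mapping at −10 dB SNR. Group statistics on the (aligned-rank
transformed) arousal ratings and the screening classifier:

```r
ar <- aggregate(arousal ~ subject_id + condition, cohort$ratings, mean)
tab <- data.frame(subject = ar$subject_id,
                  group = cohort$subjects$group[match(ar$subject_id,
                                                      cohort$subjects$subject_id)],
                  news = ar$condition, value = ar$arousal)
art <- aligned_rank_transform(tab, "group")
mixed_anova(art, value = "art_rank")[1, c("effect", "F", "df1", "df2", "p")]
#>   effect        F df1 df2           p
#> 1  Group 14.81089   1   8 0.004887966

report <- loocv_classify(pipe$features, classifier_config("combination", seed = 1))
c(auc = report$auc, tpr = report$tpr, tnr = report$tnr)
#> auc tpr tnr
#>   1   1   1

head(report$coefficients[order(-report$coefficients$mean_abs_coef), ], 3)
#>                   feature mean_abs_coef normalized
#> 6 P2_latency_Fpz_positive    0.01592859  1.0000000
#> 3 N1_latency_Fpz_positive    0.01589597  0.9979520
#> 8 N1_amplitude_Pz_neutral    0.01303076  0.8180738
```

The depressed group's lower arousal ratings come out as a significant Group
effect; on this deliberately clean cohort the 18-feature classifier
separates the groups perfectly, and the most influential features are the
positive-news latencies carrying the injected group effect.

## Package layout

```
R/                  synthetic cohorts, io, preprocessing, TRF estimation,
                    component extraction, group statistics, classifier
src/                Newton solver for the squared-hinge SVM; DTW dynamic
                    program (Rcpp / RcppArmadillo)
tests/testthat/     unit, property and end-to-end suites with independent
                    oracles (closed forms, exhaustive enumeration,
                    external optimisers)
vignettes/          methods vignette: models, assumptions, parameter
                    choices, limitations
scripts/            acceptance.R (see above)
```
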