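---
title: "Models and methods behind moodtrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind moodtrf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

EEG measured while people listen to running speech cannot be averaged into
event-related potentials the usual way: content words arrive every few
hundred milliseconds, so the responses to neighbouring words overlap. The
temporal response function (TRF) framework treats the continuous EEG
$r_{ch}(t)$ at channel $ch$ as the convolution of a binary content-word
onset train $s(t)$ with an unknown lag kernel $w_{ch}(\tau)$:

$$ r_{ch}(t) = \sum_{\tau} w_{ch}(\tau)\, s(t - \tau) + \varepsilon_{ch}(t),
   \qquad \tau \in [-100, 800]\,\mathrm{ms}. $$

Estimated by ridge regression on the lagged design matrix, $w_{ch}(\tau)$
plays the role of a deconvolved, word-locked evoked response: it shows an
N1 (negative, ~130 ms), a P2 (positive, ~200 ms) and an N400 (negative,
~300–600 ms). `moodtrf` implements the full analysis around this model for
a cohort of listeners split into depressed and non-depressed groups by a
BDI-II cut-off of 14: component amplitude/latency extraction, the factorial
group statistics, and a screening classifier, plus a synthetic-cohort
generator that makes every stage testable against ground truth.

## Synthetic cohorts

Because the target recordings are not publicly deposited, the package ships
a generator (`generate_cohort()`) that emulates the *structure* the analysis
assumes rather than the raw physiology:

* **Stimuli.** 15 news items (5 per valence condition), durations uniform
  on 45–83 s, shared across subjects (everyone hears the same items).
  Content-word onsets follow a jittered renewal process — a 150 ms
  articulatory floor plus an exponential gap whose mean keeps the rate at
  2.5 words/s. The rate is a plausible broadcast-speech figure and is
  configurable; it is not a measured quantity.
* **Signals.** Each channel is a channel-weighted sum of three Gaussian
  component kernels (N1: −, 130 ms, FWHM 40 ms; P2: +, 200 ms, FWHM 50 ms;
  N400: −, 420 ms, FWHM 180 ms) placed at every word onset, over 1–50 Hz
  band-limited $1/f$ noise, independent per channel. Gaussian bumps were
  chosen because their extrema, window means and spectra are analytically
  checkable. N1/P2 dominate at Fpz, N400 at Pz, all three are present at
  Cz, mirroring the fronto-central vs centro-parietal scalp distribution of
  auditory N1/P2 and N400.
* **Effects.** The effect plan reproduces the reported group-by-news
  structure: +21 / +27 ms N1/P2 latencies for depressed listeners on
  positive news; an N400 latency lead of 33.3 ms for negative vs positive
  news in both groups (applied as ±16.65 ms around the neutral peak);
  deeper N1 in non-depressed listeners (gain 1.25); deeper N400 to
  negative news in depressed listeners (gain 1.3); lower arousal (−0.4)
  and comprehensibility (−0.5) ratings in the depressed group. A single
  `effect_scale` multiplies every *group* effect; condition structure in
  the ratings (e.g. valence ordering) is intrinsic and not scaled.
* **Ratings.** Latent Gaussian per item and condition (means from the
  published stimulus-validation survey, SD 0.7), rounded and clamped to
  1–5.
* **Noise level.** The default SNR of −10 dB (kernel-train power over
  noise power, per channel) is the condition under which the package's own
  recovery properties are stated.

Two deliberate simplifications: injected kernel parameters are
deterministic per group × condition (no extra between-subject jitter), so
ground-truth group contrasts are exact and the null at `effect_scale = 0`
is exact; and within-group variability therefore comes only from the noise
process and rating discretisation. Passing tests consequently show that the
*pipeline* recovers what was injected under EEG-like noise — they cannot
show robustness to physiological variability the generator does not model
(volume conduction, artifacts of ocular origin, non-stationary background,
trial-to-trial kernel variation).

A study-size cohort does not fit in memory (135 subjects × 15 trials ×
~60 s × 500 Hz × 3 channels), so `generate_cohort()` returns metadata and
ground truth only; EEG trials are materialised per subject by
`generate_subject_trials()` from a deterministic per-subject substream of
the cohort seed, and `write_cohort()`/`read_cohort()` stream the on-disk
representation.

## Preprocessing

The filtering chain is fixed by the protocol: a 1–50 Hz FIR band-pass of
order 3300 at the native 500 Hz, resampling to 200 Hz, artifact handling,
then a 1–8 Hz FIR band-pass of order 1320. Two choices were genuinely open:

* **Phase handling.** The filters are applied forward and backward
  (zero-phase). The alternative — single-pass with group-delay
  compensation — is equivalent for these linear-phase designs; what matters
  is that *some* delay correction happens, otherwise every latency measure
  would be biased by half the filter length. Signals are odd-reflected at
  the edges by one filter length before filtering.
* **Design rate of the second filter.** The order-1320 band-pass is
  designed at 200 Hz, where it sits after resampling in the published
  chain's order of operations.

Resampling is polyphase windowed-sinc (Kaiser β = 8, zero-stuff by p,
low-pass at the tighter Nyquist, keep every q-th sample, integer delay
compensation). This was written in-package after the available
`signal::resample` measured a maximum error of ~0.29 on a unit 4 Hz sine
at 500→200 Hz; the in-package resampler measures < 2 × 10⁻⁵ against the
closed-form sine.

Transient artifact removal uses a threshold-interpolation cleaner
(±500 µV default): supra-threshold runs are linearly interpolated from
neighbouring clean samples, the rejected fraction is reported, and a trial
with more than 50 % rejected in any channel is flagged unusable (flagged,
not dropped — exclusion is a dataset-level decision). Subspace
reconstruction and ICA-based ocular correction are established external
methods and deliberately out of scope; the cleaner targets the same class
of large transients without modelling sources.

## TRF estimation

`ridge_fit()` solves $(X^\top X + \lambda I)\,w = X^\top y$ with an
identity penalty, no intercept and no column scaling — the impulse
regressors share a scale, so standardisation would only rescale $\lambda$.
The design is stored sparse (an impulse train with $k$ onsets has only
$181k$ non-zeros at 200 Hz), and each trial is reduced once to the
sufficient statistics $(X^\top X, X^\top Y, y^\top y, n)$ plus the
eigendecomposition of $X^\top X$, from which the weights for *every*
candidate $\lambda$ and the exact held-out MSE of arbitrary weights follow
without revisiting the signals.

The regularisation parameter is selected per subject by leave-one-trial-out
cross-validation in three steps: single-trial weights are estimated for
each training trial, averaged, and the averaged weights are scored by MSE
on the held-out trial, averaged over channels and held-out trials; the grid
is $2^1$–$2^{21}$ and ties break toward the smaller value. The population
parameter is the mode of the per-subject selections (ties again toward
smaller), re-estimated from each dataset rather than hard-coded, because
the modal value is dataset-specific. Per-condition TRFs are the means of
that condition's single-trial weights at the population parameter. Held-out
MSEs are unweighted means across trials of unequal length.

One empirical note: on this generator's data the LOOCV MSE-vs-λ curve is
monotone increasing — averaging 14 single-trial fits already suppresses
estimator variance, so the small-λ end wins and the selected value sits at
the bottom of the grid. A U-shaped curve (and hence an interior optimum)
would require noise that trial-averaging cannot remove; the machinery is
agnostic either way.

## Component measures

Amplitudes are window means of the TRF weights — 100–160 ms (N1),
170–230 ms (P2), 300–600 ms (N400), endpoints inclusive on the 5 ms lag
grid. Peak latencies are measured in two stages: the grand-average TRF
(equal subject weighting) yields one polarity-appropriate extremum per
component, searched *within the component's amplitude window* (the windows
are the only component definition available; ties resolve to the earliest
lag, flat windows return the earliest lag with a warning). Each subject's
TRF is then aligned to the grand average by dynamic time warping —
absolute-difference local cost, symmetric unit steps {(1,1), (1,0), (0,1)},
no warping window — and the subject's latency is the mean lag of the
subject samples the optimal path maps onto the grand-average peak sample.
Averaging over path plateaus makes the measure deterministic and robust to
ties. Both curves are z-scored before warping so the alignment is
amplitude-invariant; whether the original analysis normalised before
warping is unstated, and z-scoring is the choice documented here.

The feature table has 12 EEG columns (N1/P2 peak latencies at Fpz, N1/N400
mean amplitudes at Pz, each per condition — the measures whose group
effects motivated them) and 6 rating columns (per-condition mean arousal
and comprehensibility). Cz latencies are computed and reported in the
measure table but never enter the classifier, matching the published
feature definition.

## Group statistics

The two-way mixed ANOVA (Group between, 2 levels, unbalanced; News within,
3 levels) uses Type-III / unweighted-cell-means sums of squares via a
multivariate linear model with sum-to-zero contrasts (implemented on
`car::Anova`; a hand sums-of-squares oracle guards the balanced case in the
tests). Greenhouse–Geisser ε is computed from the pooled within-group
covariance; degrees of freedom are corrected only when Mauchly's test
rejects at 0.05, and ε plus the original degrees of freedom are always
reported. Partial η² is SS_effect / (SS_effect + SS_error). Subjects with
missing within-subject cells are listwise excluded with a log message;
all-constant data returns F = 0 with a warning rather than failing.

Ordinal ratings are aligned-rank transformed before the ANOVA: for each
target effect, all other estimated effects (unweighted cell-mean
decomposition) are subtracted and the aligned values midranked, one
transform per effect. EEG measures enter untransformed.

Post-hoc families follow the significance gating: a significant News main
effect triggers paired t tests over the three condition pairs (Bonferroni
family 3); a significant interaction triggers per-group paired t tests
(family 3 per group) and per-condition unpaired t tests between groups
(family 3). The participant-table statistics are the asymptotic chi-square
test of independence without continuity correction with Cramér's
V = √(χ²/(N·(min(r,c)−1))), and the pooled-variance independent t with
Cohen's d.

## Depression screening

The classifier is a linear SVM with squared hinge loss and L2 penalty,

$$ \min_{w,b}\ \tfrac12\lVert (w,b) \rVert^2
   + C \sum_i cw_i \max(0,\, 1 - y_i(x_i^\top w + b))^2, $$

solved by damped Newton iteration in compiled code (the objective is convex
and piecewise quadratic; an independent BFGS optimiser verifies the optima
in the tests). The intercept is penalised, following the convention of the
common liblinear-style implementations of this loss. Class weights are
$N/(K n_k)$ computed on each training fold.

Evaluation is leave-one-subject-out. Within each fold, strictly in order:
standardise with training statistics only (constant columns are flagged and
left unscaled); recursive feature elimination to 6 features for the EEG-only
and combination sets (one feature dropped per refit at C = 1, no
re-standardisation between iterations); grid-search C over
$10^{-3}$–$10^{3}$ by stratified three-fold cross-validation of the
training data, scored by plain accuracy on class-weighted fits with ties
toward the smallest C; fit and score the held-out subject. Pooled decision
scores give the AUC (scores rather than hard labels — one score per subject
exists and labels would coarsen the curve); scores above zero predict the
depressed class for the confusion counts.

The permutation test permutes the subject labels once per randomisation,
reuses that assignment across all folds of that randomisation's LOOCV
(preserving the dependency structure of the observed statistic), re-runs
the *entire* fold pipeline, and reports
$p = (\#\{\mathrm{null} \ge \mathrm{observed}\} + 1)/(m + 1)$. The add-one
convention is what makes the floor $1/(m+1)$ attainable — a literal
proportion would report zero. Coefficients are aggregated as the mean
absolute value across folds with zero-fill for unselected features, min–max
normalised to [0, 1] for reporting. A single master seed drives inner-fold
shuffling and the permutation order.

## Numerical and scale choices

* Sample indexing is 0-based in all documentation (an onset at time $t$
  maps to sample $\mathrm{round}(t \cdot f_s)$); lag axes are in ms; times
  on disk are seconds, trial-relative.
* Stimulus impulses that collide on one sample clip to a single 1.
* The lagged design zero-pads outside trial bounds, matching impulse-train
  semantics.
* `ridge_fit` at λ = 0 with a singular normal matrix returns the
  minimum-norm pseudo-inverse solution with a warning.
* Test and example problem sizes are deliberately compact: property tests
  use 15–30 s trials at 200 Hz (the shortest lengths that still exceed the
  order-3300 filter), the calibration studies use 8-subject null cohorts
  (50 classifier replicates, 500 ANOVA replicates at the rating level), and
  the reproduction script uses a 40-subject cohort (10/30) at the full
  45–83 s / 500 Hz study settings with 1000 permutations. The ANOVA power
  property is checked at study size (32/103) on simulated component-measure
  tables with pipeline-scale latency noise, since pushing 100 full-size
  EEG cohorts through the pipeline is not what that property is about.

## Known limitations

* The generator's between-subject homogeneity (above) makes strong-effect
  cohorts nearly separable; classifier performance on synthetic data is a
  plumbing check, not a forecast of real-world screening accuracy.
* The artifact cleaner is a surrogate: it removes amplitude transients,
  not ocular or muscular sources.
* The ART alignment uses fixed-effect cell means; mixed-model alignment
  variants are out of scope.
* The over/under-sampling imbalance variant of the classifier is
  deliberately not implemented; class weighting is the supported route.
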