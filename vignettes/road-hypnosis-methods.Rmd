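---
title: "Identifying road hypnosis from multimodal driving signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying road hypnosis from multimodal driving signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Road hypnosis — driving without awareness — is an unconscious driving state
that arises during long, highly repetitive drives: the driver keeps the
vehicle on the road with open eyes and an apparently normal posture, yet
perception is paralyzed and reaction times lengthen. Because outward
behaviour looks normal, the state is hard to observe directly; it has to be
inferred from physiological and vehicle signals. `roadhypnosis` implements
a complete identification pipeline for this latent state from three
synchronized modalities: scalp EEG, eye tracking (pupil diameters, gaze
velocity, inter-pupillary distance) and vehicle telemetry (speed,
acceleration).

This vignette is the package's account of the method: the model, its
assumptions, the tunable parameters, the synthetic data the package tests
itself against, and the numerical choices made where the design was
genuinely open.

## The model

The core is a two-state hidden Markov model over `normal` and `hypnosis`
driving, decoded at a 1 Hz observation grid. Three ingredients replace the
classical Gaussian-emission HMM:

1. **Supervised transitions.** With labeled state intervals available,
   the transition matrix $A$ with
   $a_{ij} = P(S_t = j \mid S_{t-1} = i)$ and the initial distribution
   $\pi$ are estimated by counting transitions across recordings, with an
   additive pseudo-count $\kappa$ (default 1) so the minority hypnosis
   state never produces a degenerate zero row. No Baum–Welch/EM is
   involved; training is fully supervised.

2. **Discriminative emissions.** Per state $j$, a gradient-boosted tree
   ensemble is fit one-vs-rest with a squared-error objective against the
   0/1 state indicator, plus L2 regularization of the leaf weights. The
   regression target for the "observed probability" is deliberately the
   0/1 indicator: it is the only construction consistent with per-state
   training followed by a calibration step. Raw scores are then passed
   through Platt scaling — a sigmoid fitted by logistic regression on
   *out-of-fold* scores (3 internal folds), never on in-sample scores,
   because a boosted ensemble overfits its own training scores and would
   otherwise make the calibrator vacuous. Calibrated per-state
   probabilities are renormalized so $\sum_j p(S_j \mid o_t) = 1$.

3. **Scaled-likelihood decoding.** A discriminative scorer yields
   posteriors, not class-conditional likelihoods. The standard bridge is
   the scaled likelihood $\hat b_j(o_t) = p(S_j \mid o_t)/p(S_j)$
   (posterior over training prior), floored at $10^{-12}$. Constant
   per-step factors cancel in the normalized forward recursion, so these
   terms are valid inside the forward algorithm
   $\alpha_t(j) = \sum_i \alpha_{t-1}(i)\, a_{ij}\, \hat b_j(o_t)$
   (implemented with per-step scaling; the log-likelihood is the sum of
   log scaling factors) and inside Viterbi decoding (log space,
   backpointers, ties broken toward the lower state index so decoding is
   deterministic).

A linear readout summarizes the decoded observation as a scalar *hypnosis
degree*: a 14-slot inner product over the standardized features plus an
intercept of 0.471. The shipped coefficient set names 10 features (speed,
the five EEG band powers, gaze velocity, both pupil diameters, IPD); slots
2, 3, 11 and 13 are reserved padding fixed at 0 because the identity of
those features was never published — the package flags rather than guesses
them. `refit_degree()` re-estimates the coefficients on training data by
OLS for users who prefer a data-driven readout; neither mode is asserted
to be the original estimation procedure, which was not fully specified.

## Feature extraction

**EEG.** Channels are optionally dropped, re-referenced to the average
reference, and bandpass filtered with a brick-wall FFT mask on
$[f_{low}, f_{high}]$ (default 0.5–40 Hz). The published description gives
both 0.2 Hz and 0.5 Hz as the high-pass edge; 0.5 Hz is the default here
because it matches the filtering equations and the delta band floor, and
the edge is exposed as `eeg$low_cut`. Band power uses Welch's method on
0.5 s sliding windows: the tapered periodogram
$|X(f)|^2 / (f_s \sum w[n]^2)$ averaged over non-overlapping segments
(segment length defaults to the whole window), one-sided, so that the
Riemann sum of the density over frequency reproduces the signal variance
(Parseval — this is the test oracle). Band power integrates the density
over half-open bands $\delta$ 0.5–4, $\theta$ 4–8, $\alpha$ 8–12, $\beta$
12–30, $\gamma$ 30–40 Hz, which tile 0.5–40 Hz without overlap. Windows
are timestamped at their right edge (causal convention) and averaged
across channels by default, producing one value per band. The densest
window step (1 sample) is supported but the pipeline default is 0.1 s,
which already oversamples the 1 Hz fusion grid substantially.

**Eye movements.** Cleaning replaces samples that fail the validity flag,
leave the physiological pupil range (1.5–9 mm) or sit more than 5 robust
MADs from the channel median, by linear interpolation (edges held at the
nearest valid value). Those limits are implementation choices; the source
description gives none. Filtering follows the published design exactly:
windowed-sinc FIR filters with Hamming taper — low-pass 8 Hz order 101 and
high-pass 0.1 Hz order 201 at 100 Hz — applied with reflection padding and
group-delay compensation ($(M-1)/2$ samples), followed by a 20-sample
trailing moving average. The printed ideal impulse response is garbled in
the source; the standard windowed sinc (which reproduces the printed
center value $2 f_c / f_s$) is implemented, with the high-pass obtained by
spectral inversion so its DC gain is exactly zero. Note that an order-201
filter at 100 Hz has a transition band of roughly 1.6 Hz, so the "0.1 Hz"
high-pass in fact attenuates all slow structure below about 1 Hz,
including state-dependent mean levels; this is retained as specified, and
it is why the eye channels carry relatively little discriminative signal
in the synthetic study (see below). The high-pass is applied to all eye
channels, the simpler of the two readings of the source.

Locally linear embedding is provided for nonlinear eye-feature
compression: K nearest neighbours, constrained least-squares
reconstruction weights (rows sum to 1, Gram matrix regularized by
$10^{-3} \times$ its trace — necessary for collinear neighbourhoods), and
the eigenvectors of $(I-W)^\top (I-W)$ for the $d$ smallest non-trivial
eigenvalues. Two published details are corrected: the objective needs a
squared norm for the stated eigen-solution to be valid, and forcing $W$
symmetric contradicts the row-sum constraint — standard asymmetric LLE
weights are used, with `symmetrize = TRUE` available. The default fusion
feature set keeps the named eye channels rather than LLE coordinates,
matching how the published feature-importance analyses name their inputs;
`lle_embed()` remains available (defaults K = 12, d = 2).

**Vehicle.** Sliding means of speed and acceleration over 5 s windows
stepped by 1 s (window and step are unstated in the source; these defaults
resolve state dynamics at the 1 Hz grid), population-SD speed fluctuation,
and forward-difference jerk. Only the two sliding means enter the default
fused set, again matching the named features of the published analyses.

**Fusion.** Each stream is aligned to the 1 Hz grid by the trailing mean
over $(k - T, k]$ with $T = 1$ s; rows with any empty window are dropped
and counted. Features are z-scored with *population* moments (matching the
population-SD convention used elsewhere in the method); the moments are
estimated on training data only and serialized with the model. Rows are
labeled from the half-open hypnosis intervals; unlabeled time is the
normal state. The pipeline never rebalances classes — class imbalance is
the model's job.

## The synthetic study

The original driving data are private, so the package ships a generator
whose defaults define the study conditions used by every test:

* 26 recordings of 600 s (matching the session count of the original
  study at a desk-tractable duration), EEG 500 Hz × 4 channels, eye
  100 Hz, vehicle 10 Hz;
* a latent 1 Hz chain with
  $A = \begin{pmatrix} 0.98 & 0.02 \\ 0.10 & 0.90 \end{pmatrix}$,
  giving mean hypnosis episodes of 10 s and a stationary hypnosis
  occupancy of 1/6 — hypnosis is deliberately the minority class;
* EEG channels built as sums of five band-limited Gaussian components
  (filtered with the package's own brick-wall mask, so the generator and
  the extractor agree about what "band" means) whose hypnotic-state SDs
  are $\delta, \theta \times 1.5$ and $\beta \times 0.6$ of normal;
* pupil fluctuations that shrink from 0.25 to 0.08 mm SD (AR(1),
  $\varphi = 0.95$, a \~2 s physiological time constant), gaze velocity
  dropping from 3.5 to 0.8 deg/s (near-fixation), IPD essentially
  constant, ~1% invalid samples to exercise cleaning;
* speed that steadies in hypnosis (SD 1.2 → 0.3 m/s) around a slightly
  higher cruise mean (12.5 → 13.5 m/s).

The effect directions (slow-wave power up, beta down, pupil fluctuation
down, steadier speed) are plausible settings consistent with the
qualitative drowsiness literature; they are configuration, not claims
about the original data, and tests reference the configuration — e.g. the
designed dominant feature (`beta`) must rank in the top 3 by split gain —
never the real-data rankings. What passing tests show is that the pipeline
can learn back the latent structure it assumes (transition recovery within
0.05, held-out Viterbi row accuracy ≥ 0.85 at these separations); they do
not show that real hypnotic episodes are this separable, that EEG noise is
Gaussian or stationary, or that real labels are exact.

## Evaluation and interpretation

`regression_metrics()` implements the six printed formulas (MSE, RMSE,
MAE, maximum error, $R^2$, explained variance; population variances;
$R^2$/EV flagged undefined when the target is constant).
`evaluate_cv()` performs K-fold cross-validation with *recordings* as the
fold unit — row-level shuffling would leak temporally adjacent samples
across the HMM's time axis — and reports per-fold row accuracy, a
segment-level accuracy (majority vote over maximal true-label runs; both
granularities are reported because the source does not say which its
headline accuracy uses), their mean (the printed accuracy formula omits
the $1/K$, but the accompanying text says the fold results are averaged —
the mean is implemented), and the pooled regression metrics of the
hypnosis posterior against the 0/1 indicator.

Interpretation mirrors the published analyses: split-based importance
(total gain / cover / frequency aggregated over all trees of both
per-state scorers, delegating to the boosting library's tree dump),
additive Shapley-style attribution (tree-path contributions; additivity
`base + sum = prediction` is the tested contract), a LIME-style local
surrogate (Gaussian perturbations, RBF kernel weights, weighted least
squares — validated by recovering a linear model's coefficients), an
L1-penalized selection path (own cyclic coordinate descent on the
standard elastic-net-style objective $(1/2n)\,\mathrm{RSS} + \lambda
\lVert\beta\rVert_1$, warm starts, cross-validated penalty; at
$\lambda = 0$ it must and does agree with the normal equations, and an
independent solver is used as a test oracle), and recursive feature
elimination with the boosted scorer. LASSO/RFE target the 0/1 state label
by default; the source leaves the target unstated.

## Numerical choices and conventions

* Time: 0-based sample indices; sample $i$ occurs at
  $t_0 + i/f_s$; all intervals are half-open $[t_1, t_2)$, which avoids
  double-counting at boundaries. Synchronization crops to the common span
  and never resamples, so raw samples stay bit-faithful.
* Emission floor $10^{-12}$; all decoding in log space; Viterbi ties to
  the lower state index.
* Boosting defaults: 200 trees, depth 4, learning rate 0.1, L2 weight 1,
  single thread (deterministic); the source gives no hyperparameters.
* Transition smoothing $\kappa = 1$; with $\kappa = 0$ never-visited
  rows fall back to uniform.
* Degenerate inputs error early and by name: zero-variance features at
  standardization, empty time overlaps, all-invalid eye channels,
  unknown channels/labels/config keys.
* Problem sizes in the test suite: the recovery study runs the full
  26-recording default configuration; unit fixtures use shorter
  recordings (20–200 s) and a 100–250 Hz EEG rate, which keeps the suite
  compact without changing any modelled quantity.

## Limitations

The generator emulates the *statistical* structure the decoder assumes —
state-modulated band variances, AR(1) physiological drift, a first-order
latent chain — not biophysics: no volume conduction or channel
correlation, no artifacts (the pipeline deliberately omits ICA/notch
stages), no route or traffic structure behind the speed series, and
exactly the Markov dynamics the HMM posits, which flatters the decoder
relative to real drives. The published headline accuracies were obtained
on the private 26-session vehicle dataset and are not reproducible here;
the package's quantitative claims are therefore confined to in-package
contracts (worked readout example, oracle equivalences, recovery of the
generator's own structure).
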