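---
title: "Motor-imagery EEG decoding: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-imagery EEG decoding: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcidecode)
```

# The decoding problem

A cue-based motor-imagery brain-computer interface records multichannel
EEG while a subject imagines one of four movements (left hand, right
hand, both feet, tongue). Imagery suppresses the band power of the mu
(8-12 Hz) and beta (18-26 Hz) sensorimotor rhythms over class-specific
cortical areas — event-related desynchronization (ERD). The decoding
chain in this package is:

1. **Preprocessing** — 50 Hz notch, zero-phase IIR band-pass, cue-locked
   epoching.
2. **ORICA** — online recursive independent component analysis separates
   the instantaneous linear mixture of neural and artifact sources
   (ocular, mains) block by block; components correlated with the EOG
   reference channels or concentrated at the mains frequency are removed
   and the rest is back-projected to the channels.
3. **One-vs-rest CSP** — per-class common spatial pattern filters
   maximize each class's band-power contrast against the pooled rest;
   log-normalized variances of the filtered trial are the features.
4. **Classification** — a one-vs-one kernel SVM with Platt posterior
   probabilities; during evaluation an unsupervised, confidence-gated
   rule keeps adapting it. LDA and a global-mean-adaptive LDA serve as
   baselines.
5. **Evaluation** — accuracy, Cohen's kappa, and the Wolpaw information
   transfer rate (ITR), aggregated over subjects/seeds.

Everything is testable offline because the package ships its own
synthetic EEG generator with known ground truth.

# The synthetic generator

`simulate_recording()` lays out trials (default 4 s imagery, 2 s rest,
cue event at trial onset) in seeded random class order and mixes latent
sources through a full-column-rank matrix:

* **Rhythms** (`mu_rhythm`, `beta_rhythm`): narrowband Gaussian noise
  around the centre frequency, multiplied by a slowly varying positive
  envelope `1 + g^2/2` (`g` low-pass Gaussian). The envelope makes the
  oscillation super-Gaussian (kurtosis ~ 8), which is what ICA's
  non-Gaussianity contrast needs, while keeping short-window power
  estimates stable enough that ERD ratios can be verified on 2-s epochs.
  ERD is a multiplicative envelope gain during that class's trials
  (default 0.4, i.e. band power scaled by 0.16), applied to one mu source
  per class.
* **Ocular artifact** (`eog_blink`): Poisson blink train (0.25/s). Each
  blink is a slow lid-closure pulse (sigma 50 ms) plus a fast eyelid
  transient (sigma 12 ms), so ocular energy genuinely overlaps the mu
  band the way real blink/saccade edges do. Default amplitude 150 uV RMS
  at the source: blinks in real recordings dwarf the ~10 uV rhythms.
* **Line noise**: fixed 50 Hz sinusoid. **Background**: 1/f noise.
* **Mixing**: Gaussian random matrix, singular values clamped to a
  condition-number cap (default 30). The blink source loads strongly
  (and positively) on the EOG channels and weakly on EEG channels;
  white sensor noise is scaled to a target SNR against the mixed neural
  signal (default 10 dB). Under `drift_rate > 0` the matrix moves
  linearly along a fixed random unit-Frobenius direction, so
  `||A(t) - A(0)||_F = drift_rate * t` exactly; the recording is mixed
  piecewise per second.
* **Sessions**: a simulated "subject" is a `mixing_seed`; two sessions
  share the mixing (same head, same montage) but draw fresh source
  realizations, trial orders, and sensor noise. Session 2 continues the
  drift clock (`t_start`).

What the generator does **not** emulate: volume-conduction forward
models and electrode geometry, non-ocular artifact families (muscle,
cardiac, electrode pops), non-stationarities other than linear mixing
drift, and any dependence of artifact statistics on the task. Passing
the synthetic benchmarks therefore shows the pipeline recovers what this
model puts in — not that it reaches any particular accuracy on real
recordings.

# ORICA

Blocks of `block_size` samples (default 8) stream through two recursive
updates with a shared forgetting factor
`u_i = max(u0 / (i+1)^gamma, u_min)` (defaults `u0 = 0.2`,
`gamma = 0.6`, `u_min = 1e-4`): large early for fast convergence, small
late for low-variance tracking. With the block's entry state, `v = X x`
and `a = W v`; the rank-one terms are replaced by their block averages:

* whitening: `X <- X + u/(1-u) [I - <v v'> / (1 + u(<v'v> - 1))] X`
* demixing (recursive rule):
  `W <- W + u/(1-u) [I - <a f(a)'> / (1 + u(<f(a)'a> - 1))] W`
* demixing (gradient rule): `W <- W + lr [I - <f(a) a'>] W`

A running mean under the same schedule is removed before whitening.
Activations are emitted with each block's entry state, so processing is
strictly causal per block.

**Choice of nonlinearity.** The two demixing rules differ in the
orientation of the rank-one term (`a f(a)'` vs `f(a) a'`), and the
orientation decides which contrast is stable. Empirically (and
consistently across seeds), with the recursive rule's `a f(a)'` the
separating fixed point for super-Gaussian sources is stable for the
cubic contrast `f(a) = a^3` and unstable for `tanh` — mixtures stay
unseparated with `tanh` (Amari index at chance) and separate cleanly
with the cube (median Amari ~ 0.03 on 4-source mixtures). The gradient
rule shows the mirror behaviour. The default is therefore `cubic` for
the recursive rule; `tanh` remains available and suits the gradient
variant.

**Numerical guards.** Optional row renormalization of `W` bounds norm
inflation on long quiet stretches; updates that produce non-finite
state raise an error naming the block iteration. Back-projection uses
the Moore-Penrose pseudo-inverse of `W X`, so rejecting nothing
reproduces the input to numerical tolerance.

**Artifact flagging.** A component is ocular if its absolute
correlation with any EOG channel exceeds `corr_threshold` (default
0.3), and mains-contaminated if more than `line_frac` (default 0.5) of
its periodogram power sits within 1 Hz of 50 Hz. In the pipeline the
cleaning runs on notched **broadband** data, before band-passing:
band-passing first would strip the ocular signal out of the EOG
reference channels and leave the correlation criterion pointing at
neural components. A fresh ORICA state gets two convergence passes over
the training session before components are judged; the evaluation
session continues from the converged state with a single pass.

# One-vs-rest CSP

Per class, trials are concatenated and the spatial covariance is
trace-normalized (`S_k`, unit trace; shrinkage `1e-6` towards the
scaled identity, raised with a warning on rank deficiency). The
composite `Sc = sum_k S_k` is whitened by `M = D^{-1/2} Uo'`; since
`S_k + S_k' = Sc`, the whitened class covariance `W_k = M S_k M'` and
its rest-complement satisfy `W_k + W_k' = I`, so the eigenvectors of
`W_k` with the largest eigenvalues are the directions where class k has
the most variance relative to the pooled rest. The top `m` (default 2)
filters per class, `P_k = U_k' M`, stack into the bank `Ps`; features
are `fv_m = log(V_m / sum V)` with `V_m` the per-filter variance, so
`sum(exp(fv)) = 1` by construction. Eigenvector signs are fixed
(largest-magnitude coefficient positive) and eigenvalue ties break by
original index, for bit-reproducibility.

`refine_filters()` re-ranks each class's candidate filters by the
Fisher ratio of per-trial log-variance across classes. On synthetic
data it raises in-session (cross-validated) class contrast, but it
selects against session-specific structure and transferred *worse* to a
held-out session in our benchmarks, so the pipeline leaves it off by
default and exposes it as an option.

# Classifiers and adaptation

`train_svm()` fits one-vs-one kernel SVMs (libsvm via e1071; default
sigmoid kernel `tanh(gamma <x, x'>)` with `gamma = 1/d` on
standardized features — a unit-scale sigmoid saturates on raw
log-variance features) and calibrates a Platt sigmoid per pair on
3-fold cross-validated decision values; in-sample calibration is
optimistically biased. Folds are assigned positionally within class, so
training is deterministic and invariant under class renaming. Pairwise
posteriors are coupled by the standard constrained least-squares
pairwise-coupling system; the label is the posterior argmax.

The adaptive rule is unsupervised self-training with a confidence gate:
a streamed sample whose winning posterior exceeds `th` (default 0.7)
joins the working set under its *predicted* label and all pairwise
machines are refit on the working set — initial support vectors plus
gated samples, FIFO-capped (default 500) so memory stays bounded
regardless of stream length. Initial support vectors are never evicted
and Platt parameters stay at their initial fit: recalibrating a sigmoid
on self-labelled, gate-selected samples would feed the classifier its
own confidence back. At `th = 1` nothing is ever accepted and the
adaptive classifier is bit-identical to the static one.

LDA stores class means, pooled covariance (optional shrinkage), priors,
and the global feature mean. Its unsupervised adaptation shifts all
class means by the global-mean displacement
`mu_g <- (1 - eta) mu_g + eta x` (default `eta = 0.05`, roughly a
20-trial memory), never touching labels or covariance.

# Evaluation

Cohen's kappa is `(p_o - p_e)/(1 - p_e)` from the confusion matrix; ITR
uses the Wolpaw bits-per-trial
`log2 K + P log2 P + (1-P) log2((1-P)/(K-1))` times the trial rate. The
trial rate is an explicit parameter; the pipeline derives it from the
simulated trial spacing (`60/(trial_sec + rest_sec)`) and reports it in
the run record. Aggregation tables round their mean row half away from
zero at the table's printed precision, computed on unrounded values.
The per-subject kappa/accuracy/ITR tables of the published four-class
benchmark (BCI Competition IV dataset 2a, nine subjects) are shipped as
example data; note that two of their printed mean entries do not equal
their own column averages (the kappa mean of the proposed method, and
the accuracy mean row), which the package simply recomputes.

# The experiment harness and its benchmark sizes

`run_experiment()` crosses feature methods with classifiers per seed:
session 1 trains, session 2 evaluates; adaptive classifiers adapt only
during evaluation and never see a label. All randomness derives from
the seed, so a config + seed pair reproduces every number exactly
(`config_hash` in the run record).

Problem sizes used by the package's own acceptance benchmarks were
chosen to keep a full run on a single CPU comfortable while leaving the
statistical conclusions stable:

* separation: 4-channel square mixtures of i.i.d. unit-variance Laplace
  sources, 20 000 samples, 20 dB SNR, 10 seeds. (The generator's
  envelope-modulated rhythms are unsuitable for the whitening check:
  their variance fluctuates slowly, so a finite-window covariance
  estimate fluctuates by ~0.1 regardless of whitener quality.)
* end-to-end: the generator's default montage (22 EEG + 3 EOG channels),
  72 trials/class, ERD gain 0.4, SNR 10 dB. Channel count matters here:
  with 22 channels the class covariances have more parameters per trial
  and artifact energy disperses over more candidate filters, so artifact
  removal measurably helps; on small montages (10-14 channels) CSP is
  nearly artifact-immune and cleaning is neutral.
* drift: 10-12 channels, `drift_rate` 0.005/s, i.e. roughly a third of
  the mixing's Frobenius norm over a two-session experiment — enough
  nonstationarity that static classifiers measurably degrade.

On stationary artifact-contaminated data with few channels, removing
the blink component neither helps nor hurts CSP materially: blink
contamination is class-independent and spatially rank-one, so composite
whitening absorbs it, while component removal back-projects the
component's small impurity with the blink's large spatial pattern. The
benefit of cleaning grows with the montage (more covariance parameters,
wider artifact dispersion) and in nonstationary regimes. One tracking
limit is worth knowing: the annealing forgetting schedule converges
rather than tracks — under continuous mixing drift the floor `u_min`
bounds how fast the demixing can follow, and at the default `1e-4` the
artifact subspace is lost for drift rates beyond roughly a tenth of a
percent of the mixing norm per second. Raising `u_min` trades steady-state
variance for tracking speed.

# Known limitations

* EDF/GDF readers are declared but not bundled; the native bundle
  (CSV + JSON sidecar) is the format of record.
* The incremental SVM is a warm refit on the capped working set, not an
  exact dual update; exactness was traded for the working-set bound.
* The generator's artifact model covers ocular and mains sources only.
* ICA indeterminacies (component order, sign, scale) are resolved only
  where determinism requires it; diagnostics that need ground truth
  (Amari index) are scale- and permutation-invariant by construction.
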