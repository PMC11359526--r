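---
title: "Detecting short-term stress in wearable EDA: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting short-term stress in wearable EDA: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Acute stress leaves a fast, reliable trace in electrodermal activity (EDA):
within a few seconds of a stimulus the skin conductance rises (a phasic skin
conductance response, SCR) on top of a slowly drifting tonic level, and
decays back over several more seconds. `stressdge` detects these moments of
stress (MOS) in 16 s windows of wrist-worn sensor data (EDA in microsiemens
and skin temperature in °C, sampled at 4 Hz), classifies each window with a
small LSTM, explains the classifier with Integrated Gradients, and scores
detections at the event level against the known stimulus times of a
laboratory protocol.

Because no public dataset provides second-level stress labels, the package
ships a first-class simulator of the laboratory study design it targets:
sessions of 15–22 minutes in which 10 audio stressors are delivered at
random inter-stimulus intervals of 52–125 s, recorded from a cohort of 28
subjects. All tests and the acceptance report run end-to-end on this
synthetic world.

# The simulator: what it emulates, and what it does not

A session is a `stimulus_protocol` (baseline phase, then stressors with
i.i.d. uniform gaps) plus per-subject physiology (`phenotype`):

* **SCR kernel.** The literature describes an SCR by three features:
  latency (stimulus to onset), rise time (onset to peak) and recovery. No
  functional form is canonical in the study design we emulate, so we use a
  Bateman-style bi-exponential whose fast time constant is solved
  numerically so the peak falls exactly at `latency + rise`, normalized to
  the requested amplitude. Defaults (latency 1–2.5 s, rise 1.5–3.5 s,
  recovery 4.5–7.5 s, amplitude 0.3–0.9 µS) keep the response inside the
  16 s analysis horizon.
* **Non-responders.** Each stimulus elicits an SCR with probability
  `responder_prob`. The "hard" preset fixes it at 0.4, the phenotype in
  which only 4 of 10 stressors are visible in the signal; no detector can
  exceed that ceiling, which is exactly what the hard-cohort acceptance
  test demonstrates.
* **Spurious peaks.** Spontaneous SCRs are placed by a homogeneous Poisson
  process (`spurious_rate` per minute, amplitudes 50–100% of the subject's
  SCR amplitude); they are the mechanism that depresses precision.
* **Tonic level and drift**, Gaussian sensor noise, and a skin-temperature
  channel whose post-stimulus slope defaults to **zero** effect size — so
  the finding that temperature contributes little is reproducible by
  construction, and the attribution test can assert EDA ≫ ST relevance.
* Session durations are drawn in 15–22 min and the gap set is redrawn until
  the protocol fits (the real sessions end when the protocol ends). The
  unconditional gap distribution is tested on `gen_protocol`, where gaps
  are plain `U[52, 125]` draws (mean 88.5 s, close to the reported 86 s
  average of the emulated protocol).

Not modeled: sweat-gland biophysics, motion artifacts, sensor dropout,
inter-channel coupling. A green end-to-end test therefore establishes that
the pipeline recovers the stated statistical structure — not that it would
reach the same numbers on human data.

# Signal processing

The chain is low-pass denoise → 0.05 Hz first-order high-pass (phasic
extraction) → downsample 4→1 Hz → per-session standardization → sliding
16 s windows.

* Butterworth designs are computed from the analog prototype via bilinear
  transform (validated against SciPy to machine precision during
  development); the denoising low-pass defaults to order 4, cutoff 1 Hz.
* All filtering is **zero-phase** (forward–backward with odd-reflection
  padding). The attribution analysis reads timing off the window axis, so
  phase distortion would bias it; this is why we do not use causal filters.
* Standardization uses the **population** standard deviation over the full
  session per channel; constant inputs return zeros with a warning.
* The skin-temperature band is the same 0.05 Hz high-pass by default
  (configurable); the upstream references for the exact band are not
  reproducible from the available text.
* Window labeling: a window is positive iff its start lies in
  `[t − 2 s, t + 6 s]` of a stressor `t`, mirroring the asymmetric event
  evaluation window. Stride defaults to 1 s for evaluation; training sets
  may use stride 2 s purely for cost.

# The classifier

A single-layer LSTM with the printed gating equations: input, forget and
output gates are sigmoids of affine maps of the input and previous hidden
state; the cell input `z_t` **also uses a sigmoid by default** (as printed
in the source equations; `cell_act = "tanh"` restores the classical
variant). The cell update is `c_t = f_t ⊙ c_{t−1} + i_t ⊙ z_t` and
`h_t = o_t ⊙ tanh(c_t)`; a sigmoid readout of the final hidden state gives
the stress probability. Initialization: orthogonal recurrent matrices,
xavier-uniform input weights, zero biases except the forget-gate bias of 1.
Training minimizes class-weighted binary cross-entropy (weight
`n_neg/n_pos`) with Adam, early-stopping on a subject-level validation
split. Augmented or synthetic copies of validation subjects' windows are
excluded from training to avoid leakage. There is no deep-learning runtime
in the target environment, so the forward pass, backprop-through-time and
Adam are implemented in vectorized base R; the analytic gradients are
checked against finite differences to 1e-4 relative error, and the
recurrence against an independent scalar-loop oracle to 1e-6.

Defaults (hidden 8 units, lr 1e-2, batch 128, patience 5–10) were chosen
for the synthetic task's scale; the grid-search helper performs
subject-level k-fold CV, selecting by mean F1 with ties broken by recall
then model size.

# Augmentation and the Deep Generative Ensemble

Positive windows are augmented by `scale·x + ε` with
`scale ~ U[0.8, 1.2]` and `ε ~ N(0, 0.05²)` in standardized units. A
class-conditional generative model adds synthetic windows; two backends:

* `cgan`: one-hidden-layer MLP generator and discriminator over flattened
  windows with a ±1 label input, non-saturating adversarial loss, and a
  per-class feature-matching (batch-mean) term in the generator loss.
  Minibatches are class-balanced — without both stabilizers the
  conditional mean drifts at this data scale.
* `bootstrap`: parametric resampling from the class pools (scale + noise).
  Deterministic and cheap; the default for CI and the end-to-end tests, so
  that the DGE logic is exercised without adversarial flakiness.

The DGE trains K classifiers (K = 5 by default), each on real + augmented
+ synthetic data generated under a member-specific seed (1:1:1 positive
mixing), and averages the K probabilities. An optional outer homogeneous
ensemble of M such models (differing only in seed) is provided as a
separate layer, since the two constructions are distinct objects.

# Explanation

Integrated Gradients along the straight-line path from the zero vector (in
standardized units, i.e. the session mean) to the window, right-Riemann
approximated with 128 steps by default. The completeness identity
`ΣIG = F(x) − F(baseline)` is recorded per map and must fall below 1% of
the output difference at 512 steps. Ensemble attribution is defined as the
mean of member attributions, which for an averaged-probability ensemble
equals the attribution of the ensemble output. Global maps average the
per-window maps over all stress windows of a test set; signed scores are
kept.

# Event-based evaluation

Window probabilities are thresholded (0.5) and merged: predictions within
8 s of a cluster's first member collapse into one MOS. A prediction matches
a reference stressor if it lies in `[r − 2 s, r + 6 s]`; matching is
earliest-first and one-to-one. Every unmatched reference is a false
negative (so TP + FN always equals the number of stressors); an unmatched
prediction with no reference within 8 s is a false positive, and unmatched
predictions near an already-taken reference are dropped as ambiguous
(reported separately). True negatives are counted over non-overlapping 8 s
slots containing neither predictions nor references, which reproduces the
high-accuracy scale typical of rare-event detection.

Two deliberate choices deserve emphasis:

* **Cluster representative.** `merge_predictions` keeps the earliest
  member by contract, but probability-derived event streams use the
  **cluster median**: at 1 Hz the run of firing windows begins at the very
  edge of the −2 s matching bound, so the earliest member flips between
  hit and miss with the sub-second fractional part of the true stressor
  time. The median sits near the window center and is insensitive to that
  artifact. This was adopted after observing recall 0.4 on a noiseless
  cohort in which all ten events were visibly detected ~2 s early.
* **FN definition.** The conservation property TP + FN = #references is
  enforced exactly; the "no prediction within 8 s" phrasing is reflected
  in which unmatched *predictions* count as FP.

Greedy earliest-first matching is compared against an optimal bipartite
matching (igraph) on randomized configurations; on interval instances of
this shape it is optimal, and the tests tolerate at most one event of
discrepancy per configuration.

# Numerical and degenerate-input choices

Filter warm-up requires signals longer than 3× the filter order; shorter
inputs error. Undefined metrics (e.g. precision with no predictions) are
`NA`, never 0. All stage seeds derive deterministically from one global
seed plus the stage name and stay below 2³¹. Training is single-threaded
deterministic given the seed.

# Known limitations

* The cGAN is a deliberately small MLP; it reproduces class-conditional
  means and peak placement, not the full waveform distribution.
* Hyperparameters were not tuned per cohort; the grid-search helper exists
  but the default experiment uses fixed settings for runtime.
* The simulator's spurious SCRs share the stimulus-evoked kernel shape;
  real between-stimulus peaks are more heterogeneous, so synthetic
  precision is optimistic.
* Reported human-data metrics of the emulated study (recall ≈ 0.76,
  precision ≈ 0.36) are not reproducible here because that dataset is
  unreleased; the package's end-to-end numbers characterize the synthetic
  world only.
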