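---
title: "Curriculum shaping, network dynamics and time decoding: methods"
author: "tdnmsRNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curriculum shaping, network dynamics and time decoding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and procedures: the
task and its layout on the time grid, the network and its training, the
behavioural scoring rules, the dynamical-systems analyses, the decoding
pipeline, and the synthetic spike-population generator — together with every
numerical choice that was genuinely open and the reasoning behind it.

## The tDNMS task on a discrete grid

A trial lasts 20 s discretised into 200 bins of `dt = 0.1` s. Events land
exactly on bin boundaries, and the two input channels are one-hot before
noise: channel 1 carries a 0.2 s start cue at t = 0, channel 2 the timed
cue(s). The default layout, chosen once and fixed:

* first timed cue onset at 3 s (the cue is preceded by a quiet baseline, as
  in head-fixed protocols where a brief light announces the trial a few
  seconds before the first stimulus);
* cue durations: short 2 s, long 5 s, probe "medium" 3.5 s, probe XL 10 s;
* interstimulus interval 3 s;
* response window: the 3 s immediately following the final cue offset;
* target: a boxcar of amplitude 1.0 spanning the response window on Go
  trials, identically zero on the SS match trial. The amplitude is a free
  scale absorbed by the linear readout, so 1.0 is a pure convention.

The longest standard trial (LS: 3 + 5 + 3 + 2 + 3 s) ends at 16 s; the
remaining 4 s are quiet and give the network room after the window. Inputs
are corrupted with i.i.d. N(0, 0.15) noise on every bin of both channels.
Blocks of 4 trials hold an exact trial multiset — 2 SS + 1 SL + 1 LS on the
full task, 2 SL + 2 LS during non-match shaping, four copies of one type in
single-type shaping — shuffled uniformly, with fresh noise per trial. Probe
blocks hold 5 trials (2 SS, 1 SL, 1 LS, 1 probe), so probes are 20% of a
probe session. Probe non-match slots use one SL and one LS, matching the
full-task balance.

## Network and training

Units follow the leaky update
$h_{t+1} = (1-\gamma)h_t + \gamma\tanh(W_{in}x_t + W_{rec}h_t + b + \xi_t)$
with $N = 128$, $\gamma = 0.2$, private noise $\xi_t \sim N(0, 0.3)$ injected
inside the activation argument, and a memoryless readout
$y_t = w_{out}\cdot h_t + b_{out}$. The recurrent matrix is initialised as a
random orthogonal matrix (QR with the sign convention making it unique);
input weights are uniform on $[-1/\sqrt N, 1/\sqrt N]$; the readout starts at
a small uniform ($[-0.1/\sqrt N, 0.1/\sqrt N]$) so early outputs are near
zero; biases start at zero. The uniform bounds are conventions — only
"uniform" and "orthogonal" are structural — and are recorded in the
configuration.

The loss per trial is the mean over bins of the squared output error plus
$\lambda$ times (the mean squared hidden activation + the summed squared
entries of $W_{in}, W_{rec}, w_{out}$), $\lambda = 10^{-3}$. Averaging over
bins (rather than summing) keeps one $\lambda$ meaningful for both penalty
terms. Biases carry no weight penalty. All five parameter groups are
trainable. Gradients are exact backpropagation through time (the compiled
core is checked against central finite differences to a relative error below
$10^{-4}$ in the test suite), clipped at global norm 10 — a guard for the
200-step horizon that is rarely triggered after the first blocks — and
applied with Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8), two consecutive trials
per batch, two batches per block, optimiser state persisting across phase
boundaries.

**Step size.** Adam moves each parameter by at most roughly the step size per
update. A training run of B blocks provides 2B updates, so the total
displacement available to any parameter is ~2Bα. The readout must grow from
its near-zero initialisation to order $1/\sqrt N \approx 0.1$ to emit a
unit-amplitude response, which for runs of a few hundred to a thousand blocks
requires α of order $10^{-3}$ — Adam's conventional default, and the package
default. Step sizes two orders smaller leave every trial type
indistinguishable at these run lengths (we verified this directly: all peak
outputs stall near 0.2).

**Scale.** Full-scale training is 1000 blocks with shaping, when used,
replacing the first 300. All cohort analyses in the tests and the acceptance
script run at *reduced scale* — 100 shaping + 250 full-task blocks, cohorts
of 4 seeds — chosen so that a full cohort comparison trains in minutes on one
CPU. At this scale the shaped/unshaped contrast is already unambiguous:
shaped networks reach block MSE ≈ 0.01 and solve all three trial types,
unshaped networks plateau near 0.05 with sub-threshold Go responses.

The hidden state resets to zero at every trial start: trials are shuffled
independently, so carrying state across them would make trials
non-exchangeable, which the decoding procedure (folds split by trial)
assumes.

## Behavioural scoring

A "response" is any bin with $y_t \ge$ threshold; the default threshold is
0.5, half the target amplitude, applied to noise-free or noisy output alike.
On Go trials a trial is correct iff a response occurs inside the response
window and none occurs before the second cue's onset (before the single
cue's offset on XL); on SS any response anywhere is an error. An agent that
responds after every long cue and never otherwise therefore scores all SL
and SS trials and no LS trials — exactly 75% of a {SS, SS, SL, LS} block,
an arithmetic identity the acceptance suite checks. Unshaped networks admit
no clean threshold (their correct and erroneous response amplitudes
overlap), so alongside binary scores the package always reports peak outputs
and full sweep curves. Strategy labels use cutoffs 0.9/0.1 on per-type
accuracy; they label sessions for inspection and never enter statistics.

Cue-duration sweeps build noise-free trials with one cue duration replaced
(durations snapped to the bin grid), record the peak output in the 3 s
window after the final cue offset, and report the smallest duration whose
peak crosses the threshold.

## Dynamical-systems analyses

**Tangling.** $Q(t) = \max_{t'} \|\dot x_t - \dot x_{t'}\|^2 /
(\|x_t - x_{t'}\|^2 + \epsilon)$ with backward-difference derivatives at
$\Delta t = 0.1$ s and $\epsilon$ = 0.1 × the mean squared state magnitude
over the full supplied set (one joint ε, not per trajectory). Tangling is
computed on the full 128-dimensional hidden state ("the recurrent layer"),
not on a PCA reduction; when rows from several trials are stacked, the
derivative across trial boundaries is dropped. The implementation is
chunked but algebraically identical to the O(T²) double loop; the tests
assert exact equality up to T = 500.

**Fixed and slow points.** Candidates are every 5th state of the noise-free
SS/SL/LS trajectories plus 50 random convex combinations of pairs of them.
With the input clamped (cue_on: timed channel 1; cue_off: all zero; the
start channel is 0 in both modes, since the start cue is brief and identical
across trials), the squared speed $q(h) = \tfrac12\|F(h)\|^2$ of the
one-step displacement is minimised by Adam jointly over all candidates
(1500 iterations, step 0.02), then candidates with $q < 10^{-3}$ receive a
Newton polish on $F(h) = 0$, which converges to machine precision near
regular roots. Points with $q < 10^{-6}$ are accepted, merged within a
Euclidean tolerance of $10^{-2}$ (merged members share their stability
class), classified by the eigenvalue moduli of
$J = (1-\gamma)I + \gamma\,\mathrm{diag}(1-\tanh^2 a)\,W_{rec}$
(|λ| vs 1 at tolerance $10^{-4}$: stable / unstable / saddle / marginal),
and validated by a 200-step free run that must move less than $10^{-3}$.
Candidates failing the q threshold or the validation are reported with their
final q, never dropped: slow points are data, not failures.

**Limit cycles.** Starting from the end state of a noise-free SL trial, the
network free-runs with clamped input; the first 25% is discarded as
transient. The detector searches for the smallest lag τ at which the whole
remaining window recurs, $\max_t\|h(t+\tau)-h(t)\| <$ tol, with tol = 1% of
the window's mean state norm. A window that never leaves its final state is
stationary (a fixed point, not a cycle), and a "recurring" window whose
orbit diameter is below 5× tol is a contracting spiral caught mid-decay;
both return absent. The default run is twice the trial length (400 bins);
the cohort analyses use 2000 bins because these attractors are approached
slowly — on shaped networks the achievable closure drops by an order of
magnitude between 400 and 2000 bins while unshaped networks remain
stationary, so the longer run sharpens the dichotomy without biasing it.
Detected periods can be an integer multiple of the fundamental orbit when
the rotation number is not locked to the bin grid; the hand-built-oscillator
test checks exactly this invariant.

**PCA geometry.** Two views are deliberately distinguished.
`pcaGeometry(average = TRUE)` averages within trial type before PCA — the
view for displaying task-locked geometry, for cross-projection of an earlier
checkpoint into the final network's space, and for pseudo-population tuning
curves. For *dimensionality* of task activity the package pools unaveraged
single-trial states from noisy sessions: the excess dimensionality of an
unshaped network lives in its noise-driven single-trial excursions, which
averaging would remove (trial averages of both cohorts are similarly
low-dimensional; pooled single-trial states separate them decisively).
Cross-projection centres source states by the target PCA mean and projects
onto its loadings. Flow fields embed a lattice on a PCA plane (off-plane
coordinates held at the projection of a reference state, by default the PCA
mean), advance one noise-free clamped step, and project the displacement
back; they are illustrative, and the reference is always recorded.

## Time decoding

A session of 15 noisy full-task blocks (60 trials) is split into 10 folds by
trial, balanced within trial type so every fold contains every type. Per
fold, four linear-discriminant classifiers are trained on the training
trials' bins — one per trial type and one on all types — with elapsed time
rounded to the nearest second as the class label (21 labels on a 20 s trial
at bin centres). Each classifier is evaluated on all held-out trials;
matched train/test types pool into the within-context mean absolute error,
mismatched into the across-context error; the all-types decoder is reported
separately. No bin of a test trial ever enters training, and cells missing
from a fold are recorded as missing rather than imputed.

The discriminant uses a pooled within-class covariance shrunk toward its
diagonal (default 10%), keeping it well-posed when units are strongly
correlated or samples are scarce; at shrinkage 0 it reproduces standard LDA
(checked against an independent implementation). Mean absolute error in
seconds is the headline metric; full confusion tensors are always returned
so any alternative is recomputable. RNN activity is decoded unsmoothed —
temporal smoothing belongs to the spike pipeline.

## Synthetic spike populations

The generator emulates the statistics the neural pipeline must handle, with
defaults chosen once as field-realistic: 64 units whose Gaussian temporal
fields (σ = 1.5 s) tile the 20 s trial, peak 15 Hz over a 0.5 Hz baseline,
per-trial field-centre jitter of 0.3 s, and 20% non-task-responsive units at
pure baseline. `sharing_mode` switches between an abstract time code (one
field per unit across all trial types) and a context-specific code (an
independent centre per type) — the axis the cross-context decoding analyses
probe. Spikes are inhomogeneous Poisson at 1 ms resolution (count drawn from
the intensity integral, times from the normalised intensity), which the
tests validate against Poisson count statistics.

Preprocessing mirrors a standard post-sorting pipeline: 0.5 s bins, Gaussian
smoothing with σ = 2 s truncated to an 8 s window — the kernel is
renormalised within the window (and at trial edges) so flat inputs stay
flat — then per-unit z-scoring over the pooled session, with spikeless units
flagged instead of divided by zero. Task-responsive units are those whose
mean trial-to-trial Pearson correlation exceeds 0.25; the threshold is a
correlation coefficient, the only reading under which a retention rule makes
sense. Pseudo-populations are built on 4 disjoint trial splits (balanced
within type): per split, per-type trial-averaged tuning curves are
concatenated over types, PCA is run per split, and cohorts are down-sampled
to equal unit counts before comparison.

What the generator does *not* emulate: refractoriness, firing-rate
adaptation, correlated noise across units, theta-band modulation, drift
across a session, or any relation between spiking and the animal's
behavioural output. Passing tests therefore show that the *pipeline*
(selection, smoothing, decoding, dimensionality) behaves correctly and in
the directions the abstraction hypothesis predicts — not that real cortical
populations have these statistics.

## Cohort experiments and statistics

`runCohortComparison` trains every (curriculum, seed) pair of a plan and
runs the chosen analyses on each network; failed seeds are flagged and
statistics computed on completers. Between-cohort comparisons use Welch
t-tests per metric, one-way analysis with Tukey honest-significant-difference
correction when more than two cohorts are present, and a two-way mixed-design
ANOVA (cohort × number of PCs, networks as the repeated-measure unit) for the
cumulative variance-explained curves. These are the standard base-R
procedures (`t.test`, `aov`, `TukeyHSD`), wrapped, not reimplemented.
Identical plans reproduce identical tables; every stochastic step is
governed by the plan's seeds.

## Problem sizes and determinism

The test suite trains 4 shaped + 4 unshaped networks at reduced scale and
reuses them across analyses; sessions are 15 blocks for decoding and
dimensionality, 20 trials for tangling, free runs 2000 bins for cycle
detection, and two 60-trial synthetic populations for the spike pipeline.
The acceptance script trains three shaped networks from seeds derived from
its `--seed` argument and reports the median second-cue threshold-crossing
duration. Every random draw in the package flows through R's global RNG, so
`set.seed` (or the recorded seeds in configs and plans) makes any quantity
in this document exactly reproducible.

## Known limitations

* Reduced-scale cohorts make direction-of-effect claims; effect *sizes*
  (decoding errors, tangling magnitudes, cycle periods) shift with training
  length and seed.
* The fixed-point census reports points reachable by descent from
  task-visited candidates; structures far from the task manifold are out of
  scope by design.
* Limit-cycle detection is recurrence-based: quasi-periodic attractors are
  reported at a near-commensurate lag, and orbits with periods beyond half
  the analysis window are missed.
* The cue-duration threshold is resolved at the 0.1 s sweep grid.
* Unshaped networks admit no principled Go threshold; all threshold-based
  summaries for them inherit the declared 0.5 convention.
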