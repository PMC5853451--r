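---
title: "Closed-loop auditory stimulation of sleep slow oscillations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop auditory stimulation of sleep slow oscillations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(socloop)
```

## The problem

During deep (N3) sleep the cortex produces slow oscillations (SO): large
(~75 µV and above) waves at roughly 0.5–1.2 Hz. Playing a short, quiet sound
exactly on the ascending slope of an SO tends to amplify the following
oscillations; stimulating at the wrong phase does not, and stimulating
outside N3 risks waking the sleeper. A closed-loop stimulator therefore needs
four real-time decisions from a noisy two-channel frontal EEG: *is the signal
usable*, *which channel is better*, *is the sleeper in N3*, and *what is the
instantaneous SO phase right now*. `socloop` implements that pipeline, the
offline procedures used to audit such a device (two-device clock
resynchronization, confusion-matrix staging metrics, circular phase accuracy,
event-related delta-power statistics), and a labeled sleep-EEG simulator that
makes every stage testable without human recordings.

## Pipeline

Each EEG channel is first passed through a causal acquisition cascade: a
4th-order Butterworth band-pass at 0.4–18 Hz, 6th-order Butterworth
band-stops at 58–62 Hz and 48–52 Hz (both power-line standards), and a
2nd-order Bessel band-stop at 62–63 Hz (a hardware calibration tone). The
printed orders are realized as overall filter orders. No `besself`-style
designer exists in the `signal` package, so the Bessel stage is built from
the analog order-2 Bessel prototype (poles of $s^2 + 3s + 3$), transformed
low-pass→band-stop with prewarped edges and digitized bilinearly. Causal
filtering carries explicit state (compiled direct-form II transposed), so
chunked streaming equals batch filtering to ~1e-9; an NaN sample resets the
state, preventing transients from leaking across detached-electrode gaps —
the gap policy is ours, the source material being silent on it.

**Quality gate.** Every 0.5 s, a feature vector of the trailing 2-s window of
each filtered channel (amplitude range/SD/kurtosis, clipping fraction,
flatline fraction, power-line ratio, low-frequency drift ratio, NaN
fraction) feeds a probability forest that returns a quality index
$q_i \in [0,1]$. The original device's forest and its expert-labeled corpus
are proprietary, so ours is trained on simulator-labeled windows; the
features are documented substitutes for unpublished ones. An all-NaN window
scores 0 by convention.

**Channel switcher.** A hysteresis switch with dead band $\theta$ (default
0.2): $s(t) = 1$ if $q_1 - q_2 > \theta$, $s(t) = 0$ if $q_1 - q_2 < -\theta$,
otherwise the previous state is held. Equality with the dead-band edge is
treated as "hold", since the strict inequalities of the printed rule leave it
undefined. The selected channel's samples form the *virtual channel*; a
sample is NaN whenever the selected channel's quality is below the gate
threshold (default 0.5) — in particular whenever both channels are bad, in
which case the device never stimulates. Both thresholds are configurable
because no published values exist.

**N3 gate.** Every 30-s epoch of the virtual channel yields: relative
spectral power in 0.4–4 / 4–8 / 8–12 / 12–18 Hz (normalized over the
0.4–18 Hz total; the bands are stored under frequency-range names, since the
Greek labels attached to them in print are likely misprints), normalized
permutation entropy (order 3, delay 1; ties broken toward first occurrence,
so constant signals give a single pattern and entropy 0), two complexity
measures chosen by us where the original list is unspecified (Higuchi
fractal dimension, spectral entropy), counts of detected spindles (11–16 Hz
envelope above 3× the epoch median for 0.5–2 s) and slow oscillations
(upward zero-crossing pairs of the delta-filtered signal, 0.5–2 s apart,
trough-to-peak ≥ 75 µV), and accelerometer activity. A probability forest
trained on simulated nights classifies N3 vs everything else; epochs with
more than 50% NaN are unscorable and never N3 (our rule). The decision
threshold is tuned on held-out simulated epochs to maximize specificity
subject to sensitivity ≥ 0.5, preferring the higher threshold on ties —
false positives are sounds played to a non-N3 sleeper, false negatives only
missed opportunities. Epochs are classified independently; decisions update
only at epoch ends, so an epoch's decision governs the following epoch.

**Hard safety conditions.** Stimulation requires: ≥ 15 min since the first
N3 detection; no large movement (acceleration magnitude > 0.5 g off baseline
for ≥ 0.5 s) within 3 min; and ≤ 4 h since the first N3 detection. The 15-min
rule is implemented as elapsed time since first N3 detection, not 15 min of
uninterrupted N3 — "stable" is undefined in the source and the weaker
reading matches the printed hard-condition list. The 4-h cutoff is also
enforced at sample resolution so an epoch decision taken just before the
cutoff cannot license pulses past it.

**Phase tracker.** The SO phase comes from a forgetting-factor weighted
least-squares sinusoid fit on the causally delta-filtered (0.4–4 Hz,
2nd-order Butterworth) virtual channel. For each candidate frequency
$f \in \{0.8, 0.9, 1.0, 1.1, 1.2\}$ Hz, with window time grid $t$ (2 s at
the stream rate), design matrix $D_f = [\cos 2\pi f t, \sin 2\pi f t]$ and
weights $\Lambda = \mathrm{diag}(\lambda^{n-1}, \ldots, \lambda, 1)$
($\lambda = 0.99$, newest sample weighted 1), the precomputed solver is

$$ W_f = (D_f^\top \Lambda D_f)^{-1} D_f^\top \Lambda, \qquad
   \theta_f = W_f\, y. $$

Each fit is scored by the fraction of weighted signal energy it explains,
$\rho_f^2 = (\theta_f^\top D_f^\top \Lambda\, y) / (y^\top \Lambda y) \in [0,1]$;
the best frequency wins and the phase of the fitted sinusoid at the newest
sample is the estimate, in the convention 0° = ascending zero-crossing,
90° = up-state peak, 270° = trough (the published formula's correlation
omits $\Lambda$ in the numerator and is not confined to $[0,1]$; the
$\Lambda$-orthogonal projection ratio used here is the reading under which
it is). Two published window descriptions disagree — $\lambda = 0.99$ is
said to give a 5-s memory, yet $1/(1-\lambda) = 100$ samples is 0.4 s at
250 Hz, and the "250-row" window for 0–2 s conflicts with 500 samples at
250 Hz — so both window length and $\lambda$ are parameters; the defaults
keep the printed $\lambda$ and a 2-s window at the stream's rate. A
per-sample streaming trace computes exactly the same estimates via FIR
convolution with the rows of $W_f$ (FFT-based), which is what makes
whole-night runs affordable; an equivalence test pins streaming to the
windowed estimator at 1e-8. The orientation of the phase (sign conventions
of $\theta$) is locked to the Hilbert 90°-at-peak convention by a
regression test. Phase is read at the newest sample with no forward
extrapolation — whether the device compensated its processing latency is
unstated, and triggering at the estimate keeps the implementation minimal.

**Scheduler.** A trigger fires when the phase crosses the 45° target in the
ascending direction (modular interval test between consecutive samples).
Trains hold at most two pulses — the second at the next 45° crossing, i.e.
on the following SO; if none arrives within 3 s the train closes with one
pulse (the timeout is ours). At least 9 s must separate the last pulse of a
train from the first of the next. A movement or an 8–12 Hz (alpha) burst
within 6 s of a pulse starts a 30-s pause. Stim/sham is drawn per train
(both pulses share the arm) with probability 0.5 — the randomization unit is
unstated in print; per-train preserves the paired ERP analysis. Pulses are
logged events with nominal 50-ms duration and 40-dB level; no audio is
synthesized. The "random condition" (targets drawn among ascending, peak,
descending, trough) is available through a target-list option.

## The simulator

`simulate_hypnogram()` draws an inhomogeneous first-order Markov stage
sequence with conventional cycle structure (descending N1→N2→N3, ascending
N2, REM; N3 pressure decaying across cycles). Minimum-dwell rules keep bouts
realistic; the first N3 bout lasts ≥ 25 min by construction, so a default
8-h night always contains a contiguous N3 block ≥ 20 min, and the N3 share
of epochs stays within ~10–24% across seeds (checked empirically over 200
seeds before freezing the transition parameters).

`synthesize_night()` writes stage-dependent content on a 1/f background
(18 µV rms by default, stage-scaled): discrete one-cycle slow oscillations
in N3 (frequency per event from 0.8–1.2 Hz, peak 80 µV, phase recorded
sample-exactly with 90° = peak, giving unambiguous ground truth), spindles
and occasional K-complexes in N2, 8–12 Hz activity in wake, low-amplitude
mixed activity in N1/REM. Detachment artifacts are large drifts saturating
at ±500 µV on one channel at a time; movements are accelerometer bursts
(>0.5 g for ≥0.5 s, the same criterion the hard-condition checker uses)
with a co-timed EEG transient. None of these amplitudes or rates is
published — they were chosen once as values a sleep researcher would call
plausible, are all exposed in `sleep_sim_config()`, and the simulator's
realism is validated only through a separability property: a simple
band-power threshold classifier must reach >80% N3-vs-rest accuracy.
Passing tests on this simulator therefore demonstrates the pipeline's
correctness and calibration, *not* performance on real sleep EEG: real
recordings have inter-subject spectral variability, gradual stage
transitions, arousals, and artifact morphologies the simulator does not
attempt (no ECG/EOG/EMG contamination, no pathology, no microarousals).

`apply_clock_drift()` models the second device's clock as piecewise-linear
rate error per 10-min chunk (matching the resynchronization chunking), with
lag $\text{offset} + (r-1)t$ for constant rate $r$.

## Offline analyses

*Resynchronization* maximizes, per 10-min chunk, the normalized
cross-correlation between the band-limited (0.4–18 Hz, zero-phase — the
choice of filtered rather than raw signals is ours) reference and the other
device's signal over translation and rate ratio: a coarse ratio grid around
the previous chunk's solution (sequential warm start), FFT cross-correlation
with parabolic sub-sample refinement for the offset, then a golden-section
refinement of the ratio. Chunks scoring below 0.2 are flagged unalignable.

*Phase accuracy* filters the recorded signal with a zero-phase 2nd-order
Butterworth 0.4–4 Hz band-pass, reads the analytic-signal (FFT Hilbert)
phase at each pulse, and reports circular mean, circular SD and a 72-bin
histogram of 5° bins. Circular SD is $\sqrt{-2\ln R}$ (in degrees), a
definition chosen by us since the dispersion measure behind published
"mean ± SD" phase figures is not stated. Note the evaluation runs on the
*recorded* signal, which on the device is already 0.4–18 Hz causally
filtered; evaluating against the raw simulator track instead would fold the
acquisition filter's ~30° phase lead at 1 Hz into the result.

*ERP / delta power*: trigger-locked averages use zero-phase
(forward/backward) filtering to avoid phase delays, accepting some
non-causality before the trigger. Delta power is the squared magnitude of
the DFT of the 1,024 samples after the trigger, Hann-tapered ("convolved
with a Hann function" is read as pointwise tapering — the reading under
which Parseval checks make sense), summed over bins in 0.4–4 Hz; at 250 Hz
the window spans 4.096 s, the realization of the nominal "4-s window". The
window after the second pulse starts 1 s after that pulse; the anchor is
exposed because the describing sentence is ambiguous. Per-subject powers are
averaged per condition (nights pooled within subject), the percent increase
is $(\overline{P}_\text{stim}/\overline{P}_\text{sham} - 1)\times 100$ over
the distribution means, and a paired t-test across subjects is evaluated at
p < 0.001. Under a 2× amplitude positive control the increase is exactly
300% (quadratic scaling); under the null it is centred on zero with type-I
rate consistent with the threshold. The published cohort effect sizes
(≈44% after the first pulse, ≈12% after the second) require the original
recordings and are out of scope here.

## Numerical and design choices

- Printed band-filter orders are overall orders (`butter(n/2, ...)` for
  pass/stop designs).
- Zero-phase filtering pads with odd reflections over ~3 time constants of
  the low band edge before the forward/backward pass.
- The weighted-LS normal matrix is solved directly; a singular matrix (never
  observed for the shipped frequency list) raises an error rather than
  regularizing.
- Flat or NaN-containing fit buffers give `valid = FALSE`; crossings require
  two consecutive valid estimates and an ascending advance < 180°.
- Target-crossing equality (phase exactly on target) counts as a crossing;
  dead-band equality in the switch holds the previous state.
- Forest training, night simulation and stim/sham draws all run under local
  RNG scopes seeded from explicit arguments, so every result is reproducible
  bit-for-bit from a seed and the global RNG stream is left untouched.
- Problem sizes in the test-suite and acceptance runs — training nights of
  2 × 2 h (quality) and 3 × 3 h (N3), 6-h audit nights, a 2-h all-N3 night
  for phase accuracy (~1,200 pulses), a 4–8-h pair for drift recovery, 100–200
  replicates for statistic calibration — were chosen as the smallest sizes at
  which the measured quantities stabilize.

## Known limitations

- The quality and N3 classifiers are simulator-trained analogues; their
  near-perfect synthetic accuracy says nothing quantitative about dry-EEG
  recordings of real sleepers.
- The phase tracker triggers on background delta activity between discrete
  simulated SO events, as a real device does on real N3; the simulator's
  ground-truth phase is only defined inside events, so pipeline-level phase
  accuracy is audited with the Hilbert method rather than against event
  ground truth alone.
- EDF support is a minimal 16-bit implementation sufficient for this
  package's channel layout; it is not a general EDF+ library.
- Stimulation is an event log; acoustics, loudness calibration and bone
  conduction are out of scope.
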