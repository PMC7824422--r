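---
title: "Methods: oscillatory power, imaginary-coherence connectivity, and cluster statistics for event-related EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillatory power, imaginary-coherence connectivity, and cluster statistics for event-related EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erspconn)
```

# The problem this package addresses

In event-related EEG experiments with two within-subject conditions —
here, episodes in which an adaptive system behaves supportively versus
impedingly while the participant watches — two families of oscillatory
signatures are of interest:

1. **Regional power changes** (event-related desynchronization and
   synchronization, ERD/ERS): stimulus-locked decreases or increases of
   band-limited power relative to a pre-stimulus rest baseline, localized
   in time, frequency and electrode.
2. **Inter-regional coupling**: changes in phase-lagged coupling between
   a seed region (the parieto-occipital electrodes POO1/POO2 over visual
   cortex) and the rest of the head.

Both are compared between conditions across subjects with a
non-parametric cluster-based permutation test that controls the
family-wise error over electrodes.

The trial structure assumed throughout is a 6000 ms stimulus-locked
epoch: rest (−4000..−2000 ms), an instruction cue (−2000..0 ms), a replay
of the participant's action (0..1000 ms) and the system's adaptation
(1000..2000 ms), with time 0 at replay onset. Roughly 30 trials per
condition and 16 subjects, 32 channels at 1 kHz (desk-scale default
250 Hz).

# The synthetic data generator: a stated world

No real recordings ship with the package, so every claim a green test
makes is a claim about data the generator produced. The generator is
therefore first-class, tested code, and its defaults are fixed choices,
not tuning knobs:

- **Background**: 1/f^β coloured noise (β = 1) with SD 10 µV plus a 1 µV
  white floor, per trial and channel, spectrally shaped with an
  analytically normalised amplitude profile (no per-trial empirical
  rescaling). This matches the broadband appearance and ~10 µV RMS of
  adult scalp EEG without claiming physiological detail. The 1/f profile
  is flattened below 0.5 Hz so the epoch-length variance stays finite.
- **Power modulations**: the epoch's own band component (an exact FFT
  band decomposition) is scaled by the amplitude gain `10^(dB/20)` inside
  a cosine-tapered window (10 % Tukey ramps). Scaling the signal's own
  band content — rather than adding an independent oscillator — makes the
  injected band-power change exactly the stated dB in the window
  interior regardless of the background level, and the taper avoids edge
  discontinuities that would smear into the time-frequency maps.
- **Lagged coupling**: a band-limited Gaussian source component (RMS
  8 µV, comparable to a clear posterior alpha rhythm) is added to the
  source channel; targets receive a copy scaled by the coupling
  coefficient and delayed by `phase_lag / (2π f_center)` seconds. The
  delay is applied as an FFT phase ramp (exact fractional delay), because
  at e.g. 40 Hz and 250 Hz sampling the required delay is 0.78 samples
  and integer rounding would distort the lag. A nonzero lag produces
  genuine imaginary coherence; lag 0 reproduces pure volume-conduction
  coupling, which ciCOH must ignore.
- **Zero-lag mixing**: any square matrix can be applied instantaneously
  to emulate volume conduction.
- **Artifacts**: raised-cosine transients of stated peak amplitude on
  stated channels/trials, for exercising the amplitude-rejection rule.

Every injected effect is recorded in a ground-truth ledger (subject,
kind, channels, band, window, magnitude, affected trials), and all
randomness flows from one root seed through deterministic per-stage,
per-subject derived seeds, so identical configurations are bit-identical.

**What the generator does not emulate** — and hence what a green test
does *not* establish: no biophysical head model or dipole forward
solutions (the mixing is an arbitrary matrix, not a realistic leadfield),
no non-stationarity of the background across a session, no eye/cardiac
artifact waveform realism beyond "frontal, slow, large", and no
between-subject anatomical variability. Results on real data additionally
depend on those factors.

# Preprocessing

- **Detrend**: per-channel least-squares linear detrend over the whole
  continuous recording (before segmentation), then re-referencing to
  mathematically linked mastoids (the mean of TP9/TP10 subtracted from
  every channel).
- **Band-pass 0.5–48 Hz**: a first-order FIR cannot realise such a
  band-pass, so the filter is a windowed-sinc (Hamming) linear-phase FIR
  whose length is set by a 0.5 Hz transition at the low edge
  (≈ 1651 taps at 250 Hz), applied forward–backward. The net result has
  exactly zero phase (a 10 Hz tone's peak cross-correlation with the
  input is at lag 0) and squared magnitude; passband ripple is well below
  0.5 dB, so filtering twice changes a passband tone by < 1 dB.
  Reflection padding suppresses onset transients.
- **Epoching**: one 6000 ms epoch per condition-tagged replay-onset
  marker; markers too close to the recording edges are skipped with a
  warning count. Epochs are exact slices of the raw data (no padding of
  the time series; zero-padding happens only as FFT-length padding inside
  spectral routines, because padding the signal itself would bias
  amplitude rejection).
- **Amplitude rejection**: a trial is rejected when the absolute
  deviation from the per-channel epoch mean exceeds 200 µV in any of the
  four frontal channels (AFp1, AFp2, AFF5h, AFF6h). Deviation-from-mean
  is the default because it is robust to DC offsets and the strictest
  common reading; a peak-to-peak variant is available
  (`method = "peak_to_peak"`). The rule updates only the kept-mask —
  signal values are never modified — and the boundary is strict
  (a 199 µV deviation is kept, deviations above 200 µV are rejected).
- **ICA**: logistic infomax (natural-gradient, whitened data, annealed
  learning rate, deterministic given a seed), which separates the
  super-Gaussian sources EEG artifacts are. Component rejection in
  practice is visual; for reproducibility the package flags components by
  deterministic heuristics with exposed thresholds — *ocular*: frontal
  topography dominance (mean |frontal weight| > 2× mean |weight|) plus
  > 55 % of power below 4 Hz; *muscular*: power spectrum rising above
  20 Hz plus an edge-focal topography (peak electrode beyond 0.85 of the
  scalp radius) — and a manual `override` argument preserves the
  inspection workflow. Removing zero components reconstructs the input to
  < 1e-6 µV.

# ERSP

Per-trial power is computed by short-time Fourier transform with a Hann
window of 128 samples at 250 Hz (512 at 1 kHz), zero-padded fourfold, so
the frequency grid step is fs/nfft ≈ 0.488 Hz over 1–45 Hz; the time
grid steps by 100/3 ms. Window centres span the full epoch; frames
overhanging the epoch edges are zero-filled and divided by their
window-energy coverage, which keeps stationary power unbiased at the
edges (at the price of inflated variance in the outermost ±256 ms —
an accepted trade-off so that the band × window summaries cover the
full adaptation second). Power is scaled as a one-sided density, so it
is directly comparable to a Welch periodogram (agreement within 1 dB on
stationary noise is a tested invariant).

ERSP is divisive-baseline in dB: trial-averaged power divided by its
mean over the rest window (−4000..−2000 ms), `10·log10` of the ratio.
This gain model makes the map exactly 0 dB over the baseline itself (in
the power domain) and turns a k-fold power change into `10·log10(k)` dB
wherever it occurs. Summaries are the mean ERSP per channel over
α (8–14), β (15–35), γ (35–45 Hz) × four 250 ms windows following the
adaptation onset (+1000 ms epoch time). The β/γ edges share the 35 Hz
bin by construction; a strong effect at exactly 35 Hz therefore shows in
both bands, which is the stated band definition, not an artifact.

A Morlet-wavelet alternative was considered and not implemented: the
uniform time-frequency grid used here is what the downstream summaries
require, and a constant-Q decomposition would change the variance
structure of the γ band without changing any of the statistics.

# Connectivity

Cross-spectra use multitaper estimation: 1000 ms windows, 100 ms step,
time-bandwidth NW = 3, hence K = 2·NW − 1 = 5 Slepian tapers, FFT length
the next power of two (1024 at 1 kHz, spectral resolution 0.98 Hz). The
tapers come from the classic symmetric-tridiagonal eigenproblem, solved
for only the top K eigenpairs with LAPACK's `dstevr` (a dense solver
needs seconds at N = 1000; the tridiagonal route takes milliseconds);
concentrations are computed from the sinc-kernel quadratic form and all
five exceed 0.9.

From the coherency `COH = S_ij / sqrt(S_ii S_jj)`, the corrected
imaginary coherence is `ciCOH = Im(COH) / sqrt(1 − Re(COH)²)`. Where
|Re(COH)| reaches 1 (pure real coherency, e.g. self-coherency) the value
is defined as 0 — there is no imaginary part to correct — and the
denominator is guarded at 1e-12. A Fisher z-transform (`atanh`, with
clipping at 1 − 1e-12 and a warning) is available; by default it is
*not* applied before the event-related contrast, because the contrast is
defined on |ciCOH| itself; setting `fisher_before_contrast = TRUE`
applies it to the per-trial magnitudes first.

The event-related map is computed **per trial**: |ciCOH| between each
seed and every electrode, averaged over the bins of each band, in two
1000 ms windows — baseline (last second of rest, −3000..−2000 ms) and
the window of interest (first adaptation second, +1000..+2000 ms) — then
`(TOI − baseline) / max(baseline, ε)` with ε = 1e-3, averaged over
trials and finally over the two seeds. The ε floor exists because a
per-trial 5-taper |ciCOH| near zero would otherwise explode the ratio.
Within a 1000 ms segment the sliding step yields exactly one window, so
the five tapers are the whole per-trial ensemble.

**A known property of this estimator**: with only five tapers the
per-trial |ciCOH| of *uncoupled* channels has a noise floor around
1/sqrt(K), and because the contrast divides by a noisy baseline, its
expectation over uncoupled electrodes is slightly positive (Jensen's
inequality), typically ≈ +0.2 under the generator's defaults. This bias
is identical in both conditions and cancels exactly in the paired
condition contrast the statistics operate on; single-condition maps
should be read relative to that floor, not to zero. Seed electrodes
themselves are NA in the maps.

# Cluster statistics

Per electrode, a dependent-samples t over subjects of the condition
difference; electrodes with zero difference variance get t = 0 with a
flag (conservative — they can never be supra-threshold). Electrodes with
|t| above the two-tailed p < 0.05 critical value are clustered into
sign-homogeneous connected components of a neighbourhood graph; cluster
mass is the summed t.

The neighbourhood construction is a free design choice in sensor space;
the default connects electrodes closer than 1.3× the median
nearest-neighbour distance (on the shipped 32-channel layout every
electrode then has ≥ 2 neighbours), with a symmetrised k-nearest
alternative (`method = "knn"`). Delaunay triangulation was considered
and dropped: no computational-geometry dependency is available in the
supported environment, and the distance rule reproduces the same
neighbourhoods on this layout.

The null distribution is the maximum absolute cluster mass under
within-subject condition swaps (sign flips of the per-subject
differences, which leave the per-electrode sums of squared differences
invariant — exploited to vectorise all permutation t maps). Two-tailed
max-|mass| pooling over both signs operationalises "95th percentile,
two-tailed". Monte-Carlo p-values use the add-one estimator
`p = (1 + #(null ≥ obs)) / (n_perm + 1)`, which cannot return 0; with
n ≤ 12 subjects and n_perm > 2ⁿ the full enumeration is used instead and
p-values are exact (note p can then never fall below 2⁻ⁿ — with four
subjects no cluster can reach p < 0.05, which is a fact about the
design, not a bug). A cluster is significant at corrected p < 0.05.

The empirical family-wise error rate of the whole procedure, measured
over 200 null datasets in the acceptance suite, is ≈ 0.04–0.07,
consistent with the nominal 0.05 within Monte-Carlo error.

# Pipeline, formats, reproducibility

Stages (`simulate`, `preprocess`, `ersp`, `connect`, `stats`) communicate
through an output directory: per-subject epoch containers (a serialized
hierarchical layout — data, time axis, labels, condition, kept-mask,
attrs with fs, config hash, seed, package version — with a bit-exact
round trip), long-format TSV tables, and TSV/JSON cluster reports. Every
output embeds the MD5 hash of the canonical JSON serialization of the
configuration, so changing any parameter changes the hash. The
BrainVision reader supports multiplexed IEEE float32 and int16 with
per-channel resolution scaling; a writer exists to generate round-trip
fixtures. Configurations are JSON with defaults equal to the stated
analysis constants (0.5–48 Hz, 200 µV, bands, 1000/100 ms, 5 tapers,
1000 permutations). The simulate stage clears stale subject containers
from previous runs before writing.

The demo scenario (`demo_config()`) injects −3 dB α and β ERD over six
connected parieto-occipital electrodes and π/2-lagged γ coupling from
both seeds to four frontal electrodes, all confined to the adaptation
window of the supportive condition, plus 250 µV frontal artifacts on two
trials. With the paired contrast supportive − impeding this must yield
negative significant ERSP clusters at the injected electrodes, positive
significant γ ER-ciCOH clusters at the targets, and rejection of exactly
the artifact trials — which is what the acceptance suite asserts. The
γ-band source also raises 35–45 Hz power at source and target channels,
so the demo additionally shows positive γ ERSP clusters there; this is a
physical consequence of injecting an oscillatory source, not leakage.
ICA is disabled in the demo configuration: no artifact species needing
it is injected, and a blind decomposition re-mixing the injected
coupling source would make the ground-truth comparison ill-posed; ICA
has its own recovery tests.

# Known limitations

- Sensor-space only; no source reconstruction, no leadfield-based
  volume-conduction model.
- The ERSP edge frames (outermost ±½ window) are variance-inflated.
- The per-trial ER-ciCOH ratio has the positive background bias discussed
  above; only condition contrasts are bias-free.
- Infomax ICA assumes super-Gaussian sources; sub-Gaussian artifacts
  (e.g. line noise) are not separated (an extended-infomax switch would
  be the natural extension).
- The cluster test permutes subject-level condition means (sign flips),
  the standard dependent-samples design; trial-level permutation within
  subjects is out of scope.
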