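---
title: "Scoring speech-to-speech synchronization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring speech-to-speech synchronization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s2sync)
```

## The task and the measurement problem

In the accelerated speech-to-speech synchronization task a participant
listens to a train of synthesized /ta/ syllables whose rate steps from 4.3
to 4.7 Hz, while continuously whispering /ta/ in time with it. The behavioral
readout is the Phase Locking Value (PLV) between the amplitude envelope of
the stimulus and the amplitude envelope of the participant's whispering:

$$\mathrm{PLV} = \frac{1}{T}\left|\sum_{t=1}^{T} e^{i(\theta_1(t) - \theta_2(t))}\right|$$

where $\theta_1, \theta_2$ are the unwrapped instantaneous phases of the two
band-limited envelopes. A stable phase difference — including any constant
response lag — gives PLV near 1; drifting or unrelated rhythms give values
near 0. Cohorts typically split into high- and low-synchronizers, with class
boundaries taken from a Gaussian mixture fitted to a reference cohort
(low < 0.4014, border up to 0.4113, high above; runs outside [0.1, 0.9] are
treated as unreliable). This package implements the full scoring pipeline
plus a stimulus synthesizer and a participant simulator, so every stage can
be verified against known ground truth without collecting recordings.

The scientifically interesting failure mode, and the reason the pipeline
reports more than one number, is *subharmonic synchronization*: a
participant who whispers to every second syllable (e.g. at 2.25 Hz against
4.5 Hz) produces envelope modulations at the second harmonic of their
production rate. The 3.3–5.7 Hz analysis bandpass removes the 2.25 Hz
fundamental and keeps the 4.5 Hz harmonic, so the PLV compares 4.5 Hz
against 4.5 Hz and can be deceptively high. The pipeline therefore pairs
the PLV with a per-segment syllable-rate estimate and an explicit
subharmonic flag.

## Pipeline stages and their parameters

**Stimulus model.** The stimulus is defined by a five-segment table: rates
4.3/4.4/4.5/4.6/4.7 Hz with 120/120/120/120/246 phonemes of
116.28/113.64/111.11/108.70/106.38 ms (two phonemes per syllable), giving
segment boundaries near 13.95, 27.59, 40.92, 53.97 and 80.14 s and 363
syllables in total. `default_segment_spec()` encodes the table;
`build_timeline()` turns it into onset times; `render_stimulus()` produces a
surrogate audio rendering (a 15 ms high-passed noise burst for the /t/
release and a 200 Hz harmonic complex, band-limited below 1.5 kHz, for the
vowel). The surrogate is not a reconstruction of the original diphone
synthesis; it only needs the right envelope rhythm, transient onsets for
the onset detector, and spectral content confined below 3 kHz so the
leakage filter removes it. Onset times are snapped to the sample grid, so
the rendered duration can differ from 80.137 s by under 1 ms at 16 kHz.

**Leakage removal.** Stimulus audio that bleeds into the recording carries a
200 Hz fundamental and lives below 3 kHz, while whispered /ta/ energy
concentrates above 3 kHz. `remove_leakage()` applies a 6th-order Chebyshev
type-II filter with a 3 kHz stopband edge and 40 dB stopband attenuation.
The printed rule is a bandstop over [0, 3 kHz]; a bandstop whose lower edge
is 0 Hz is exactly a high-pass, which is how it is realized here.

**Envelope.** `extract_envelope()` computes the magnitude of the analytic
signal (FFT-based Hilbert transform), downsamples to 100 Hz and removes the
DC offset. The envelope rate is a package choice: it must exceed twice the
5.7 Hz band edge, and 100 Hz keeps a 5 s window at a convenient 500 samples.
Resampling runs as staged block-mean decimation followed by a zero-phase
Butterworth anti-alias filter and interpolation onto the target grid; the
block-center time offset is tracked so envelopes from different recordings
stay aligned. `env_bandpass()` applies the 5th-order Butterworth 3.3–5.7 Hz
rhythm filter. All filters run forward and backward (zero phase) so that
phase lags reflect behavior rather than filter delay; a causal single-pass
mode exists for parity experiments with delay-carrying setups.

**Onsets and silent gaps.** Whispering has no fundamental and low, highly
variable intensity, so onsets come from the spectral-flux onset-strength
envelope: the half-wave-rectified frame-to-frame increase of the magnitude
spectrogram summed over frequency (frames 46 ms, hop 10 ms), which peaks at
/t/ transients. The picker takes local maxima above median + 3 scaled MADs,
with a floor of 10% of the maximum strength — without the floor, recordings
with long near-silent stretches collapse the robust threshold to the
numerical noise floor. A refractory spacing of 80 ms suppresses double
detections (onsets cannot be closer even at 4.7 Hz). Silent gaps are
maximal onset-free spans longer than 3 s (spans before the first and after
the last onset included). Gap edges are padded inward by 110 ms — about half
a syllable period — so energy adjacent to the gap is not removed; the pad is
clamped so a reported gap never drops below the 3 s rule. An optional
refinement removes shorter gaps (default 1.5 s) for participants with many
breathing pauses; arbitrary intervals (e.g. accidentally voiced stretches)
can be merged in manually via `merge_manual_exclusions()`.

**PLV variants.** Gap samples are removed *after* phase extraction, at the
same indices in both series, and the retained samples are concatenated
across the cut without re-unwrapping (`apply_gap_removal()`); removing
envelope samples before phase extraction distorts the phase at the splice,
and a regression test keeps the two orders distinguishable.
`moving_window_plv()` uses 5 s windows with 3 s overlap. Its *legacy* mode
reproduces a documented off-by-one from an earlier analysis script — slot
count `floor(duration/step)` with one trailing slot left at zero but still
averaged — which turns a self-comparison of the ~80 s stimulus into
0.975 = 39/40 instead of 1; the corrected mode averages only fully assigned
windows. `segmented_plv()` computes one PLV per stimulus segment (no
overlapping windows) on the gap-removed samples, assigns NaN where less
than 50% of a segment survives removal, and reports a mean weighted by
remaining samples per segment; NaN segments are excluded from the mean
rather than poisoning it, and an all-NaN run is flagged unreliable.

**Rate estimation.** Instead of modulation-spectrum peak picking (unreliable
on short segments), the PLV is repurposed as a similarity metric: the
participant envelope is filtered to 1–5 Hz and compared, per segment and
with silent gaps of at least 1.5 s removed to approximate phonation time,
against reference phases for 81 candidate frequencies (1–5 Hz in 0.05 Hz
steps), using 2 s windows with 1 s overlap; the argmax frequency wins. A
second pass re-filters to 1–3.3 Hz (first-pass estimate below 3 Hz) or
2.7–5 Hz (otherwise) and re-scans the restricted grid. The matching window
of 2 s with 1 s overlap is a package choice: small enough to tolerate
inter-onset variability, large enough to hold two cycles at 1 Hz. The 3 Hz
switch point sits in the overlap of the two printed refinement bands. Grid
ties resolve to the lowest candidate so a harmonic alias can never beat the
fundamental it came from. The articulation rate is the phonation-time
weighted mean of the per-segment estimates. A participant is flagged as a
subharmonic synchronizer when at least 3 of 5 segment estimates fall within
0.15 Hz of the segment's stimulus rate divided by the same integer m ≥ 2;
the tolerance and the 3-of-5 rule are package choices (three times the grid
step, and a majority of segments).

**Classification.** `classify_run()` applies the printed thresholds exactly,
including the closed/open endpoints (0.1 is low, 0.4113 is border, 0.9 is
high). `decide_participant()` retains a participant only when both runs land
in the same low/high class; border cases may be reclassified through
explicit override records (never silently), and an override may only move a
label to an adjacent class. A border case in *both* runs without an override
is reported as excluded pending override — the threshold table gives no
resolution for that case, so the package surfaces it instead of guessing.
The legacy exclusion rules (PLV outside [0.1, 0.9], spoken rate ≤ 2 Hz
including silences, any silent gap over 3 s) are evaluated for reporting
only, so refined and legacy decisions can be compared on the same runs.

## The simulator: what it emulates, and what it does not

`simulate_participant()` places whisper-like /ta/ bursts — a 15 ms sharp
noise transient band-limited to 3–7 kHz with an ~80 ms breathy decay, no
fundamental — at every m-th stimulus onset (1:1, 1:2, 1:3), on a
self-paced grid (free-running), or on a schedule of mode switches. Onsets
are shifted by a constant response lag plus Gaussian jitter truncated at
±3 SD (so onsets stay ordered), per-burst gain is drawn uniformly from
[0.7, 1] to mimic the variable intensity of whispering, breathing gaps
silence scheduled intervals, and the rendered stimulus can be mixed in at a
configurable leakage gain. Identical configurations produce byte-identical
WAV output.

The simulator emulates event timing, whisper-band spectra, silences and
leakage. It does not model articulation: no coarticulation, no drift in
production rate within a segment, no gradual re-entrainment after a gap, no
room acoustics or recording noise. Passing tests therefore demonstrate that
the *pipeline* recovers what the simulator put in — timing, rates, gaps,
classes — not that real whispered speech meets the simulator's assumptions.
In the same spirit, end-to-end classification tests give simulated
participants human-scale onset jitter (30 ms SD): a jitter-free simulation
synchronizes with artifact-level perfection (PLV above 0.9) and is
correctly labeled unreliable by the printed thresholds.

## Numerical choices and degenerate inputs

The analytic signal is computed by the standard FFT method with zero
padding to a 2-3-5-smooth length; envelope values within a few hundred
milliseconds of the signal edges carry transform edge effects, which is
harmless here because windows and segments are long relative to the edges.
Windows are sample-aligned (`round(start × rate)`), and partial trailing
windows are discarded in corrected mode. PLV of fewer than one sample is
rejected; phase extraction of a broadband (non-band-limited) envelope is
rejected as meaningless. A segment fully removed by gaps yields a NaN rate
with zero phonation time; an all-NaN rate estimate yields a NaN
articulation rate with a warning.

## Known limitations

- **Rate floor near the analysis band edge.** The 1–5 Hz pre-filter's lower
  edge attenuates a fundamental at exactly 1 Hz while its harmonics pass
  unattenuated, so for very sparse pulse trains the envelope phase winds at
  the harmonic centroid and the estimator reports ~3 Hz instead of 1 Hz.
  Recovery is reliable from roughly 1.3 Hz upward — comfortably below the
  slowest plausible subharmonic production (4.3 Hz / 3 ≈ 1.43 Hz) — and the
  test suite asserts recovery from 1.3 Hz.
- **Voiced-speech detection is manual.** Identifying non-whispered
  stretches could be automated with F0 detection; here they are removed
  through the manual-exclusion interface only.
- **Thresholds are constants.** The mixture-model class boundaries are
  carried as printed constants for comparability; refitting them to a new
  cohort is out of scope (a config escape hatch accepts alternatives).
- **Surrogate acoustics.** The synthesized stimulus is acoustically
  equivalent for this pipeline (rhythm, transients, sub-3 kHz content), not
  a reproduction of the original recording.

## Problem sizes used by the test suite

The suite verifies the full 80.14 s stimulus for the windowing identities
(the 0.975 = 39/40 legacy self-comparison, segment boundaries, subharmonic
deception end to end). Cohort-level direction properties (the refined
decision retaining more simulated participants than the legacy criteria)
run against a shortened five-segment stimulus of about 28 s with the same
rates and phoneme durations — the identities under test are scale-free, and
the shorter stimulus keeps simulated cohorts cheap.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config()
prep <- prepare_stimulus(cfg)

# a participant whispering to every second syllable, 30 ms onset jitter
sim <- simulate_participant(
  participant_sim_config(mode = "1:2", jitter_sd_ms = 30, seed = 21),
  prep$timeline)
entry <- analyze_run(cfg, sim$audio, prep, id = "demo")

entry$moving$scalar            # deceptively high PLV (~0.72)
entry$classification$label     # "high"
entry$rates$articulation_rate  # ~2.26 Hz: half the stimulus rate
entry$subharmonic$m            # 2
```
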