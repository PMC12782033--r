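---
title: "Benchmarking EEG systems on synthetic recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking EEG systems on synthetic recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegbench)
```

## The problem

Portable, consumer-grade EEG systems promise data collection outside the
laboratory, but their lower amplifier quality, wireless transmission and
simplified trigger chains raise the question of whether the classic
electrophysiological effects — the occipital alpha increase with eye
closure (Berger effect), steady-state visual evoked potentials (SSVEP),
and the N170, N200, P300 and mismatch-negativity (MMN) event-related
components — survive with usable effect sizes, and how many trials they
require. `eegbench` implements a complete within-subject benchmarking
pipeline for this question: paradigm generation, continuous-EEG
simulation under per-system imperfection models, the standard
preprocessing chain with explicit artifact thresholds, spectral and ERP
measurement, and the statistical battery used to compare systems.
Because all effects are *simulated* with known ground truth, every stage
of the pipeline can be validated quantitatively without any real
recordings.

## Paradigms and their constraints

Five tasks are generated with exact counts and ordering constraints:

* **Resting state** — alternating eyes-open/eyes-closed blocks (default
  four 1-minute blocks). Block order is EO first; the analysis is
  order-invariant, so this is a fixed convention.
* **SSVEP** — flicker blocks at 6, 10 and 15 Hz (two 30-s blocks each,
  2-s fixation lead). One marker per flash; the on-phase is half the
  cycle, i.e. 83.3, 50 and 33.3 ms.
* **Face perception** — 300 trials, half faces and half scrambled
  textures, 300 ms stimulus + 1000 ms fixation.
* **Active auditory oddball** — 400 sounds, 20% deviants, at least one
  standard between deviants and at least four leading standards.
* **Passive auditory oddball** — 674 tones (562 standards, 112 deviants,
  16.6%), at least two standards between deviants, inter-trial interval
  jittered uniformly on 550–650 ms.

**Quartile balance.** Dataset-reduction analyses keep the first 75% or
50% of trials. So that reduced sets have deterministic, proportional
condition counts (e.g. 505 trials with 84 deviants at 75% of the passive
oddball), the generators balance conditions within each quartile of the
sequence, with cumulative quartile boundaries at `floor(n*q/4)` —
the same floor rule the pack reduction itself uses. This is a design
choice: a free pseudo-random order would make reduced-set counts
irreproducible.

## The simulator

`synthesize_recording()` builds, at the system's native rate,

$$x_c(t) = g \,\bigl[\alpha_c(t) + s_c(t) + \textstyle\sum_k e_{kc}(t)\bigr] + n_c(t),$$

where $g$ is the system attenuation, $\alpha_c$ a 10 Hz occipital
sinusoid whose amplitude is multiplied by the EC/EO gain during
eyes-closed blocks (default base 5 µV, gain 2), $s_c$ the flicker
response (fundamental + two harmonics on O1/Oz/O2; default 1, 0.5,
0.25 µV), $e_{kc}$ evoked templates, and $n_c$ background noise.

* **Templates** are Gaussian-tapered half-sinusoid lobes whose extremum
  equals the nominal amplitude at the nominal latency. Defaults: P100
  +4 µV/100 ms/60 ms, N170 −5 µV/150 ms/70 ms (faces > textures), N200
  −3 µV/260 ms/80 ms, P300 +5 µV/380 ms/150 ms, MMN −2 µV/190 ms/80 ms,
  with fronto-central or occipito-temporal weight maps. No claim of
  biological realism is made for the shape; any smooth unimodal template
  with the stated latency/amplitude supports the validation logic.
* **Noise** is spectrally shaped Gaussian noise with power $\propto 1/f$
  (σ = 5 µV by default), the standard stand-in for EEG background
  activity. Blink-like frontal transients exist but default off, since
  the pipeline deliberately contains no ocular-correction step.
* **System imperfections**: overall gain, a signed latency shift applied
  to evoked responses (the consumer system's documented tendency to
  earlier apparent peaks), a noise multiplier, Bernoulli per-event
  trigger loss, and faulty channels (signal replaced by σ = 500 µV white
  noise — large enough that the artifact rules, which operate on the
  *filtered* record, still catch it).
* **Presets**: EM-like (128 Hz, gain 0.6, −20 ms, noise ×1.5, 1% trigger
  loss, 5% faulty channels), LA-like (500 Hz, gain 0.95, tiny defect
  rates) and BA-like (250 Hz, reference quality), mirroring the native
  rates and the observed signal-quality ordering of the three commercial
  systems the benchmark models.

What the simulator does **not** emulate: inter-individual amplitude and
latency variability (all virtual participants share the ground truth, so
across-participant variance is measurement noise only — effect sizes are
not calibrated to literature values), non-stationary alpha dynamics
(a fixed-phase sinusoid is used so amplitude ratios are exactly
recoverable), movement or ocular artifacts, and volume-conduction
topography beyond simple weight maps. Passing tests therefore show that
the *pipeline* is correct and sensitive, not that the simulator predicts
human data.

## Preprocessing

The chain is fixed per task: band-pass + 50 Hz notch → (downsample to
128 Hz for the rate-equalized pack) → common-average reference →
muscular-artifact marking → faulty-electrode removal → epoching →
baseline → threshold rejection. Thresholds are the benchmark's published
rules: 500 µV peak-to-peak within a per-sample sliding 800-ms window
marks a muscular artifact; channels artifactual for more than 5% of the
recording are removed (never interpolated); epochs with any retained
channel exceeding 200 µV peak-to-peak (strict inequality) are rejected.
Task bands: 0.016–30 Hz (resting, both oddballs), 0.01–55 Hz (SSVEP),
0.1–40 Hz (faces).

Numerical choices:

* Band-pass as a cascade of a 2nd-order Butterworth high-pass and a
  4th-order low-pass, both zero-phase (forward–backward). Sub-0.02 Hz
  high-pass corners sit at normalized frequencies of 1e-4–1e-5 where the
  recursion can be ill-conditioned; when the corner falls below one
  cycle per record length the high-pass degenerates to mean/linear
  detrending, which is what such a filter does to a finite record
  anyway. The notch is a 2-Hz-wide 2nd-order band-stop.
* Faulty-electrode coverage is evaluated on the filtered continuous
  record; artifact marking precedes re-referencing so that faulty
  channels can be excluded from the common average.
* Downsampling is Fourier-domain resampling (spectrum truncation at the
  new Nyquist), an exact anti-alias for band-limited content; markers
  are remapped to the nearest target sample. Only downsampling is
  supported — rate equalization never upsamples.
* Sample indices are 0-based and all time windows half-open
  `[start, end)`, except the AUC integration window, which is a closed
  50-ms interval whose fractional edges are handled by linear
  interpolation (below).

## Spectral measures

Resting-state alpha power uses Morlet wavelets (7 cycles at every
frequency, L2-normalized — the package's reading of Gabor
normalization; the cycle count is a fixed convention). Power is averaged
over the 8.5–12.7 Hz band and the valid (non-edge) samples, per
electrode, then over O1/Oz/O2, then over the condition's segments; the
Berger effect is the EC − EO difference. Since the analysis extracts
only this band, band-restricted frequency grids give identical results
to the full 1–40 Hz grid at lower cost; the orchestrator uses an
8–13 Hz grid at 0.5 Hz steps.

SSVEP spectra use a Hann window with amplitude corrected for the
window's coherent gain, on a 0.05 Hz output grid: the segment is
zero-padded when its natural resolution is coarser, and regridded by
linear interpolation when finer (a 30-s segment has natural resolution
0.033 Hz; the 0.05 Hz grid is a stated output convention, so both cases
must land on it). The SNR at bin $k$ divides its amplitude by the mean
of the 20 surrounding bins (10 per side, excluding the immediate
neighbor on each side); edge bins use the available one-sided
neighbors rather than being dropped, so low-frequency fundamentals stay
computable. Condition SNR averages amplitude spectra over the two
segments and the three occipital electrodes *before* the SNR transform,
then pools the fundamental with its first two harmonics (6→12, 18;
10→20, 30; 15→30, 45 Hz).

## ERP measures

Condition averages exclude rejected epochs; the active-oddball standard
average drops standards immediately following a deviant, and the MMN
standard average keeps only standards immediately preceding a deviant.
Components are measured on the deviant-minus-standard difference wave
(oddballs) or the condition average (faces): single-sample extrema
within per-system search windows (N170 120–160 ms, or 100–140 ms for the
short-latency EM preset; P100 80–120/60–100 ms; N200 200–280 ms; P300
280–420 ms; MMN 100–250 ms), ties resolved to the earlier sample. The
N170 is quantified as the P100→N170 peak-to-peak difference.

The MMN amplitude is the signed trapezoidal area (nV·s) over a 50-ms
window centered on the mean of the Fz and Cz grand-average peak
latencies (a single usable electrode supplies the center alone). Because
window endpoints rarely coincide with samples, the integrand is linearly
interpolated at the endpoints; without this the truncation error at
128 Hz reaches ~10%, with it the area agrees with fine-grid integration
of the underlying template to well under 1%.

## Statistics

One-sample and paired t-tests report Cohen's d (`|mean|/sd`, so
`d = t/√n` for the one-sample case); repeated-measures ANOVAs (via `aov`
with a participant error stratum) report partial η² =
SS~effect~/(SS~effect~+SS~error~), with plain integer degrees of freedom
(no sphericity correction by default, matching the reporting convention
the benchmark follows). Pairwise comparisons use Bonferroni
multiplication clipped at 1. Between-system consistency is the Pearson
correlation over participants present in both systems. Wilcoxon
signed-rank, Friedman and Mann–Whitney tests wrap the base R
implementations (exact p for small untied samples, normal approximation
with correction otherwise). Effect sizes are reported unsigned.
Participants with missing cells (e.g. faulty electrodes at a measurement
site) are removed listwise.

The standardized measurement error (SME) of a participant's measure is
the standard deviation of the measure recomputed on `n_boot` (default
1000) bootstrap resamples of that participant's retained epochs; for a
mean-amplitude measure on i.i.d. noise it estimates σ/√n, and it is the
package's per-participant precision metric.

## Orchestration

`run_benchmark()` loops participants × systems × tasks × packs from one
configuration and master seed (all child seeds derive from it via a
counter scheme; reruns are bit-identical). Packs: `100a` equalizes all
systems to 128 Hz before analysis; `100b` keeps native rates (skipped
for systems already at 128 Hz, whose native rate *is* the equalized
rate); `75`/`50` keep the first fraction of trials for ERP tasks and the
leading fraction of each segment for the continuous tasks (the
time-based reading of dataset reduction for resting/SSVEP). The report
holds the long measure table, a signal-quality summary (lost triggers,
faulty electrodes, rejection percentage: mean, SE, range per system),
the task × pack × system Cohen's-d grid with generator-derived dataset
headers, and the MMN window table. Counterbalancing of system order is
omitted: the simulator has no carry-over, so order cannot matter.

## Problem sizes in the test suite

The package defaults are the full study conditions (19 participants,
4×60 s resting blocks, 6×30 s flicker blocks, 300/400/674 trials). The
test and acceptance suites run the same code on smaller designs chosen
once for turnaround: e.g. 8–19 virtual participants, 3–8 s blocks, 40–60
trials, band-restricted wavelet grids, and 150–1000 replicates depending
on the statistic. Calibration bands are fixed a priori from the
sampling distribution of the quantity under test (e.g. a 0.05 ± 3·SE
band for a rejection rate over 500 replicates; a ±3·SE band around the
exact mean of the F distribution), never adjusted after the fact.

## Known limitations

* No ICA or ocular correction: the simulator's blinks default off, and
  threshold rejection is the only epoch-level cleanup.
* BrainVision support covers the float32/int16 binary dialects only; no
  EDF/BDF/FIF.
* The greedy marker–log alignment handles sporadic trigger loss
  (including a lost first trigger) and slow drift; pathological loss
  patterns can fall back to a dynamic-programming alignment via
  `match_events(dp = TRUE)`.
* Simulated effect sizes are not calibrated to human between-subject
  variability; qualitative orderings between system presets are
  meaningful, absolute d values are not.
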