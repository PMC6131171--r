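---
title: "PSICAT: stimulus synthesis, session simulation, and the analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSICAT: stimulus synthesis, session simulation, and the analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psicat)
```

## The task and the scientific question

The Primed Subjective Illusory Contour Attention Task (PSICAT) is a
two-alternative forced-choice continuous performance test. Each trial shows a
brief fixation cross (100 ms), a task-irrelevant red line primer (150 ms), and
then a Kanizsa-style target that stays on screen until the participant
classifies it as containing a subjective contour illusion (SCI) or not. SCI
targets place "Pac-Man" inducers at the vertices of an implied polygon with
their mouth edges collinear with the polygon's edges; no-SCI targets use the
identical polygon and inducers with each inducer independently rotated so no
contour is induced. Primers are angle figures: congruent primers trace the
upcoming target's inducer angles, incongruent primers trace the angles of the
opposite-class twin built from the same polygon, so they reinforce the wrong
class. The design crosses congruency (con/inc) with target class (SCI/noSCI)
and vertex count (3/4), eight cells in total, with vertex count a control
dimension only.

The headline question is whether the task-irrelevant manipulation (primer
congruency) evokes larger behavioural and neural effects than the
task-relevant one (SCI vs no-SCI). The package implements the whole chain
needed to ask that question: stimulus geometry, trial scheduling, a calibrated
synthetic-session simulator, behavioural rank tests, a windowed-amplitude ERP
pipeline, early-versus-late spectral dynamics, and pooled effect-size
reporting.

## Stimulus geometry

Polygons are sampled by placing 3 or 4 vertices at jittered angular positions
(+/-20 degrees) on a circle of jittered radius (3 +/- 0.5 degrees of visual
angle), rejecting candidates until all interior angles fall inside
[30, 120] degrees for triangles or [50, 130] degrees for quadrilaterals
(capped at 1000 retries, then a configuration error). Infeasible bounds (for
example a triangle with all angles at least 170 degrees) are rejected up
front using the angle-sum identity. Inducer radius defaults to 1 degree,
which keeps Pac-Men non-overlapping for every polygon the sampler can emit;
`geometry_config()` enforces this against the worst-case inter-vertex chord.

No-SCI rotations are drawn independently per inducer, uniform in magnitude on
[40, 140] degrees with random sign. The lower bound guarantees visible
disruption of collinearity; the upper bound prevents the mouth edges from
re-aligning with the polygon from the other side. Because rotation preserves
the disc-minus-wedge area, SCI and no-SCI targets built from one polygon have
identical ink area in vector form (within 1% in the aliased raster), so the
class cannot be told apart by low-level luminance.

Primer segments default to the inducer radius in length; the incongruent
primer uses the opposite-class twin of the same polygon, the only reading
under which incongruent primers actively reinforce the opposite class rather
than being merely different. Coordinates are degrees of visual angle,
centre origin, y up; rasterization and the SVG writer document the flip into
screen convention. Antialiasing is off by default so renders are exactly
reproducible and testable pixel-by-pixel.

## Protocol scheduling

A test schedule is five blocks of 110 trials with a one-minute break between
blocks; condition labels are drawn independently and uniformly from the eight
cells per trial. We read "uniformly randomly distributed" as i.i.d. draws
rather than exact stratification because 550 is not divisible by 8. The
practice schedule is 12 trials, exactly three per primary condition, with
vertex counts alternating 3/4/3 across the repetitions. Inter-trial intervals
are uniform on 500 +/- 100 ms. With a 750 ms mean response time the expected
trial duration is 100 + 150 + 750 + 500 = 1500 ms, i.e. roughly 22 minutes
for a session. The SCI response hand alternates with participant parity.
Every schedule is a pure function of its configuration and seed, and the
events table (a BIDS-events-style TSV) round-trips losslessly.

A simulated response timeout (3000 ms, absent from the original protocol)
bounds the realized timeline; it truncates less than 0.1% of simulated RTs.

## The synthetic-session simulator

The simulator exists so the full analysis chain can be exercised end to end
without any recorded data. It is first-class, tested code, and its defaults
are the study conditions: 17 participants, 550 trials each, 512 Hz, with the
reduced 20-channel montage (the 19 channels used by any analysis ROI plus one
control channel; the full 128-channel Biosemi label set is available with
synthetic approximate positions, used only for topography falloff and plots).

**Behaviour.** Hit RTs are ex-Gaussian per primary condition, calibrated by
root-finding so the distribution median and SD equal the published
per-condition medians and RT variabilities (396/65, 453/101, 468/78,
489/85 ms), with error probabilities at the published rates (0.7, 0.7, 2.0,
0.8%). Between-participant structure has three parts, each documented and
deliberately small because the published rank statistics (U = 0 for the
largest RT contrast) imply near-complete separation of participant medians:
a common speed offset (SD 8 ms) on every condition's mu; a multiplicative RT
dispersion factor (lognormal, sdlog 0.28) with the condition medians
re-anchored so median RT structure is untouched -- RT variability is the
classic individual-differences dimension in sustained-attention work; and a
right-skewed lognormal scaling (sdlog 0.7) of each condition's error-rate
logit gap above the congruent baseline, motivated by the published
observation that a few participants showed ~5% errors in the incongruent-SCI
cell while medians stayed low. A 0.2% lapse rate draws long uniform RTs with
chance accuracy.

A genuine limitation follows from the published error rates themselves: a
participant's error percentage over 275 trials at rates of 0.7% vs 1.4%
carries binomial noise of about 0.5-0.7 percentage points, which caps the
expected rank-test effect size for the error contrast near 0.5 under any
independent-trials error model. The behavioural arm of the headline
effect-size comparison is therefore fragile at n = 17: its verdict holds for
the clear majority of seeds but not for all of them. The tests report one
canonical seed; this paragraph is the honest account of the design margin.

**EEG.** The recording is a sum of (i) per-trial ERP components, (ii) 1/f
noise, and (iii) fronto-medial theta dynamics. Components are Gaussian
deflections (FWHM 40 ms for N1-type, 120 ms for P3-type) at the primer N1
(peaking at target onset, i.e. 150 ms after the primer), target N1 (165 ms),
P3a (280 ms), and P3b (480 ms) latencies, with topography weight 1 on the
component's ROI channels and smooth Gaussian falloff elsewhere (no forward
head model: the pipeline tests need ROI contrast, not source realism).

Component amplitudes are specified on the *measured* scale: each
per-condition parameter is the windowed mean amplitude under the hypothesis's
own baseline mode -- exactly the quantity the analysis reports -- and raw
Gaussian peaks are obtained by inverting the linear window/baseline/topography
overlap matrix. This matters because the primer N1 straddles target onset, so
roughly a fifth of its mass lies inside the -100..0 ms target baseline; the
dual-baseline design accepts that leakage, and defining amplitudes on the
measured scale makes "the pipeline recovers the injected delta" well-posed.
The injected contrasts equal the published condition-wise differences:
P3a congruency +3.23 uV, P3b congruency -3.09 uV, primer N1 gestalt
-1.30 uV, target N1 gestalt +1.67 (congruent; the published sign reversal)
and -1.59 uV (incongruent), target P3a gestalt +1.63/+1.00 uV.

Noise is 1/f (exponent 1) at 10 uV RMS per channel with a 30% common-mode
share. Theta dynamics follow the sustained-attention signature: an induced
(random-phase) 4-8 Hz component whose RMS ramps linearly from 2 to 5 uV
across the session at the fronto-medial channels, plus a target-locked
fixed-phase 6 Hz burst (Gaussian envelope centred 150 ms post-target, SD
75 ms) whose amplitude declines from 3 to 1 uV across trials -- rising power
with falling phase-locking.

What the simulator does *not* emulate: ocular/muscle artifacts, channel
drop-outs, volume-conduction mixing beyond the smooth falloff, non-stationary
alpha, or RT-correlated single-trial component latencies. Passing tests
therefore show the pipeline is correct and calibrated on its stated model,
not that it is robust to every pathology of real recordings; the
amplitude-threshold rejection hook (`reject_epochs()`) stands in for the
full artifact chain of the original study, which used published toolboxes.

## ERP pipeline

Preprocessing is a 0.5 Hz high-pass: a least-squares linear-phase FIR of
order 1.5 x sampling rate (stopband to 0.425 Hz, passband from 0.5 Hz,
don't-care transition) with a DC-zero equality constraint, applied centred so
it is exactly zero-phase. The constrained least-squares design was chosen
over a windowed-sinc because the narrow transition demands it: a Hamming
windowed-sinc of the same length attenuates the ~0.65 Hz trial-repetition
fundamental by ~40% and visibly shrinks sustained components; the
least-squares design keeps 10 Hz gain within 0.1% and rejects DC exactly.
The residual passband ripple near 1 Hz (~10%) is inherent to the
order/transition combination.

Epochs are 750 ms (-250 to +500 ms around target onset; 384 samples at
512 Hz), hit trials only for ERP work. Two baseline modes implement the
dual-baseline logic: congruency questions and the primer N1 use the 100 ms
before the whole trial (-250..-150 ms), target-locked gestalt questions use
the 100 ms before the target (-100..0 ms), which controls primer carry-over
trial by trial. After correction the active window mean is zero to 1e-9 by
construction. A 20 Hz zero-phase FIR low-pass (order 128, reflection-padded
at the epoch edges so the P3b window at the epoch boundary keeps its level)
precedes measurement. Amplitude is the mean over a closed component window
(nearest-sample rounding) averaged over ROI channels, never a peak pick.

The seven condition contrasts are one-tailed paired t tests (df = n - 1)
with Holm adjustment as one family and Cohen's d = t * sqrt(2/n). That
conversion is the one consistent with the published effect sizes (6.68 with
n = 17 gives 2.29); the published df column mixes 33 and 16 across rows,
which no single paired-test form reproduces, so we report df = n - 1
honestly and let the effect sizes carry the comparison.

## Spectral dynamics

The sustained-attention comparison subsets epochs (all trials, hits and
errors) to the first and last 10% by trial order. Three estimators share the
comparison: a Welch power spectrum (per-epoch Hann periodograms, 1-30 Hz)
at the fronto-medial ROI; an event-related spectral perturbation at C20 from
a 3-cycle complex Morlet-style wavelet (4-30 Hz in 1 Hz steps -- the 750 ms
epoch cannot support lower frequencies -- kernels truncated at 2.5 SD),
expressed in dB against the mean -250..-150 ms baseline power pooled over
both subsets so a session-long drift appears as opposite-signed deviations
instead of being normalised away; and inter-trial coherence from the same
wavelet coefficients (single decomposition pass), the resultant length of
unit phasors across epochs.

Near the epoch edges the wavelet is zero-padded and renormalized by the
kernel mass overlapping real samples. This keeps coherent (phase-locked or
sinusoidal) amplitude unbiased everywhere -- a stationary sinusoid ensemble
gives 0 dB across the map and a post-stimulus power doubling reads +3 dB --
at the cost of a small negative dB offset for broadband noise at the lowest
frequencies, identical in both subsets and therefore cancelling from every
early-versus-late comparison the package reports.

Significance uses label-shuffle permutation (default 500 permutations,
two-tailed, p = (k+1)/(n+1)), with alpha defaults 0.01 for the spectrum and
ITC and 0.05 for the ERSP, mirroring the thresholds at which the original
results were reported. Because permutation masks are stochastic,
`stability()` repeats an analysis ten times with independent seeds and
reports per-bin consistency fractions. In the cohort pipeline the early/late
subsets are taken within participant and pooled across participants (a
fixed-effects comparison), which is the cheapest design that leaves the
within-session ordering intact.

## Effect-size report

Each significant test contributes one record tagged by family (behavioural,
estimator |z|/sqrt(N); neural, estimator d-from-t) and question (congruency
vs gestalt). The transitive RT chain mixes both manipulations and is tagged
"mixed", so it never enters a pooled cell; the three-record gestalt pool on
the neural side arises because the congruent target-N1 contrast reverses
sign and drops out by significance, exactly as in the published table.
Pooled cells never mix estimators (asserted), medians of absolute effect
sizes are rounded half-away-from-zero to two decimals, and nominal labels
use closed lower bounds (0.8 is "large", 2.0 is "huge"). The verdict is
true only if the congruency median exceeds the gestalt median in every
family; a missing cell makes it explicitly incomputable rather than false.

## Problem sizes and numerical choices

The cohort pipeline runs 17 participants x 550 trials on the 20-channel
montage at 512 Hz, about 4-5 minutes on one CPU; unit tests use one-block
schedules and constructed epoch arrays. FFT work is padded to highly
composite lengths. Monte-Carlo calibration checks use 4000 null replicates
(rank and t type-I error) and 50 x 40-bin permutation replicates. Ties take
average ranks with tie-corrected variance and continuity correction; the
exact Mann-Whitney branch (both n at most 8, no ties) uses the null U
distribution. Degenerate inputs -- constant pooled samples, zero-variance
differences, all-zero wavelet coefficients -- are flagged and excluded
rather than propagated as NaN.

## Known limitations

The EDF writer targets the 16-bit signal container only (markers live in the
JSON sidecar, not embedded annotations). The montage coordinates are a
synthetic approximate layout, adequate for topography falloff and plots, not
for source analysis. The behavioural arm of the headline verdict is fragile
at the study's own sample size, as quantified above. The simulator's theta
ramp is linear; real vigilance decrements are often nonlinear in time.
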