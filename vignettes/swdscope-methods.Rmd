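---
title: "State-resolved spike-wave discharge analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-resolved spike-wave discharge analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swdscope)
```

`swdscope` quantifies nonconvulsive spike-wave discharges (SWDs) in rodent
video-EEG. This vignette is the package's account of the underlying
procedure: the rules it implements, the parameters that matter and their
defaults, the synthetic data it validates against, and the places where a
genuine design choice had to be made.

## Behavioral staging from video tracking

Staging uses only the tracked (x, y) position at video rate (~20 fps) —
never the EEG — so that direct drug effects on the EEG cannot masquerade as
behavioral-state changes. The pipeline order is fixed: trajectory cleaning,
smoothing, instant speed, frame classification, despiking, the sleep rule,
then sweep assignment.

*Cleaning.* Two glitch classes typical of centroid trackers are corrected.
Sharp turnbacks: where the signed angle between successive displacement
vectors exceeds ±135°, the middle point is replaced by the mean of itself
and the next point, scanning forward on the working copy. The turn angle is
defined in (−180°, 180°], and the inequality is strict; a numerical
tolerance of 10⁻⁹ degrees keeps exactly-constructed boundary geometry
(135.000…°) on the unmodified side of the rule. Star-shaped jumps: from
each accepted point the nearest of the next four points is taken as the
next realistic location; bypassed points are replaced by linear
interpolation between the accepted neighbours. Interpolation (rather than
deletion) preserves the frame count, which the fps-based rules below
require. Both corrections process the trajectory strictly left to right on
the current working copy.

*Smoothing.* Coordinates are smoothed independently by a cubic smoothing
spline with the penalty chosen by generalized cross-validation
(`stats::smooth.spline`) — discretized penalized least squares with
automatic parameter selection. We supply a dense knot set (one knot per
~4 frames) so that the roughness penalty, not a sparse spline basis, does
the smoothing: with the default knot budget (~200 knots for a 3-h session,
i.e. one per several seconds) the fit cannot track sub-second
stop/start transitions, and staging accuracy at bout boundaries degrades
measurably.

*Rules and their constants* (all exposed as arguments, defaults in
parentheses): a frame with instant speed strictly above 0.5 cm/s (0.5) is
movement, otherwise immobility; an isolated single movement frame with at
least 10 (10) immobility frames on each side is relabeled immobility; in
any immobility period strictly longer than 30 s (30), frames from 30 s
after onset to the end of the period are sleep; each 10-s (10) sweep takes
the frame state strictly exceeding 60% (0.6) of its frames, immobility
mapping to "waking immobility", otherwise the sweep is a mixed
(transition) epoch. Sweeps are aligned to session start, half-open, with a
trailing partial sweep dropped — the alignment must be fixed somewhere for
EEG/video synchronization to be reproducible, and session start is the
only canonical anchor. The first frame copies the second frame's speed so
that every frame carries a value without inventing a spurious immobility
frame. Mixed-state sweeps pool all transition subtypes; discriminating
them would leave too few cases per session for statistics.

## Artifact rejection and channel qualification

Each channel is cut into the same 10-s sweep grid as the behavior. A sweep
whose summed 1–100 Hz power exceeds 2×10⁴ mV²/Hz (strictly) is excluded
from *all* further analysis — detection, rates and spectra all receive the
mask. "Summed power" is computed as a Welch estimate with 1-s Hann
segments at 50% overlap, which yields exactly 1-Hz bins, summed over bins
1 to 100 inclusive; the summation convention (inclusive endpoints, bin
values in mV²/Hz) is stated here because the rule's threshold is only
meaningful relative to it. Manual exclusions (a CSV of sweep indices)
union with the automatic flags, mirroring visual quality control. A
channel qualifies for analysis only with fewer than 60 noisy sweeps
(10 min of a 3-h session), strictly.

## SWD detection

The detector reproduces the classic envelope-threshold prescreen:

1. Band-pass 7–23 Hz, zero phase. We filter by FFT masking with
   raised-cosine transitions that reach zero at half the low edge
   (3.5 Hz) and 1.5× the high edge (34.5 Hz). A real symmetric frequency
   mask has exactly zero phase — event boundaries are not lagged, which
   matters because event onset feeds state assignment — and the method is
   O(N log N) at 21.6 M samples per 3-h channel.
2. Envelope: the magnitude of the analytic signal (one-sided spectrum
   doubling).
3. Threshold: `mean + k_sd × SD` of the envelope, computed over
   artifact-free samples of the whole record; excluded sweeps are blanked
   before filtering so that artifact energy cannot leak through the filter
   response into neighbouring sweeps. `k_sd` is per record, default 2.5 —
   the midpoint of the 1.8–3.4 range that per-record visual calibration
   produces in practice. Crossings delimit candidates; runs separated by a
   sub-threshold gap shorter than 100 ms merge, because a single
   within-discharge envelope dip is shorter than one ~9 Hz cycle and must
   not split one discharge in two. Durations are measured after merging.
4. Inclusion: a candidate is kept when strictly longer than 400 ms *or*
   containing strictly more than three spike-wave cycles. Cycles are
   counted as prominent positive peaks of the band-passed segment
   (prominence above half the segment's median envelope), with peaks
   closer than one period of the band's upper edge (1/23 s) collapsed to
   the taller one — two genuine spike-wave cycles cannot repeat faster
   than the band allows, and without the separation rule brief noise
   candidates over-count.
5. Review: by default every inclusion-passing candidate is accepted
   (automated mode). A decisions table reproduces the blinded-rater
   workflow; it is treated as the raters' complete verdict, and it cannot
   resurrect a candidate the inclusion rule rejected.

Events take the behavioral state of the sweep containing their start (a
boundary-spanning event belongs to its start sweep); events starting in
artifact sweeps are dropped. Counts and summed durations are normalized
per state by artifact-free hours in that state; movement is excluded from
event statistics because SWDs essentially never occur during locomotion,
and a state with zero artifact-free hours reports missing rather than
zero. The whole detector is invariant to a global gain factor, since the
threshold is an affine function of the same scaled envelope.

## Spectral summaries

The merged-SWD PSD concatenates accepted event segments in time order and
applies Welch's averaged modified periodogram over consecutive 10-s
windows of the merged series. Welch segments are 1/8 of the window with a
Hamming taper and 50% overlap — the conventional default — floored at 1 s
so that degenerate short merges retain ~1-Hz resolution. All spectra are
binned to 1-Hz bins; bin *b* covers [b−0.5, b+0.5) Hz, which makes the
1–30 Hz band sums unambiguous. By default the merge pools events from
sleep, waking immobility and mixed state; an immobility-only pooling is
available via the `states` argument.

Absolute state PSDs average the per-sweep Welch spectra over the
artifact-free sweeps of a state. The relative PSD divides every 1-Hz bin
by the mouse's own summed 1–30 Hz power and multiplies by 5,000, per mouse
*before* any group averaging; the relative spectrum therefore sums to
exactly 5,000 over 1–30 Hz for every mouse, state and treatment. Group
comparisons run an independent-samples t-test per 1-Hz bin with
Benjamini–Hochberg correction across the 30 tested bins at adjusted
p < 0.05; for treatment-versus-control comparisons the control
conventionally pools both saline sessions.

## Group statistics

Each measure × state family (SWD count/h, total duration s/h, mean single
duration, in sleep / waking immobility / mixed) is first gated by a
one-way repeated-measures ANOVA across treatments with Greenhouse–Geisser
correction: ε is computed from the eigenvalues of the double-centered
sample covariance of the condition columns, both degrees of freedom are
multiplied by ε (clamped to [1/(k−1), 1]), and the p-value uses the
fractional df. Mice missing any treatment in the family are dropped
listwise from the omnibus. When the gate opens at p < 0.05, each drug is
compared with the *first* saline session by a paired, two-sided t-test on
the overlapping mice only, with Benjamini–Hochberg correction across the
drugs of that family. Two-sided tests are used throughout because effect
directions are not pre-specified; the FDR family is the measure × state
cell (configurable), the narrowest family consistent with how the
per-state results are read. The second saline session serves as a
stability check (paired t per measure against the first), not as a
control.

## The synthetic-session generator

The generator exists so that every stage above can be tested against known
ground truth. It emulates, per session: a bout schedule of movement /
immobility / sleep; a trajectory that is a smooth heading random walk
(speeds 1.5–8 cm/s) inside a circular arena of radius 9.25 cm during
movement — steering gently away from the wall so that contacts are grazing
— and sub-threshold jitter (SD 0.005 cm/frame) around an anchor during
immobility; state-dependent background EEG at 2 kHz built from 1/f noise,
1–4 Hz delta (strong in slow-wave sleep), intermittent 12–15 Hz spindle
packets (0.5–0.8 s, ≥2 s apart, sleep only) and 6–9 Hz theta in REM-like
sub-epochs covering ~15% of long sleep runs; spike-wave trains whose
cycles are a slow sinusoid at the fundamental (default 9 Hz) plus a narrow
Gaussian spike (FWHM of one-eighth period) centered on the slow-wave
maximum — this morphology makes the spike count equal the cycle count, so
the cycle-counting operator is generator-verifiable; broadband artifact
bursts in a configurable fraction of sweeps, scaled to ≥2× the exclusion
threshold while clean background stays far below half of it; and tracking
glitches at configurable per-minute rates (lateral turnback spikes of 3×
the local step, which exceed the 135° rule at exactly one vertex and are
restored by a single mean-replacement, and single-frame jumps to one fixed
spurious point outside the arena).

Ground-truth frame states are derived from the schedule by the same
30-s sleep-onset semantics the stager uses, so a perfect stager scores
100%. True events are placed per behavioral state as a Poisson process
over that state's artifact-free sweeps (default rates: 100/h in sleep,
40/h in waking immobility and mixed — saline-like sleep rates in aged
amyloid-model mice are on the order of 100 per hour), with a 2-s
refractory gap enforced by resampling rather than thinning so the counts
stay Poisson with the configured mean, and with onsets constrained to
frames of the matching state and whole events kept clear of movement
frames and artifact sweeps.

Two generator constants deserve explanation. **Discharge amplitude**: the
default peak amplitude is 3× the standard deviation of the session's own
raw background trace. We state this definition precisely because the
superficially similar convention "3× the *envelope* SD" is unusable: for
any narrow-band envelope with Rayleigh-like statistics the envelope mean
is ≥1.9× its SD, so an event whose envelope is 3 envelope-SDs high sits
*below* a mean+2.5 SD detection threshold identically — no detector could
see it. The raw-signal convention reproduces what real recordings show:
discharges that are visually obvious against background, detectable
across the whole 1.8–3.4 `k_sd` range. **Spindle amplitude** (0.04 mV):
chosen so that spindle packets stay below the detection threshold under
default conditions — spindles are the background feature most likely to
fool an envelope detector, and the generator is calibrated so that they
test the detector's specificity without guaranteeing false positives.

What the generator does *not* model: volume conduction and bilateral
coherence (only one analyzed channel is synthesized), unilateral
parieto-occipital discharge subtypes, electrode drift and slow impedance
changes, real nonstationarities of vigilance-state transitions, and
EMG-based staging information (an EMG channel can be synthesized but is
never analyzed). Passing tests therefore demonstrate that the
*implementation* of every rule is correct and that the pipeline recovers
known structure under its stated assumptions — not that the detector's
operating point is optimal for any particular real recording, where `k_sd`
still needs per-record calibration.

## Numerical choices and degenerate inputs

Strict inequalities at printed boundaries (135°, 60%) carry a 10⁻⁹
tolerance against floating-point flips; all other comparisons are plain.
Constant envelopes (SD = 0) yield no candidates with a warning; zero-power
spectra are an error for relative normalization; trajectories with fewer
than 3 (turn correction) or 4 (smoothing) frames pass through unchanged;
identical paired samples give t = 0, p = 1, while a constant non-zero
paired shift is reported as unbounded evidence. Test and validation runs
use reduced problem sizes chosen to keep the full suite comfortably
reproducible on a single core: 30-minute sessions at the native 2 kHz for
detector performance, 460-s sleep-heavy sessions at 250 Hz (the artifact
rule needs Nyquist ≥ 100 Hz; detection needs ≥ 46 Hz) for the 100-seed
rate-recovery and 100-replicate power studies, and 1000 measure-level
replicates for type-I calibration of the gated decision procedure. The
power study uses a two-session design (first saline vs one treatment at a
50% rate reduction across 9 mice), the minimal crossover in which the
omnibus gate, pairing and FDR flagging all operate.

## Known limitations

Candidate boundaries are envelope-threshold crossings, so detected
durations are measured at the threshold, not at the discharge's true
extent; duration statistics are comparable across treatments but are not
unbiased estimates of discharge length. Cycle counting on sub-100-ms noise
candidates can still occasionally reach 4, so automated mode admits a
small false-positive rate on event-free records (about 1–2 per 10 min at
`k_sd` = 2.5); the rater round-trip exists precisely to remove these. The
GCV smoothing parameter is chosen per session and can under-smooth very
short recordings. The staging rules are a deterministic, fixed protocol;
they are not a general sleep-scoring method and inherit the protocol's
10-s granularity and video-only limits.
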