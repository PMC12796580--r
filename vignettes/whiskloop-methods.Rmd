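---
title: "Methods: simulating and analysing photoinactivation experiments in the whisker system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing photoinactivation experiments in the whisker system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskloop)
```

## The experiment being modeled

Awake, head-restrained mice whisk intermittently. Extracellular
recordings are taken simultaneously in barrel cortex (S1) and in one of
two somatosensory thalamic nuclei — POm (higher-order) or VPM
(first-order) — while layer-6 corticothalamic cells expressing
archaerhodopsin are silenced with 550-nm light. The protocol is
sweep-based: blocks of 30 sweeps per condition (light only, air-puff
only, or both), block order randomized within each cycle, the whole
cycle repeated twice. In combined sweeps the light pulse (70 ms)
starts 50 ms before the deflection reaches the whiskers and ends with
it; the air puff itself takes about 10 ms to travel from the trigger to
the whisker pad, and that arrival time is the alignment zero for all
evoked analysis — response latencies of ~5 ms are only physically
meaningful relative to air arrival, not the electrical trigger.

Everything downstream — state segmentation, PSTHs, unit classification,
response metrics, statistics — is implemented against this sweep
structure. Because population-level recordings of this kind cannot be
regenerated at will, the package's first module is a session simulator
with complete ground truth; every analysis stage is then testable as a
parameter-recovery problem.

## The simulator

**Rate model.** Each unit is an inhomogeneous Poisson process

$$r(t) = r_0 \cdot m^{[t \in \text{whisking}]} \cdot
  s^{[t \in \text{suppression window}]} + A\,k(t - t_\text{defl})$$

with baseline $r_0$ (spikes/s), whisking multiplier $m \ge 1$,
photoinactivation factor $s \in [0,1]$ active on
$[\text{light on} + \ell,\ \text{light off}]$ for suppression latency
$\ell$, and an additive evoked kernel of amplitude $A$ at each
deflection. Sampling is by thinning against the exact upper bound
$r_0 m + A$ (plus the second-component amplitude where present), so the
realization is exact for any kernel shape. Suppression multiplies the
background rate only; the evoked kernel is additive on top. The
per-unit random stream is derived deterministically from
`(session seed, unit_id)`, so adding a unit to a population never
changes any other unit's spike train — a property the determinism and
substream tests rely on.

**Evoked kernel.** The whisker-evoked response (WER) kernel rises
linearly from `onset` to `peak` and decays exponentially with time
constant `decay` after the peak. A strict alpha function has a single
time constant and cannot expose independent peak and decay parameters,
so this rise-then-decay family is used instead; it is exactly
integrable,

$$\int_0^\infty k = \tfrac12(\text{peak}-\text{onset}) + \text{decay},$$

which the simulation tests exploit: an amplitude chosen to give 0.5
expected evoked spikes per sweep must produce a total count inside the
exact Poisson interval. A `boxcar` shape (constant on
`[onset, peak]`) is available for step-response calibration of the
onset detector. VPM-like units add a second, late component (default
onset 41 ms) so the biphasic split has ground truth to recover.

**States and LFP.** Whisking and quiet episodes alternate with
exponential durations (means 2 s whisking / 3 s quiet, truncated at
500 ms — bout statistics in awake mice are irregular on roughly this
scale, and no published value constrains them further). The LFP is a
per-episode sinusoid drawn from the quiet band (4–12 Hz) or from the
two active bands (13–30, 25–60 Hz, amplitude split so total
oscillatory power matches), plus broadband Gaussian noise
(default SD 0.5 against oscillation amplitude 1). What this emulates is
exactly the feature the classifier uses — dominant band power tracking
state. What it does **not** emulate: 1/f background, spectral
nonstationarity within an episode, movement artifacts, or volume
conduction; passing the segmentation tests therefore shows the rule is
implemented correctly and separable under clean band structure, not
that it would reach the same accuracy on real LFP.

## State segmentation

The spectrogram is a sliding Welch estimate: 1-s windows with 50%
overlap, each averaged over four half-overlapping Hamming-tapered
segments (window length and overlap are free choices — recording
practice rarely reports them — and are exposed as parameters). Per
window the discriminant is the ratio of linear power integrated over
the *union* of the active bands (the two bands overlap at 25–30 Hz;
integrating the union avoids double counting) to power in the quiet
band. Ratio above 1.5 → whisking; below 1/1.5 → quiet; anything in
between, including an exact tie, is excluded. Episodes shorter than
500 ms are relabeled excluded. The threshold 1.5 is symmetric on a log
scale and was fixed a priori; raising it can only shrink the labeled
set (a tested monotonicity property).

The human-verified classification this replaces removed ambiguous
"active non-whisking" time from analysis; the excluded label implements
that removal rule. Consequently segmentation accuracy is reported over
the *labeled* portion of the session (with the labeled fraction
alongside): excluded time never enters any PSTH denominator, so the
operative question is whether the time that *is* analyzed carries the
right label. A sweep inherits a label only when a single labeled
episode covers its entire analysis window (default −200 to +100 ms
around the deflection); sweeps straddling transitions are excluded,
which is why realized per-condition sweep counts differ between states
— all rate denominators use the realized counts.

## PSTHs and rates

Bins are half-open `[t, t + 2 ms)` — a spike exactly on an edge belongs
to the right bin — and rates are per-sweep-normalized:
`count / n_sweeps / bin_width`. The bin width default of 2 ms matches
the binning of the onset criterion. Window rates over selected sweeps
use the number of included sweeps times the window duration as the
denominator and refuse empty selections explicitly rather than
returning NaN.

The optional spike detector band-passes 300–3000 Hz (4th-order
zero-phase Butterworth) and takes negative-going crossings of 4 SD. The
SD is computed over the whole filtered trace: the convention of
estimating noise from "background" segments requires a segmentation
this package does not own, and the whole-trace SD is a conservative
stand-in (spiking inflates it, raising the threshold slightly).

## Unit classification

**Opto-tagging.** The criterion compares the mean rate in the first
5.5 ms after light onset (2-ms bins of the sweep-averaged PSTH; the
three bins overlapping the window) against baseline statistics from
the 200 ms before the pulse. The default rule requires the tag-window
rate to fall to `max(0, μ − 2σ)`; a criterion sometimes printed as
"below μ + 2σ" is almost certainly a sign error — any unit whose rate
merely fails to increase would satisfy it — but it is kept selectable
(`rule = "literal"`) so the discrepancy is auditable. When
`μ − 2σ < 0` (common for low-rate units) the fallback requires exactly
zero tag-window activity plus a full-pulse rate below baseline. Units
with baseline under 1 spike/s are unclassifiable and excluded. The
comparison uses the averaged PSTH, not per-sweep variance — with per
bin σ of order `sqrt(μ / (bin · n_sweeps))`, the criterion is noisy at
60 light sweeps per session (the protocol scale) and sharp in the
large-sweep regime; the tag-recovery analyses therefore run thousands
of light sweeps per unit, which measures the criterion itself rather
than its small-sample behavior.

**Interneurons** are a strict conjunction (asymmetry > 0.15,
trough-to-peak < 0.3 ms, half-width < 0.2 ms) and are excluded from all
population analyses. **Layers** map half-open depth intervals; depths
above the L2/3 border are "outside".

## Response metrics

The onset is the left edge of the first run of at least five
consecutive post-stimulus bins strictly above baseline mean + 2 SD;
with fewer than five bins the run does not count, and a PSTH that never
qualifies has no onset (never a fabricated zero). By construction the
detector cannot fire before the stimulus. The peak is the maximum bin
between 0 and 100 ms, ties resolved to the earliest bin; the slope is
the OLS fit of bin rate on bin-center time over `[onset, peak]`,
reported in spikes/s per ms (a slope printed "in spikes/s" divides out
the time axis ambiguously; both the raw OLS value and the time span are
available to the caller). The biphasic split integrates 5–40 ms and
41–100 ms by bin centers, so adjacent windows sharing an edge do not
double count; the late POm response sometimes seen at 50–150 ms is
deliberately not a default window. Control-minus-light deltas require
identical binning and alignment on both PSTHs.

## Statistics

The two-factor repeated-measures ANOVA is fit via the standard error
strata (each within effect tested against its effect-by-subject
interaction); a mixed variant treats the column factor as
between-subjects, since descriptions of this design alternate between
the two readings — the choice is a per-analysis flag. No sphericity
correction is applied: every within factor here has two levels, where
sphericity holds trivially. Post-hoc comparisons use the pooled error
mean square of the stratum in which the column factor is tested, with
Bonferroni multiplication by the number of row levels. An independent
brute-force sums-of-squares oracle (marginal-mean arithmetic, no model
fitting) pins the decomposition to 1e-9 relative tolerance in the
tests, and total SS conservation is asserted exactly.

ROUT-style outlier removal implements the location-only case
sufficient for per-unit difference scores: median location, robust
scale from the 68.27th percentile of absolute residuals with an
`n/(n−1)` small-sample correction, t-distribution p-values, and a
step-up FDR threshold at rate Q over the most extreme 30% of points.
Replicating a commercial implementation's internals bit-for-bit is a
non-goal; the flags are affine-invariant and monotone in Q, which is
what the downstream exclusion logic needs.

Degenerate inputs have explicit conventions: zero-variance identical
samples give t = 0, p = 1 (no evidence of difference); zero variance
with a nonzero mean difference gives ±Inf, p = 0.

## Pipeline, exclusions, and problem sizes

`run_pipeline()` chains the stages and applies the exclusion sequence
— interneurons, unclassifiable units, then robust outliers on
quiet-state suppression deltas — before any statistics; the run log
records the census so that
`units_in = analyzed + interneurons + unclassifiable + outliers`
exactly. Grouping can follow the opto-tag classifier or the simulated
ground truth: parameter-recovery analyses (e.g. verifying that the
estimated control-minus-light delta matches
`base × (1 − s) × suppressed-window fraction`) use ground-truth
grouping deliberately, so classifier error does not contaminate rate
estimation; classifier quality is measured separately.

Problem sizes used in the shipped analyses: the default session is the
protocol scale (180 sweeps, ~6 minutes of simulated time, 38 units);
tag-recovery runs 50 units × 4000 light sweeps (the asymptotic regime
of the averaged-PSTH criterion); onset calibration uses 200 replicates
of 30 sweeps; the null-calibration of the paired test uses 1000
replicates of 8 units × 20 sweeps per condition. These sizes make every
recovery criterion sharp at desk scale while each stage remains exact
at any size.

## Known limitations

The simulator's independence assumptions (Poisson spiking, no
refractory period, no cross-unit correlations, stationary rates within
a state) are stronger than real data; the LFP lacks 1/f structure; the
"active non-whisking" state cannot be distinguished from whisking
without video, so it is absorbed into the exclusion rule; and the
opto-tag criterion's small-sample behavior at 60 sweeps is
intrinsically noisy for units below ~3 spikes/s. Session export is the
documented CSV layout; no NWB writer is included.
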