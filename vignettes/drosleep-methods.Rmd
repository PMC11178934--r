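---
title: "Methods: simulation, staging and statistics in drosleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, staging and statistics in drosleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drosleep)
```

## Scope

`drosleep` implements the computational stack of a comparative study of
sleep across Drosophila species: ethoscope-style activity recordings are
scored for sleep by the five-minute immobility rule, staged into four
behavioral states with a constrained hidden Markov model (HMM), probed
for arousal threshold with air-puff/mock stimulus schedules, analyzed
for circadian rhythmicity with the chi-square periodogram, and compared
across deprivation protocols with exact rank statistics. Because the
original behavioral datasets are hundreds of gigabytes, the package
ships a generative simulator whose cohorts exercise every stage of the
pipeline end to end; all validation runs on simulated data with known
ground truth.

## The generative model

A fly is a time-inhomogeneous Markov chain over four states —
`ACTIVE_WAKE`, `QUIET_WAKE`, `LIGHT_SLEEP`, `DEEP_SLEEP` — stepped at a
10 s bin. Per bin the chain emits one of three movement symbols,
`MOVING`, `MICRO` (micro-movement: twitch or posture shift without
locomotion), `IMMOBILE`. The 10 s bin resolves the 30 s closed-loop
immobility trigger while keeping three days of data at ~26k bins per
fly; the three-symbol alphabet realizes the distinction between total
and partial inactivity that the probing protocol targets.

Transition weights blend a day and a night base matrix through a smooth
periodic night weight (logistic edges at ZT 0 and ZT 12, width about
1 h), with multiplicative bumps: crepuscular activity peaks at ZT 0 and
ZT 12 (entries into active wake), a mid-day siesta bump on
wake-to-light-sleep entries whose amplitude is sex-specific, and an
early-night bump (center ZT 13.5) on deep-sleep entry. The last bump is
a field added to the parameter set (`night_depth_amplitude`) because a
time-homogeneous night matrix cannot concentrate deep sleep in the
early night, which is a robust cross-species observation. Deep sleep is
entered only through light sleep and exits only into light sleep —
awakening from deep sleep passes through light sleep — mirroring the
structural constraints imposed on the staging model. Under constant
darkness every modulation amplitude is scaled by `dd_rhythm_amplitude`;
at zero the chain is homogeneous (arrhythmic), and the free-running
period is kept at 24 h rather than species-specific values, a
simplification that suffices for rhythmicity calls.

Sleep pressure follows a linear homeostat: `P` rises by `pressure_rise`
(default 0.5 h⁻¹) per hour awake and falls by `pressure_decay` (default
1.2 h⁻¹) per hour asleep, clamped at zero. No published functional
form exists for fly sleep-pressure dynamics at this level of
description; the linear form is an explicit stand-in. Pressure couples to behavior through a
protocol-selected gain: wake-to-sleep entry weights are multiplied by
`1 + gain * P` and light-sleep exit weights are divided by the same
factor. The second coupling (consolidation) is a deliberate extension
of the simplest entry-only mechanism: with entry promotion alone,
recovery sleep is more frequent but remains fragmented below the 5-min
rule, and no scored rebound appears at all — sleep homeostasis
empirically consolidates sleep, and the model needs that to express a
measurable rebound. Mechanical deprivation couples through
`homeostasis_gain_mech`, social deprivation through
`homeostasis_gain_social`; the dissociation between the two pathways is
what the species presets vary.

The closed loop watches the *emitted symbol stream* (as the hardware
watches the video tracker): after `tau` seconds of continuous
non-moving observation a stimulus fires — with probability `pi` a real
one, otherwise a logged mock — and the timer resets on every event and
on every moving bin. Real air puffs wake the fly with the
state-specific `arousal_prob` (wake states always respond); the 400 rpm
tube rotation of mechanical deprivation uses a flat high waking
probability (0.98) instead, reflecting that it is a far stronger
stimulus than a puff. Social deprivation is modeled as an intruder
present ZT 0–23 of the deprivation day that both suppresses
wake-to-sleep entries (×0.05) and amplifies sleep exits (×6); the net
effect is forced wakefulness with a little residual fragmented sleep.

### Species presets

The seven presets share one emission matrix and the base transition
architecture and differ where the species differ:

* homeostasis gains — melanogaster-like: both > 0; simulans-,
  sechellia-, yakuba-like: social only; erecta-, willistoni-,
  virilis-like: none;
* deep-sleep entry — erecta-like enters deep sleep rarely and leaves it
  faster, giving a light:deep ratio of roughly 5 versus roughly 1.5–2
  elsewhere. The real outlier species shows a ratio near 10, but at
  that rarity the deep state carries under 1.5% of bins and a 4-state
  HMM fitted at desk scale no longer identifies it; the preset keeps
  the direction (far above every other preset) at an identifiable
  magnitude;
* free running — virilis-like has `dd_rhythm_amplitude = 0`
  (arrhythmic in constant darkness) and a female-biased siesta; all
  others stay rhythmic in DD with a male-biased siesta.

Defaults for sample sizes in the shipped analyses are 20 flies × 3 days
per preset for staging and 40 flies per arm × 20 replicates for the
rebound comparisons — large enough for the claims tested, small enough
to run on one CPU in minutes.

## Sleep scoring and quality control

Sleep is any maximal run of non-moving bins (micro-movement counts as
inactivity) lasting at least 300 s. Bins are half-open, left-aligned,
0-based from recording start; ZT is attached after binning. Micro
movements count as life for the dead-fly rule — a fly is dead when its
final 12 h contain no moving or micro bin; published protocols state
the dead-fly exclusion without an operational criterion, so the rule
here is deliberately conservative and testable. Flies asleep more than 30% of a deprivation
window are excluded as deprivation failures; the boundary is a strict
inequality (exactly 30% is kept), matching the usual phrasing of the
rule.

## Staging model

The staging HMM has the same four states and three symbols as the
generator, with structural zeros: deep sleep enterable only from light
sleep or itself, and never exiting directly to active wake. Fitting is
Baum–Welch EM (scaled forward–backward in compiled code), 5 restarts,
tolerance 1e-4 log-likelihood units, at most 500 iterations, with a
floor of 30 iterations: rare emissions (a sleep state's probability of
`MOVING`) decay geometrically toward zero across iterations and need a
few dozen more steps to collapse after the log-likelihood has
plateaued; stopping early would leave spurious mass that lets Viterbi
bridge movement bins inside sleep bouts. Restarts draw Dirichlet rows
centered on the behavioral roles the constraint mask encodes (wake
states mobile, sleep states immobile, deep stickiest) so that the
positional constraints keep their intended meaning during EM; after
fitting, restarts whose canonically relabeled transition matrix
violates the mask (scrambled local optima that repurposed the
constrained state) are rejected and the best consistent restart wins.

Labels are assigned by behavioral signature: the state with the highest
`MOVING` emission is active wake; of the rest, the two most
immobile-emitting states are the sleep states, the longer-dwelling one
(`1/(1 - A[s,s])`) deep; ties break on immobile emission. Decoding is
Viterbi — posterior decoding would maximize per-bin accuracy but
fragments bouts, and every downstream analysis is bout-based.

Bouts truncated by a recording boundary are flagged censored and
excluded from duration-based summaries (the long-immobility agreement
and the deep-bout inactivity floor): a censored episode's true duration
is unknown, and at the start of a recording the decoded labels
additionally depend on an arbitrary initial distribution.

## Arousal probing

The scheduling logic is replayed ex post on binned data for analysis
(`schedule_events`), identical to the loop embedded in the simulator. A
response is any moving bin within 30 s after the event; mock events are
scored identically and measure spontaneous awakening. When validating
against the generator's arousal map, response probabilities are
corrected for spontaneous movement with the mock rate:
`wp = (p_real - p_mock) / (1 - p_mock)`. Decoded-stage response rates
are *not* expected to match the generator map: an awakened fly
truncates its immobility run, which changes the decoded label of the
delivery bin (short runs decode as quiet wake, long ones as sleep), an
outcome-dependent selection intrinsic to any ex-post pairing of staging
with probing. The ordering of
response probabilities across decoded stages (wake ≥ light ≥ deep;
real ≥ mock within sleep stages) is the validation the pipeline
asserts.

## Chi-square periodogram

For a candidate period of `P` bins the series is folded into `P` phase
columns and `Q_P = Σ_h K_h (M_h − M̄)² / σ̂²` is referred to χ² with
`P − 1` degrees of freedom (Sokolove–Bushell convention; unequal column
counts use all data, with a switch for complete-cycle truncation; for a
noiseless periodic signal over complete cycles `Q = N` exactly). The
activity metric is the count of moving bins per 30 min. Candidate
periods lie on the bin grid in 16–32 h. The significance threshold is
Bonferroni-corrected across the candidate grid by default: behavioral
series are autocorrelated at the bout scale, and an uncorrected
per-period α = 0.05 over ~33 candidates called the majority of truly
arrhythmic simulated flies rhythmic. With the correction the
DD-arrhythmic preset yields no significant peak in ≥ 90% of flies while
the rhythmic presets peak at 24 ± 0.5 h. A single-period scan is
unaffected by the correction, and the per-period call at 24 h on iid
noise keeps its nominal type-I rate. "Power" is reported as
`Q − threshold`, and the peak is the most powerful significant period.

## Statistics

The deprivation/rebound comparisons use the exact Wilcoxon rank-sum
test with mid-rank ties: full enumeration when `C(n+m, n) ≤ 1e5`, an
exact shift-algorithm convolution up to 200 pooled observations, and
seeded Monte-Carlo permutation beyond; the p-value is the probability
of a rank sum at least as far from its null expectation as observed.
FDR adjustment is Benjamini–Hochberg. Cohort time courses get
percentile bootstrap bands over flies (default 1000 resamples). The
sleep-pressure trend over chronic deprivation is a per-fly Spearman
correlation of daily delivered-stimulus counts against the day index,
combined by a Wilcoxon signed-rank test against zero — no canonical
test exists for this readout, so the choice is the package's own. Survival comparisons are standard log-rank via the
survival package, pairwise with FDR when more than two groups.

## What the simulations do and do not show

The generator reproduces the structure the pipeline is meant to
extract: crepuscular bimodal activity, night-dominant sleep with a
sexually dimorphic siesta, two sleep depths with distinct arousal
thresholds, early-night deep sleep, closed-loop deprivation dynamics,
and species-dissociated homeostatic rebound. It does not emulate
tracking noise or dropouts, position within the tube, stimulus
intensity gradations, temperature effects, inter-individual parameter
variability beyond seed noise, or mortality. Passing the end-to-end
suites therefore demonstrates that the analysis code is correct and
self-consistent on data with this structure — not that the biological
parameter values are those of real flies. Where a quantity has a
printed anchor (the 1.5 light:deep ratio, 100% of 5-min bouts staged
as sleep, the 8-min deep-bout inactivity floor, the 24 h free-running
peak), the simulated pipeline reproduces it through the full
train-and-decode path.

## Numerical choices and degenerate inputs

Stochastic matrices are validated to row sums within 1e-9. Forward
passes are scaled (no log-space underflow); Viterbi runs in log space
with exact `-Inf` for structural zeros. EM M-steps keep masked entries
at exactly zero and leave a row unchanged if its expected count
vanishes. Single-symbol training data produce a warning and a flagged
best-effort fit. Zero-variance activity series are a hard error in the
periodogram, as is a light:deep ratio with no deep sleep, and an
all-censored survival comparison returns p = 1 with a flag rather than
a statistic. Model serialization is plain text at 17 significant
digits, round-tripping exactly. Master seeds derive per-fly seeds as
`(seed * 10007 + i) mod (2³¹ − 1)`, keeping every stream reproducible
and within R's integer range.

```{r example}
co <- simulate_cohort("melanogaster_like", protocol("baseline", duration_h = 48),
                      n_flies = 3, seed = 1)
sc <- score_sleep_5min(bin_movement(co$recordings[[1]], 10))
c(day = sleep_amount(sc, c(0, 12), day = 1),
  night = sleep_amount(sc, c(12, 24), day = 1))
```
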