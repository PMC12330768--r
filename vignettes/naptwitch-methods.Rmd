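---
title: "Methods: models, detectors, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, detectors, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(naptwitch)
```

This vignette documents the scientific and numerical choices behind
`naptwitch`: what each stage computes, what the synthetic-cohort generator
does and does not emulate, and where the design was genuinely open.

## Time conventions

All times are seconds from recording start. Intervals — artifact windows,
spindle events, analysis windows — are half-open `[start, end)`, so abutting
intervals neither overlap nor leave gaps and durations add exactly. Sleep
stages come as 30-s epochs labeled `W, N1, N2, N3, REM`; sample `i` of a
recording covers `[(i-1)/fs, i/fs)`.

## Preprocessing

The wide-band stage uses zero-phase (forward–backward) IIR filters: a
0.5–70 Hz Butterworth pass band (2nd-order high-pass cascaded with a
4th-order low-pass) and a 2nd-order band-stop notch at 60 ± 2 Hz.
Forward–backward application makes the response zero-phase, so event
latencies are preserved; a symmetric pulse stays symmetric.

The two *narrow* analysis bands — 11–15 Hz for spindles and 0.5–4 Hz for
delta — are filtered in the frequency domain instead: gain exactly 1 inside
the band and 0 outside, with raised-cosine transition ramps (1 Hz wide,
capped at the lower band edge). The reason is quantitative: a forward–
backward Butterworth 11–15 Hz band-pass has gain ≈ 0.5 at 13 Hz, i.e. it
attenuates the very rhythm being measured, which would halve every spindle
amplitude and bias the envelope threshold. The FFT design is exactly
zero-phase and unity-gain where it matters. Its cost — circular boundary
effects over a few seconds at the recording edges — is negligible at
session length.

Bad-channel repair is an inverse-distance weighted average over a
user-supplied neighbor map. Spherical-spline interpolation would require
electrode geometry that the analysis does not otherwise need; with the few
channels synthesized here the result does not depend on the interpolation
scheme, so the map is plain data (labels and distances) and the weights are
`1/d`, normalized over good neighbors.

Downsampling low-passes at 80% of the target Nyquist frequency (6th-order
Butterworth, zero-phase) before decimation.

## Spindle detection

The detector thresholds the amplitude envelope (magnitude of the analytic
signal) of the 11–15 Hz band at **2× the median** envelope over
artifact-free samples. The median is taken over all artifact-free samples
by default; a `median_scope = "sleep"` switch restricts it to sleep epochs,
since "artifact-free periods" can be read either way. An event must stay
supra-threshold for ≥ 1 s; sub-threshold dips shorter than 1 s are absorbed
into the event, and the offset is the first sample of the first
sub-threshold run lasting ≥ 1 s. The 1-s offset rule logically implies that
two bursts separated by a shorter dip are one event, so merging (not
restarting) is the implemented reading. Events overlapping an artifact
interval are discarded. Because the threshold is median-relative, detection
is invariant to a global rescaling of units.

One numerical choice needs emphasis: the envelope is smoothed with a 0.3-s
centered moving average before thresholding. The raw Hilbert envelope of
*any* band-limited Gaussian noise is Rayleigh-distributed and exceeds twice
its median about 6% of the time regardless of the noise level; combined
with the 1-s dip-absorption rule this chains noise excursions into on the
order of one to several spurious events per minute. Smoothing over roughly
one envelope correlation length suppresses these exceedances (measured
false-positive rate on pure pink noise: ≈ 1.4/min at 0.2 s, ≈ 0.45/min at
0.3 s, our default) while changing a planted noiseless 20 μV spindle's
measured amplitude by under 5%. Recall on synthetic recordings at the
default signal-to-noise remains ≥ 0.99.

Features: amplitude is the maximum envelope value within the event (μV);
peak frequency is the argmax of an 8×-zero-padded periodogram of the
band-passed segment, restricted to the band. Zero-padding interpolates the
spectral grid to ~0.1 Hz for a 1-s event, well below the carrier spread of
interest; the estimator itself is unbiased for an isolated tone burst.

## Delta power and NREM windows

Delta power is the squared amplitude envelope of the 0.5–4 Hz band (μV²)
at every sample. Each maximal contiguous NREM run (N2/N3 with no
intervening W, N1, or REM) is tiled left-to-right into 60-s windows;
remainders and windows intersecting an artifact are dropped. Windows may
span an N2↔N3 transition — the analysis pools "NREM" — and carry the
majority stage as a label. Twitches belong to a window by onset time,
consistent with the coupling convention below.

## Twitch metrics

Stage rates divide onset counts by artifact-free stage minutes. Inter-event
intervals are onset-to-onset gaps between successive events, excluded
whenever the pair spans a stage change, wake, or a masked artifact. Burst
segmentation chains events greedily while successive onset gaps are
*strictly* below 0.5 s (a tie at exactly 0.5 s breaks the chain, matching
the strict inequality of the definition); chains of length ≥ 2 are bursts.
Chains cannot span stage transitions or artifacts — the definition is
silent there, but the choice is consistent with the interval exclusions.
Inclusion rules ("at least 10 twitches and 10 spindles in both N2 and N3",
"at least 2 min of artifact-free N2 or N3", …) are data, not code: a table
of `(metric, stage, min)` thresholds evaluated against a per-infant summary.

Two-coder agreement matches events greedily by onset within 1 s, aligns
matched events to the primary coder, bins both streams at 1 s, and computes
Cohen's kappa on the per-bin 2×2 table. The binning grain is a package
choice; the tabulation underlying the published kappas is not specified
anywhere we could follow.

## Coupling and the shuffle null

Co-occurrence is anchored on twitch **onset**: a spindle co-occurs if at
least one twitch onset falls inside its `[onset, offset)`; a twitch
co-occurs if its onset falls inside a spindle. Anchoring both directions on
the same point event keeps P(Spindle | Twitch) and P(Twitch | Spindle)
consistent counts of the same overlap relation; whether a twitch whose
duration (but not onset) overlaps a spindle should count is genuinely
ambiguous, and onset-in-interval is the single consistent rule adopted.

Perievent curves report, for each 1-s bin offset in ±20 s around a trigger
(twitch onset, or spindle midpoint for the inverted analysis), the fraction
of triggers with a target present in that bin — interval overlap for
spindle targets, onset membership for twitch targets. Bin width 1 s is a
package default, exposed in the configuration.

The null model is an interval-preserving shuffle: within each segment the
multiset of inter-event intervals is kept exactly and only the order is
permuted, with the first onset anchored, so the surrogate train has the
same rate, the same interval distribution, and never leaves the segment.
Segments are maximal artifact-free same-stage runs; respecting stage
boundaries is the conservative choice and is configurable. Each surrogate
index derives its own seed, so results are reproducible and independent of
evaluation order. Expected probabilities are surrogate grand means; bands
are per-bin 2.5/97.5 percentiles. With no planted coupling, the observed
probability exceeds the upper band in ≈ 2.5% of replicate simulations
(measured ≤ 7.5% at 200 replicates, the binomial slack at that replicate
count).

## The mixed model

Window twitch counts are modeled linearly (Gaussian, identity link), as in
the source analysis — counts are large enough (≈ 6/window) that a log link
would change the estimand, not improve it. Delta is decomposed by
person-mean centering: `MeanDelta_i` (infant mean, centered on the observed
grand mean of infant means — not a hard-coded constant) and
`WithinDelta_ti` (deviation from the infant's own mean), both divided by
100 so slopes are per 100 μV². The model is a random-intercept REML fit
with Satterthwaite denominator degrees of freedom (the fractional df
reported for such models imply a Satterthwaite-type method; the method used
is recorded in the fit's metadata rather than asserted). The ICC of delta
comes from the intercept-only random-intercept decomposition. Singular
fits are flagged, not errors.

## Group statistics

Normality gates use Shapiro–Wilk on the paired *differences* — the
quantity the paired t test assumes normal; p < .05 routes to the Wilcoxon
signed-rank test. The Friedman test uses within-subject ranks; Conover
all-pairs post hocs use the standard rank-sum statistic on a t distribution
with (n−1)(k−1) df, Dunn–Šidák-adjusted. The two-way repeated-measures
ANOVA delegates its numerics (including Mauchly's test and the Huynh–Feldt
ε) to the multivariate linear-model machinery in `car`; this package owns
the gating (correction applied only when Mauchly p < .05), partial η²
(`SS_effect / (SS_effect + SS_error)`), and the report schema. A fully tied
Friedman design short-circuits to χ² = 0 rather than a 0/0.

## The synthetic cohort

The generator's defaults are the study conditions; they are not tuning
knobs. Stage structure, event rates, spindle properties, the coupling
level, and the mixed-model truth are all planted at the reported group
values, and the tests recover them.

**Hypnograms.** A semi-Markov chain with geometric bout lengths: per stage,
the bout count is Poisson with mean `total_epochs / mean_bout_epochs` and
bout lengths are geometric with the configured mean, interleaved in random
order. Expected per-stage totals equal the configured means exactly
(REM 5.44, N2 4.87, N3 16.25 min), and — as in the real cohort — a given
infant can lack a stage entirely. The bout-length law and the mean bout
lengths (REM 6, N2 4, N3 10 epochs) are package choices; no bout statistics
were reported.

**Twitch trains.** Per stage, a cluster process: burst clusters (≥ 2
twitches, within-burst gaps uniform on 0.05–0.45 s) and single twitches,
with inter-cluster gaps of 0.5 s plus an exponential tail. The burst-size
mean, cluster-type probability, and gap rate are solved in closed form from
the configured aggregate rate, burst rate, and proportion-in-burst
(renewal-reward), so all three are matched in expectation — e.g. N2:
13.45 twitches/min, 2.58 bursts/min, 0.63 in bursts. The ≥ 0.5-s
inter-cluster spacing mirrors the definition of a single twitch (> 0.5 s
from both neighbors); without it, chance chaining across clusters would
inflate the realized proportion-in-burst above its planted value. A
configuration whose implied mean burst size falls below 2 is rejected with
an explanation. No generative model of twitching was reported; this
burst/single mixture is one compatible choice, not a claim about mechanism.

**Spindle trains and EEG.** Ground-truth spindles arrive per stage as a
renewal process with a ≥ 2-s refractory gap (planted events stay well
separated, which is what detector recall is defined on), durations uniform
on 1–2.5 s, carriers Normal(13.15, 0.09) Hz, peak amplitudes within 10% of
20 μV. The EEG is pink (1/f) noise plus a hard-band-limited 0.5–4 Hz delta
component whose amplitude follows a per-second schedule — stage scale
(N3 > N2) times a slow log-normal fluctuation so 1-min windows genuinely
vary — plus Hann-windowed spindle sinusoids. The broadband noise SD
defaults to 3 μV; detector-recovery studies use 1 μV, i.e. in-band noise
some two orders of magnitude below spindle amplitude, which is what "high
signal-to-noise" means here. The delta scale map (N2 0.55, N3 1.13, …) is
chosen so the duration-weighted NREM mean equals the 1100 μV² grand mean.

**Coupling.** `p_twitch_given_spindle` is planted as the *realized*
conditional probability: exactly `round(p·n)` spindles end up containing a
twitch onset (twitches are relocated in, or inserted with a warning when
none are available) and twitch onsets are relocated out of the remaining
spindles. A literal "relocate into a fraction p and leave the rest alone"
procedure would add chance co-occurrence (~0.3 at N2 rates) on top of p and
make the parameter unrecoverable; planting the realized value keeps one
interpretable knob. `p = 0` leaves the train untouched — the independent
null used for calibration. P(Spindle | Twitch) is emergent from the rates,
not planted: fixing both conditionals would over-constrain the bipartite
overlap structure.

**Window-level dataset.** The mixed model's dedicated generator plants
`MeanDelta_i ~ Normal(1100, σ²_b)` and centered within-window deviations
with `σ²_b/(σ²_b+σ²_w) = 0.57`; twitch counts are a rounded,
floored-at-zero Gaussian response with fixed effects γ00 = 6.07,
γ10 = −0.93, γ01 = −0.01 (per 100 μV²), an infant random intercept, and
Gaussian residual — linear, matching the model fitted to it. Three scale
parameters are not reported anywhere and were fixed once from reported
quantities: the residual-to-effect ratio follows from the per-infant
R² ≈ 0.29 (residual SD ≈ 1.56 × effect SD, the same ratio implied by the
within-slope standard error at ~300 windows); the within-infant delta SD is
set to 150 μV² so that, with these effects, fewer than ~2% of latent counts
fall below zero and the rounding/flooring leaves the linear model
essentially unbiased; the random-intercept SD is 1.2 twitches. Per-infant
deviations are centered exactly, so within-predictor sums are zero by
construction.

**What the generator does not emulate.** Real EEG morphology beyond band
structure (no K-complexes, no respiration or cardiac artifact); heavy-tailed
and nonstationary noise; between-infant differences in the *EEG-route*
delta level (the EEG generator plants stage structure and coupling, while
the ICC-matched variance split lives in the window-level generator — so the
EEG-route window table has a much smaller ICC than 0.57, and the EEG route
does not plant the within-infant delta–twitch slope at all, only the
stage-level association that N3 has more delta and fewer twitches);
visual scoring noise in hypnograms. Passing tests therefore demonstrate
that each estimator recovers what was planted under its stated model, not
that the detectors would perform identically on recorded infant EEG.

## Problem sizes

The test and acceptance studies use: 50 replicate cohorts of 21 infants ×
20 windows for slope recovery; six to eight replicates of 100 × 50 windows
for the ICC; 10–20 two-hour single-stage sessions for rates and bursts;
10 one-hour sessions for coupling; 200 replicates × 200 permutations for
null calibration; and 6–10 half-hour to one-hour EEG sessions for the
detector. These sizes put Monte-Carlo error comfortably below the planted
effects while keeping the full suite within a desk-scale run.

## Known limitations

- The detector's envelope smoothing trades a few percent of amplitude on
  the shortest (1-s) events for a ~tenfold reduction in false positives on
  noise; both numbers are measured in the test suite.
- Conditional probabilities are undefined (NA, flagged) for infants with no
  spindles or no twitches in a stage; group summaries must apply the
  inclusion rules first.
- The Conover post hoc is the unprotected all-pairs form with Dunn–Šidák
  adjustment; other implementations differ in the protection scheme.
- `write_cohort()` emits CSV matrices, not EDF; no EDF writer is part of
  the package's dependency set.
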