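---
title: "Detecting daily and ultradian transcriptome rhythms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting daily and ultradian transcriptome rhythms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarhythm)
```

## The problem

Field chronobiology studies of marine zooplankton sample animals repeatedly
over a single day — typically seven samplings at 4 h intervals covering 24 h,
with a few replicate pools of animals per sampling — and ask which
transcripts oscillate, at what period, with what peak time (phase) and
relative amplitude. At high Arctic latitudes around the summer solstice the
sun never sets, so the interesting contrasts are between *daily* rhythms
(20 or 24 h periods, trackable to the residual diel cycle of solar
elevation) and *ultradian* rhythms (12 or 16 h periods, of which ~12.4 h
matches the semidiurnal tide), and between stations that differ in latitude
and sea-ice cover.

polarhythm implements that analysis end to end: a rank-based rhythm
detector at candidate periods of 24/20/16/12 h, phase/amplitude
characterization of the detected transcripts against deterministic models
of the solar and tidal cycles, cross-station comparison of the rhythm
architecture, flat over-representation analysis, and a synthetic-data
generator that plants known rhythms so every stage can be validated without
access to any particular sequencing data set.

## The detection statistic

For a candidate period $P$, samples are folded by their cycle position
$t \bmod P$ (positions equal after rounding to one minute fold together).
On the default design the 24 h fold yields $m = 6$ groups of sizes
6/3/3/3/3/3 (the 0 h and 24 h samplings coincide), the 12 h fold $m = 3$
groups of sizes 9/6/6.

The alternatives are *cyclic umbrella orderings*: expression rises over $r$
cycle steps to a peak group and falls over the remaining $m - r$ steps,
wrapping around the cycle. A pattern is a (peak index, rise length) pair;
there are $m(m-1)$ of them. Each pattern is scored with a
Jonckheere–Terpstra-type statistic
$$U = \sum_{(a,b)} \#\{x \in g_a,\, y \in g_b : x < y\}
      + \tfrac12 \#\{x = y\},$$
summed over all group pairs within the rise chain, plus all pairs within
the fall chain with reversed orientation. $U$ depends on the data only
through ranks, so the test is invariant under any strictly increasing
transform of a transcript's values and robust to the heavy tails of
expression data.

The p-value of a pattern is the right tail of $U$ under random assignment
of the pooled values to the observed group sizes. Three deterministic
routes are used:

* **Full enumeration** when the pooled sample has at most `exact_n = 12`
  values and at most `exact_cap = 2e5` distinct assignments: exact for
  arbitrary tie structures.
* **A counting dynamic program** for larger tie-free samples (the generic
  case for continuous expression values): inserting the values in
  decreasing order and tracking group occupancies gives the exact null
  distribution of $U$, because placing the next value in group $g$ adds the
  occupancy of every high-side partner of $g$. The distribution depends
  only on (sizes, pattern) and is cached for the session. Assignment counts
  stay below $2^{53}$ on the supported designs, so the tail probabilities
  are exact to machine precision. This matters: with 21 samples in 6
  groups a strong rhythm can reach tail probabilities around $10^{-9}$,
  far beyond the resolution of any normal approximation.
* **A tie-corrected normal approximation** (with continuity correction)
  for larger samples with ties. Rather than a textbook variance formula —
  none covers the cyclic two-chain statistic — the permutation mean and
  variance are computed *exactly* from the pooled tie structure by
  pair-overlap combinatorics, so the approximation is correct in its first
  two moments for any pattern and any tie pattern. The test suite checks
  both moments against exhaustive enumeration.

Per transcript and period, the $m(m-1)$ pattern p-values are combined by
Bonferroni: `raw_p = min(1, m(m-1) * min(p))`, with the best pattern
reported (ties broken toward the lowest peak index, then the lowest rise
length). Bonferroni over the patterns is deliberately simple and
conservative; the patterns are strongly dependent (reversed shapes are
near-complementary), so the realized per-period false-positive rate at a
nominal 0.05 sits around 0.02–0.04. The cost is real power on marginal
rhythms — a dependence-aware combination would detect more — and we accept
it for the sake of an exactly characterizable null. The null calibration
and its conservatism are asserted in the test suite.

Benjamini–Hochberg adjustment is then applied **jointly across the full
transcript × period p-value vector**, and each transcript is assigned its
most significant period (minimum adjusted p; exact ties broken toward the
longer period, so a daily label is favoured only on measure-zero ties).
Transcripts assigned 20 or 24 h are classed *daily*, 12 or 16 h
*ultradian*. Stations are analysed separately, each with its own joint
adjustment; there is no cross-station multiplicity correction.

### Power on a 4 h grid

Two structural limits are worth knowing. First, the 12 h fold has only
three cycle positions, and when a transcript peaks near a sampling time the
two off-peak groups have equal expected values; the strongest attainable
evidence is then "the 9 peak samples all exceed the other 12", i.e. a raw
p of $6/\binom{21}{9} \approx 2\times10^{-5}$ after the pattern
correction. Second, the pattern Bonferroni costs a factor $m(m-1)$ on
every transcript. Together these mean that moderate-amplitude rhythms
(amplitude around 2, multiplicative noise around 10%) are detected at a
joint BH cutoff of 0.001 at roughly 80% (24 h periods) and 50–70% (12 h
periods) per station rather than near-perfectly; comparisons of detected
counts between conditions inherit that bias. Heatmap-level conclusions are
unaffected, but planted-truth recovery experiments should expect those
rates.

## Phase, amplitude, environment coincidence

Phase is the argmax of the per-cycle-position replicate **medians** (ties
to the earliest position), reported both as position within the cycle and
as the local clock hour of the corresponding sampling time. With 3–6
positions per cycle and non-sinusoidal waveforms this ordinal estimate is
the honest resolution of the design; a cosinor fit would interpolate
between positions but assumes sinusoidality, and is deliberately not the
default. Noiseless recovery is exact at sampled phases and correct to the
nearest grid point elsewhere (property-tested by exhaustive sweep).

Amplitude is $(\max - \min)/\min$ of the median profile after adding a
pseudocount (default 0): an amplitude of 0.5 means the peak–trough
difference equals half the trough level. Profiles whose shifted minimum is
not positive raise a hard error rather than silently producing infinities —
zero-containing rows require an explicit pseudocount choice. Amplitudes are
binned as [0, 0.5), [0.5, 1.5), [1.5, 5], (5, ∞). Both phase and amplitude
are invariant under per-transcript median normalization (the normalization
used for display heatmaps), which the tests assert.

Coincidence labels compare a transcript's peak clock hour with the nearest
environmental extremum (solar culmination or tide turn) on the 24 h clock
circle, within a tolerance of 2 h — half the sampling interval — by
default. On an exact distance tie between a solar and a tidal event, tidal
events take precedence for ultradian transcripts and solar events for
daily ones, matching how the two period ranges are interpreted.

## Environmental cycle models

Solar elevation uses the standard low-precision fractional-year formulas
(declination and equation of time as short Fourier series, then the hour
angle), accurate to a few tenths of a degree over 2000–2030 — enough for
diel shape, culmination times and the above/below-horizon status that the
analysis needs. No atmospheric refraction is applied. When a configuration
supplies only month and day, the year defaults to 2018, the field season
the default station coordinates refer to; both are configurable.
`midnight_sun()` scans the civil day at ≤10-minute resolution and reports
whether the minimum elevation stays positive.

The tide model is a pure harmonic sum
$h(t) = z_0 + \sum_i A_i \cos(2\pi t/T_i - \phi_i)$ with a single default
constituent, the principal lunar semidiurnal M2 ($T = 12.4206$ h, unit
amplitude). It is a timing toy, not a prediction: no gauge harmonics ship
with the package, and users who care about a specific site supply their
own constituents file. Extrema of both series are located as sign changes
of the first difference, plateaus reported at their midpoint, series
endpoints never reported — a deterministic rule that needs no tuning.

## The synthetic-data generator

Planted rhythms follow the raised cosine
$x(t) = b\,(1 + \tfrac{A}{2}(1 + \cos 2\pi (t - \phi)/P))$, chosen so the
noiseless $(\max-\min)/\min$ equals the planted amplitude $A$ exactly
(trough $b$, peak $b(1+A)$). Noise is multiplicative lognormal — the
pipeline consumes normalized expression and the detector only sees ranks —
with a negative-binomial mode available for count-level realism. Phases are
drawn uniformly, clustered (von Mises around a configured clock time, to
emulate phase-locking to solar minimum or high tide), or fixed. The
default scale is a desk-scale 1,000 transcripts; the study-scale 76,550 is
a configuration change, not a code change. A single master seed drives one
generation stream in a fixed order, so a run is reproducible end to end.

The generator emulates the statistical structure the detector assumes —
independent cross-sectional samples (each time × replicate is a distinct
pool of animals), multiplicative noise, rhythmic fractions by period — and
deliberately does **not** emulate read-level sampling depth, transcript
length or GC biases, library-composition effects, or temporal
autocorrelation within animals. Green tests on synthetic data therefore
validate the statistics and bookkeeping, not upstream quantification.

The two-station scenario plants the seven-category cross-station
architecture (exclusive to either station, shared with the same period
range, shared with a range switch in either direction, arrhythmic) with
exact configured counts, defaulting to a daily-dominated station A and an
ultradian-enriched station B with amplitude 2 and noise 0.1 — the regime
the per-station detector is calibrated in.

## Numerical and design choices

* Cycle positions are rounded to one minute before folding; candidate
  periods must leave at least three distinct positions or the fold errors.
* Degenerate nulls (all values tied) give p = 1, so constant rows can
  never be called rhythmic.
* The exact-enumeration path additionally requires at most 2×10^5
  assignments: enumeration cost is the multinomial coefficient, which
  explodes for singleton-heavy folds even at small N.
* BH adjustment is the standard step-up with cumulative-minimum
  monotonicity (`stats::p.adjust`), validated on hand-computed examples.
* Ties in ranks use midranks and the half-tie U convention throughout.
* "Both-same" in the comparison requires the same period *range*, not the
  same exact period: a 24 h ↔ 20 h pair is still `both_same_daily`.
* The ORA universe is the set of transcripts tested for rhythmicity, not a
  genome, and term sets are flat (no ontology propagation).
* Whether amplitude should use replicate medians or means, and raw or
  normalized expression, is not settled by the upstream literature; this
  package uses medians of the values the detector saw, and documents the
  choice rather than hiding it.
* Test-suite problem sizes are desk-scale by design: 1,000 transcripts per
  calibration run, 72 h of simulated tide at 1-minute resolution,
  enumeration oracles at N ≤ 10. They exercise every code path; larger
  runs change runtime, not behaviour.

## Known limitations

The detector assumes independent samples; longitudinal autocorrelation
(repeated measures of the same animals) would inflate significance.
Periods not commensurate with the sampling grid (including true 12.42 h
circatidal periods, tested here as 12 h) are out of scope, as are cosinor
fits, GO-DAG-aware enrichment, and real tidal prediction. The pattern
Bonferroni trades power for an exact, simple null — see "Power on a 4 h
grid" above for what that costs and where it bites.
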