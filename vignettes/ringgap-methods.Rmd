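---
title: "Models and methods behind ringgap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ringgap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringgap)
library(dplyr)
```

## The two assays

`ringgap` models and analyses a gap-crossing behavioural screen in
*Drosophila melanogaster*. Walking flies cross gaps of up to about 1.7 body
lengths (a body is ~2.6 mm); whether a fly initiates a climb is decided
visually, from the parallax motion of the distal gap edge during approach.
Two experimental formats are covered.

**Ring-gap assay.** Fifteen flies start in the recess of a Ø 138 mm disk
carrying five concentric water-filled gaps ("grooves") of widths 2.0, 2.5,
3.0, 3.5, 4.0 mm, and explore for 10 minutes under a low glass ceiling; an
overhead camera logs positions once per second. A fly that attempts a gap
beyond its ability falls and drowns, marking its smallest challenging width;
its frozen position keeps contributing to the cohort's mean distance from
centre. The screen statistics per experiment are the maximum over time of
the cohort's mean distance from centre (relative units of the disk radius),
the time of its first attainment, the percentage of drowned flies with their
groove indices, and the walking activity.

**Single-gap (catwalk) assay.** One fly at a time walks a
30 x 10 x 4 mm catwalk with a single rectangular gap (2.0 to 6.0 mm wide,
5 mm deep) and is scored over ten voluntary approaches: attempted
(leg-over-head foreleg strokes), fell, or crossed. Per-fly fractions out of
ten approaches are summarised as box statistics and compared between lines
by two-sided Wilcoxon rank-sum tests per gap width.

## The decision model

The simulator's core is a two-stage decision at every gap encounter.

**Perceived width.** Manipulations of the parallax percept are summarised by
a multiplicative *gain* $g$ and a visibility *contrast* factor $c$:

$$w_\mathrm{eff} = \frac{w}{g \cdot c(\mathrm{visibility})}$$

with $g = 1$ for controls, $g > 1$ for enhanced parallax (as under silencing
of the inhibitory C2/C3 medulla-to-lamina feedback neurons: the distal edge
appears closer, gaps appear narrower), and $g < 1$ for attenuated parallax
(artificial depolarization of the same cells). Visibility scales the same
signal: a dark distal wall has $c = 1$, clear Perspex $c_\mathrm{clear} =
0.2$ (weak contrast: the signal is weak regardless of $g$, so gain
manipulations saturate and have no behavioural effect), and black-and-white
stripes $c_\mathrm{striped} = 1.5$ (enhanced contrast). The contrast values
are free parameters chosen so that a 4 mm clear gap maps beyond the attempt
curve's last knot for all gains in $[0.6, 1.6]$ (gain insensitivity), while
stripes leave the same gains on the sloping part of the curve.

**Attempt.** The probability of initiating a climb is a piecewise-linear,
non-increasing function of $w_\mathrm{eff}$, clamped to the knot range. The
control curve uses two knots: (2.5 mm, 0.80), which is the anchored control
attempt rate at 2.5 mm, and (6.0 mm, 0.15), a free parameter consistent with
an approximately linear decline of attempts with width. A gap smaller than
2.5 mm is treated as equally inviting as 2.5 mm (the clamp); the model does
not represent the drop of *climbing* behaviour at sub-body-size gaps that
are crossed by a simple stride. One consequence worth stating explicitly:
because the curve is clamped below its first knot, the attempt difference
between gains 0.6 and 1.6 at a 4 mm gap is widest at $c = 1$ and smaller
under stripes (both gains slide toward the plateau); stripes do, however,
separate the gains far more than the clear wall does, and raise attempts
above the dark condition at control gain.

**Outcome.** Whether an *attempt* succeeds depends only on the *true* width
-- perception manipulations change how often flies try, not how well they
climb. The profile stores a per-approach success curve $s(w)$ at $g = 1$
(control anchors: 0.70 at 2.5 mm and $18/440$ at 4.0 mm, the printed
aggregate counts; the super-climber profile uses $40/300$ at 4.0 mm), and a
constant per-attempt fall probability $f$. Internally the simulator converts
$s$ once into a per-attempt crossing probability conditional on not
falling,

$$q(w) = \min\!\left(1, \frac{s(w)}{a(w)\,(1 - f)}\right),$$

where $a(w)$ is the profile's own attempt curve evaluated at the true width
with $g = c = 1$. At control gain the realized per-approach success then
equals $s(w)$ exactly, while under any gain manipulation the per-attempt
success $(1-f)\,q(w)$ is unchanged -- which is the observed dissociation the
model is built to reproduce. For strongly clumsy profiles ($f$ large) the
clamp at 1 binds near 2.5 mm, so their realized success falls below the
control curve; that *is* the phenotype.

## The locomotor model

Between encounters a fly performs a correlated random walk at 1 Hz: with
probability $p_0 / (1 + t/\tau)$ it draws a fresh uniform heading, otherwise
it keeps its heading, then advances by a truncated-normal speed
($\mu$ = 8 mm/s, $\sigma$ = 3 mm/s for most profiles). The hyperbolic decay
of the turn rate ($p_0 = 0.5$, $\tau = 60$ s) makes paths straighten over
time, so the cohort disperses outward, the qualitative behaviour of randomly
searching flies. The disk rim reflects; once a fly has left the centre
recess it cannot re-enter it.

A step that would carry a fly across a groove edge stops at the edge and
triggers the decision model. Declines and retreats reverse the heading away
from the water and start an *approach refractory* (default 60 s) during
which groove edges act as plain walls. The refractory is the package's
answer to an open modelling question -- how often a fly re-approaches a gap
it has already declined -- and is the main control over the number of
decisions per 10-minute recording; 60 s yields on the order of five to ten
resolved approaches per fly, and with the control fall probability of
$f = 0.01$ per attempt (a free default; falls of healthy flies at
surmountable widths are rare events) a control cohort loses a realistic one
to two of its fifteen flies. Successful crossings are timed teleports: the
fly waits at the proximal edge for `crossing_duration` (3 s) and reappears
at the distal edge -- only 1 Hz positions are analysed downstream, so
climbing kinematics are deliberately not modelled. A fall freezes the fly at
the groove midline at the crossing azimuth, and its `status` flips to
`dead` for the rest of the recording.

Determinism: every fly derives its RNG substream from the experiment seed by
a fixed offset, so an identical configuration reproduces byte-identical
output, and adding flies to a cohort never changes the trajectories of the
existing ones.

## Arena geometry defaults

The groove *widths* are fixed by the assay (2.0--4.0 mm in 0.5 mm steps) but
their radial placement is not printed anywhere, so the default geometry
spaces the recess (radius 10 mm), the five grooves and the rim with six
equal land rings. With a 69 mm disk radius that makes each land
$\,(69 - 10 - 15)/6 \approx 7.33$ mm wide; the outermost groove's outer edge
lands at 61.7 mm, leaving one full land ring before the rim. All radii are
configurable through `arena_geometry()`.

## Screen classification

Per line, replicate experiments are collapsed to medians of the two screen
axes (`summarize_lines()`). Boundaries are empirical population percentiles
with linear interpolation of order statistics (`quantile(type = 7)`): the
10th and 90th percentile of the per-line median maximum mean distance, and
the 90th percentile of the per-line median death percentage. The decision
ladder in `classify_lines()` uses *inclusive* comparisons -- a line exactly
at a boundary is flagged -- because the death statistic is discrete
(multiples of 100/15), and with ties the flagged group can only be at least
as large as in the tie-free case. The six categories partition the plane:
under-performing + high-death = very clumsy, under-performing = overcautious,
over-performing + high-death = overeager, over-performing = super climber,
high-death alone = clumsy, everything else = normal. There is no low-death
category. Ties in the time of the maximum mean distance are broken by first
attainment.

## Rank-sum testing

`rank_sum_test()` implements the two-sided Wilcoxon rank-sum test with
midranks. For combined sample sizes up to 20 the null distribution of the
rank-sum statistic is enumerated over all $\binom{n}{n_a}$ label
assignments and the p-value counts assignments at least as extreme (in
distance from the null mean) as observed; this is exact under ties as well.
Beyond 20 a normal approximation with tie correction and a 0.5 continuity
correction is used. Both values are always computed and reported, since the
assay's group sizes (ten or more flies per arm) straddle the regimes. On
tie-free 10 + 10 samples the two paths agree to within 0.01 on random
fixtures. Stars follow the strict thresholds `***` p < 0.001, `**`
p < 0.01, `*` p < 0.05; per-width comparisons are uncorrected by default
(matching the assay's figure convention), with an optional Holm adjustment.

## Synthetic camera and tracking

`render_frame()` draws the backlit disk as a bright field (intensity 1.0)
with darker groove annuli (0.75), a dark exterior and one dark elliptical
blob of body length 2.6 mm per fly; overlapping flies merge. The default
pixel pitch is 0.2 mm/px (0.4 mm/px in the package's own demonstrations to
keep them light). `detect_blobs()` thresholds with Otsu's method computed on
the *land* pixels of the disk interior -- excluding the groove annuli from
the threshold estimate keeps the split between fly and bright land, so
drowned flies lying inside a groove remain detectable as isolated dark
components -- labels connected components (EBImage) and filters them by an
area band (0.8--20 mm²) that rejects any groove-sized component. Linking is
greedy nearest-neighbour with a 15 mm gate (the largest plausible 1 s
displacement); a track with no detection coasts in place and is flagged, and
a surplus detection re-captures the nearest coasting track. Identity swaps
between nearby flies are possible and tolerated: the screen statistic is a
mean over flies and is insensitive to relabelling, which is why the
round-trip error on the maximum mean distance stays within 0.02 relative
units.

## What the generator does and does not emulate

The generator reproduces the statistical structure the analysis relies on:
width-dependent attempt decisions, gain/contrast modulation of those
decisions, outcome probabilities tied to true width, drowning that freezes a
fly in a groove, 1 Hz sampling, ten-approach catwalk sessions. It does not
emulate climbing kinematics, leg placement or body pitch, jumping or
flight, sub-second motion, identity-swap artefacts of real multi-animal
video, temperature as a continuous variable (only discrete profile
variants), or social interactions between the fifteen flies. Passing tests
therefore validate the analysis pipeline and the internal consistency of
the decision model -- not any claim about real fly kinematics.

## Problem sizes and numerical choices

The package's tests and demonstrations use deliberately compact sizes: ring
cohorts of 15 flies for 120--300 s (the full 600 s runs in ~0.1 s, and
durations are parameters everywhere), catwalk sessions of 50--200 flies,
round-trip tracking demonstrations at 150 s and 0.4 mm/px over 20 seeds, and
the binomial-median recovery checks at 75 flies over 60 seeds per rate.
Floating-point ties in the exact test are compared with a 1e-9 slack;
quantiles use type 7 throughout; track coordinates are written at micron
precision so that write--read--write cycles are byte-stable; death
detection uses an immobility tolerance of 0.5 mm held to the end of the
recording.

## Known limitations

* The attempt and success curves are anchored at the few printed control
  statistics; all other knots are free defaults, so absolute simulated
  rates at unanchored widths are conventions, not predictions.
* The clamped two-knot attempt curve cannot produce a larger gain contrast
  under stripes than under a dark wall at 4 mm (see the decision-model
  section); the model captures the direction and saturation of the
  contrast manipulations, not their relative effect sizes.
* Ring-assay death rates depend strongly on the approach-refractory
  parameter, which has no measured counterpart; comparisons across profiles
  are meaningful, absolute death percentages are calibration.
* The tracker is intentionally simple (greedy linking, no occlusion
  reasoning) and is validated only for cohort-level statistics.
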