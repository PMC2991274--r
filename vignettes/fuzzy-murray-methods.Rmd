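---
title: "Methods: a weighted Sugeno FIS for lung injury severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a weighted Sugeno FIS for lung injury severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzylis)
```

## The problem

The Murray lung injury score averages four component scores, each obtained
by banding a physiological variable with hard cut-offs. Clinicians,
however, categorize these variables with fuzzy frontiers and do not weight
them equally when diagnosing. This package models the collective judgement
of a physician panel as a weighted Sugeno fuzzy inference system (FIS)
built from two questionnaires, and measures its agreement with the crisp
Murray score on a factorial grid of hypothetical patients.

## The two questionnaires and their encoding

**Questionnaire 1 (category frontiers).** Each variable's domain is split
into equal segments — PaO2/FiO2 into 9 segments of 50 over [0, 450] mmHg
ratio, compliance into 10 segments of 10 over [0, 100] ml/cmH2O, PEEP into
10 segments of 2 over [0, 20] cmH2O — and each physician assigns every
segment to one of three contiguous categories with no gaps or overlaps. A
response is therefore two cut indices `1 <= cut1 < cut2 <= n_segments - 1`,
which guarantees all three categories are non-empty.

**Questionnaire 2 (severity rules).** Each antecedent line combines one
category per continuous variable with one of five chest-film levels; each
physician ticks exactly one severity level 0–3 per line. The full line set
has 3 × 3 × 3 × 5 = 135 combinations. The original study used a 107-line
"probable" subset it did not enumerate; since that subset is unrecoverable,
the package defaults to all 135 lines and accepts any filtered subset as
configuration.

## From votes to membership functions

At each segment midpoint, the *vote density* of a category is the fraction
of the panel assigning that segment to the category. Densities are attached
to segment midpoints — the natural representative of a segment — and, by
construction, the three category densities sum to 1 at every midpoint.

Each density is interpolated by a parametric membership function chosen
from nine families (Z-shape, S-shape, sigmoid, difference of sigmoids,
product of sigmoids, generalized bell, Gaussian, two-sided Gaussian,
trapezoid): every offered family is fitted by least squares and the family
with the smallest residual sum of squares wins, ties going to the earlier
family in the offered order. The original analysis drew on a toolbox
repertoire of which eight unnamed curve types were used; fixing this
nine-family list and selecting per category by SSE is the package's own
reconstruction of that choice.

Fitting is Levenberg–Marquardt (`minpack.lm::nls.lm`, at most 200
iterations) with box bounds in a *raw* parameter space whose transform
enforces each family's ordering and positivity constraints (e.g. `zmf` is
fitted as `(a, width)` with `b = a + width`, `width > 0`). Initial values
are data-driven and deterministic: the abscissa where the density crosses
0.5 (interpolated; domain-end fallbacks when no crossing exists) seeds the
frontier parameters, and monotone families additionally try a small ladder
of widths (1×, 2×, 4× the grid step) to avoid local minima on step-like
densities. Refitting any family to its own sampled curve recovers SSE
below 1e-6, which the test suite asserts for all nine families.

Evaluation clamps inputs marginally outside the domain (relative tolerance
1e-9) to the nearest endpoint and errors on grossly out-of-domain values;
outputs are clamped into [0, 1], which matters only for the difference-of-
sigmoids family, whose raw form can stray slightly outside the unit
interval.

**Chest film.** Film inspection is quantized to 0–4 consolidated
quadrants, but its fuzzy reading uses five generalized bells centered at
0–4 over [0, 4]. Defaults are width `a = 0.5` and slope exponent `b = 3`,
chosen so that the midpoint between adjacent centers (e.g. 1.5 quadrants)
has membership exactly 0.5 in both neighbours — the qualitative property
the construction must honour; the original publication gives no numeric
bell parameters.

## The weighted rule base and inference

Every (line, level) cell with at least one tick becomes one rule with crisp
consequent `k` and weight `ticks / panel size`; zero-tick cells produce no
rule, so per-line weights sum to exactly 1 and a P-physician panel yields
between 1 and 4 rules per line. A rule's firing strength at a quadruplet is
the product of its four membership degrees (product T-norm). The
probabilistic OR `probor(a, b) = a + b - ab` is implemented and tested as
the declared disjunction operator, although the shipped rule format needs
only conjunctions; across rules, aggregation and defuzzification reduce to
resolving the multiple crisp outputs in one step, as is standard for
Sugeno-type systems.

The continuous degree of severity is the weighted mean
`sum(f_i w_i k_i) / sum(f_i w_i)`. Normalizing by the total firing mass
keeps the output a convex combination of the fired consequents (hence in
[0, 3]) and makes it invariant to rescaling all weights by a common
constant; both properties are asserted in the tests. The severity level is
the nearest integer, with ties at .5 rounded up — the source material says
only "nearest", so the upward tie-break (toward more severity) is a
documented package choice. A quadruplet fired by no rule raises a
"no rule coverage" error carrying the offending values rather than
returning a silent default.

## The crisp reference and the evaluation grid

Band boundaries for the component scores follow the original Murray
publication (PaO2/FiO2 300/225/175/100; compliance 80/60/40/20; PEEP
6/9/12/15) and live in an editable table, since the survey study shows
them only graphically. Severity levels come from the score intervals
[0, 0.1], (0.1, 1.5], (1.5, 2.5], (2.5, Inf); the 1.5 split of the
original mild-to-moderate band separates injury without ALI from injury
with ALI.

The evaluation grid takes, per continuous variable, each band's center
(`(lo + hi)/2` of the printed discrete bounds, so the 100–174 PaO2/FiO2
band has center 137) plus a flanking pair at `frontier ± delta` around
each interior frontier (`delta` = 1 for PaO2/FiO2 and compliance, 0.5 for
PEEP — the source says only "two close values"). That gives 13 PEEP values
exactly; PaO2/FiO2 and compliance are padded to 18 values by deterministic
greedy gap bisection (repeatedly inserting the midpoint of the widest
remaining gap, domain endpoints included, ties leftmost). The exact
18-value construction of the original grid is not recoverable — its worked
example row contains 250, which is neither a default center nor a flank —
so the lists are fully configurable and the defaults are documented as a
reconstruction. The full product is 18 × 18 × 13 × 5 = 21,060 quadruplets.

Two exclusion predicates ship as defaults, the two printed as examples in
the source: PaO2/FiO2 = 450 with film = 4, and PaO2/FiO2 ≤ 137 with film
0 or 1. Because the original exclusion list was longer but unstated, the
default retained count (18,252) is close to, but not equal to, the
original 18,013; the package promises only the 17,000–21,060 bracket.

## The synthetic panel: what it emulates and what it does not

The raw survey responses were never published, so the package generates
them. Each simulated physician:

1. places each category frontier at a nominal mean plus independent
   Gaussian jitter, snapped to the nearest segment boundary (`round()` of
   frontier/width; R's half-to-even applies at exact midpoints, e.g. the
   PEEP frontier 15 cmH2O snaps to boundary 16) and clamped so no category
   collapses — clamping rather than rejection keeps the panel size fixed;
2. grades each antecedent line by instantiating it as its representative
   quadruplet (category-run midpoints under the *nominal* frontiers, film
   verbatim), taking a weighted mean of the Murray component scores of
   those representatives, adding a bias and personal Gaussian noise, and
   ticking the severity level of the resulting score (clamped at 0).

Nominal frontiers default to the boundaries between Murray component-score
bands 0|1 and 3|4 (PaO2/FiO2 100/300, compliance 20/80, PEEP 6/15), which
aligns the faithful preset with the crisp bands. The `"faithful"` preset
(equal weights, zero jitter, zero noise, zero bias) makes every physician
tick exactly the crisp Murray level of the representative quadruplet — the
oracle the generator's tests are built on. The `"overweight"` preset
doubles the PaO2/FiO2 and chest-film weights (2/1/1/2) and adds moderate
jitter (25, 5 and 1 domain units; roughly half a segment) and score noise
(SD 0.25, about a quarter of a severity level) — values chosen once as a
plausible degree of inter-physician disagreement for an ICU panel, not
estimated from data.

The generator deliberately omits inter-physician correlation, systematic
subgroup behavior, and any learning from real responses. Consequently,
passing tests demonstrate that the pipeline's machinery is correct and
that the qualitative phenomena (high faithful agreement; mean
overestimation under gas-exchange/film overweighting) emerge from the
stated mechanisms — they do not validate the synthetic panel as a model of
any real physician group, and survey-dependent magnitudes (membership
shapes, rule counts, kappa values of simulated runs) are not comparable to
the published ones, which derive from the unpublished real responses.

## Agreement statistics

The S−M difference vector uses the population standard deviation and the
normal-approximation CI `mean ± 1.96 sd / sqrt(n)`, which reproduces the
published interval from the published table. The mean over disagreements
restricts to `d != 0` and is reported to three decimals; recomputing it
from the published table gives 9062/9897 = 0.9156, which rounds to 0.916
rather than the printed 0.915, so it is excluded from exact assertions.
Cohen's kappa uses the standard asymptotic delta-method standard error
(Fleiss–Cohen–Everitt), cross-checked in the tests against an independent
implementation on a frozen table; the published overall SE (0.0066) is not
reproduced by this standard formula (which gives 0.0051 on the same table)
and only the kappa point estimates are asserted exactly. The band-wise
discrepancy analysis reports, per Murray severity, variable and band, the
proportion of cases the survey pushes one level up; empty strata yield
`NA` rather than errors. Two-proportion comparisons use the pooled
two-sided z-test; a degenerate pooled proportion (0 or 1) is reported as
`z = 0, p = 1` with a flag.

## Problem sizes and runtime choices

All shipped analyses run on one CPU in seconds to a couple of minutes: the
full 21,060-row grid is evaluated vectorized (membership degrees for all
rows, then an n × rules firing matrix), membership fitting is nine small
least-squares problems per survey, and the property suites use 200
simulated panels for the density/membership invariants and 100 random
tables for the statistic oracles. These sizes were chosen to exercise the
full study conditions — the complete default grid, the 12-physician panel
— without artificial down-scaling.

## Known limitations

- The 107-line "probable" antecedent subset and the complete exclusion
  list of the original grid are unrecoverable; defaults are documented
  reconstructions, and exact reproduction of the 18,013 retained rows is
  not attempted.
- Membership estimation is parametric only; no spline/kernel alternative.
- Weighted kappa and resampling-based kappa intervals are out of scope.
- The neuro-fuzzy inversion of the Murray equation reported alongside the
  original survey analysis (symmetric memberships learned from Murray
  outputs) is not implemented; its training procedure was unspecified.
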