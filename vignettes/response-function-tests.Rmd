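---
title: "Response-function randomization tests for single-case designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-function randomization tests for single-case designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scedrf)
```

## The model

In a randomized single-case experiment a single case is measured repeatedly
and the assignment of measurement occasions to conditions (for instance, the
occasion on which the intervention starts) is chosen at random from a
predefined set.  Under the null hypothesis of no intervention effect, every
admissible "data division" -- every way the fixed measurement sequence could
have been split into conditions -- was equally likely to be the realized
one.  A randomization test therefore computes the test statistic for the
realized division and for every other admissible division (the
*pseudovalues*); the one-sided p-value is the proportion of divisions whose
statistic is as large as or larger than the observed one.  No sampling
distribution and no parametric error model are involved: the inference is
exact by construction, conditional on the randomization actually performed.

The package's contribution is the *test statistic*.  Rather than committing
to a mean difference (sensitive only to immediate, abrupt, sustained changes
in level), the expected effect is encoded as a **response function**: a
vector of constants $f = (f_1, \dots, f_n)$, one per measurement occasion,
describing the predicted response.  The statistic is Pearson's
product-moment correlation $r(y, f)$ between the observed scores and the
response function, computed over the included occasions.  When $f$ is binary
this is the point-biserial correlation; with richer codings the same single
statistic is sensitive to delayed, gradual, temporary and nonlinear effects.
Crucially, the response function is *rebuilt for every candidate division*,
because the number of baseline zeros and the intervention-phase coding
depend on the candidate phase lengths.

## Effect patterns and their codings

`effect_spec()` describes the expected effect along four dimensions
(onset × progression × duration, plus the aim of the intervention), which
combine into eight prototypes.  For a division with $n_A$ baseline and
$n_B$ intervention occasions, `build_rf()` codes the baseline as $n_A$
zeros and the intervention phase as:

* **abrupt**: ones for the duration of the effect, zeros after it wears
  off; a permanent effect is simply the maximal duration;
* **gradual**: a ramp $1, 2, \dots$; a temporary effect rises to the
  duration $d$ and then ends according to the `offset`: a unit-per-occasion
  decay $d-1, d-2, \dots, 0$ (the default, mirroring how the effect
  appeared), an abrupt drop to zero, or a hold at $d$ (an upper asymptote:
  "no further improvement" rather than "effect lost");
* **delayed**: `latency` leading zeros before either coding starts;
* optionally an overall linear trend $1, \dots, n$ added element-wise, for
  settings where spontaneous improvement is plausible;
* or an arbitrary user-supplied vector (e.g. a quadratic ramp read with
  `read_user_rf()`), truncated to the candidate phase length.

```{r}
as.double(build_rf(effect_spec(onset = "delayed", latency = 2,
                               progression = "gradual",
                               duration = "temporary", effect_duration = 3),
                   n_A = 5, n_B = 8))
```

Two conventions deserve a note.  The decay rate of the gradual offset is
fixed at one unit per occasion; the published layouts for durations 3-5
with an eight-occasion intervention phase all follow this rule, and a
configurable rate would add a parameter with no empirical anchor.  And the
direction of a *desired decrease* is handled by negating the scores
(`orient_scores()`), not the response function, so the codings above stay
directly comparable with the published tables and favorable results always
produce positive statistics.

Masking (`apply_mask()`) excludes occasions from the statistic without
shortening the series -- e.g. `{NA, 0, 0, 0, 0, 0, 1, 2, 3, NA}` focuses an
immediate slope comparison on four occasions per phase.  Missing
*measurements* are deliberately rejected by the data container: exclusion
is a property of the comparison, encoded in the mask, not of the data file.

## Randomization schemes

Four enumerable assignment spaces are supported; `enumerate_divisions()`
lists them, `n_divisions()` counts them in closed form, and the two always
agree (this is property-tested over a randomized sweep of schemes).

| design | divisions | count |
|---|---|---|
| `ab_design(n, min_a, max_a, min_b)` | intervention start occasions | `min(max_a, n - min_b) - min_a + 1` |
| `mb_design("WW", starts, n)` | tier-order permutations over fixed staggered starts | $t!$ |
| `mb_design("KL", starts, n)` | tier orders × per-position start choices | $t!\prod_i s_i$ |
| `abab_design(n, I, k)` | ordered phase-change tuples, every phase ≥ k | $\binom{n - Ik + I - 1}{I - 1}$ |
| `atd_design(b)` | block-randomized condition sequences | $2^b$ |

The minimum attainable p-value is $1/m$; a design should allow $m \ge 20$
for significance at $\alpha = .05$ to be reachable at all.  For
multiple-baseline designs the per-division statistic is the unweighted mean
of the per-tier correlations -- the coding is simply repeated per A-B
comparison, and the mean keeps tiers of unequal length on the same scale.
For reversal (ABAB) designs the intervention coding is repeated inside each
B phase of the candidate division.  Koehler-Levin candidate start sets may
overlap across positions; this is permitted with a warning, and the
enumeration then keeps one division per (order, choice) combination so that
every randomization outcome stays equally weighted.

## Numerical conventions

* **Ties.** The observed value counts itself, and ties count as extreme
  (the rank is the number of pseudovalues $\ge r_{obs}$).  This is the
  conservative reading of "as extreme as or more extreme" and keeps the
  test valid: the p-value support is exactly $\{1/m, \dots, 1\}$.
* **Degenerate divisions.** A candidate division can make the response
  function constant -- most commonly when the scanned latency is at least
  the candidate intervention length.  Such divisions are *kept* with the
  statistic conventioned to 0 and flagged (dropping them would change $m$
  and destroy exactness).  `build_rf()` signals these cases with a classed
  condition so that programmatic callers can distinguish them from errors.
* **Two-sided option.** The default test is one-sided in the favorable
  direction, matching directional aims; a two-sided variant ranks
  $|r|$ instead.

## Exploratory scans and multiplicity

The exact latency of a delayed effect, or the exact duration of a temporary
one, is often unknown a priori.  `scan_latencies()` and `scan_durations()`
re-run the test across operational definitions (latencies $1..L_{max}$;
permanent plus durations $1..d_{max}$) over the *same* division set, so the
per-scenario ranks are directly comparable.  Raw p-values are reported by
default -- in a purely exploratory reading they are descriptive measures --
and Bonferroni or Holm adjustment (`adjust_pvalues()`, via
`stats::p.adjust`) is available whenever the scan is used for confirmatory
statements.  The scan reports should be read together with the time-series
plot: the framework assumes the chosen response function resembles the
actual data pattern, and a poor match correctly yields small correlations
and large p-values.

## A caveat on the mean-difference equivalence

For a *fixed* division, the point-biserial correlation is a monotone
function of the mean difference, so the two statistics give the same
permutation p-value when group sizes are held fixed.  Across the divisions
of a start-point scheme, however, the phase sizes vary:
$r = \mathrm{md}\cdot\sqrt{n_A n_B}/(n\,s_y)$, and the varying factor
$\sqrt{n_A n_B}$ can reorder divisions, so the correlation test and a raw
mean-difference test are *not* interchangeable there (the correlation
weights balanced splits up).  In block-randomized alternation designs every
division has the same group sizes and the equivalence is exact; the test
suite verifies it there by full enumeration.

## The synthetic-data generator

`generate_series()` draws
$y_t = \mu + \beta t + \delta f_t + \varepsilon_t$, where $f_t$ is the
ground-truth effect shape normalized to unit peak (so $\delta$ is the
effect size in score units for every prototype) and $\varepsilon_t$ is
Gaussian noise, i.i.d. by default or stationary AR(1) with parameter $\phi$
(marginal SD kept at $\sigma$), with optional rounding/flooring for
count-like outcomes.  Defaults ($\mu = 0$, $\beta = 0$, $\delta = 1$,
$\sigma = 1$, $\phi = 0$) give a unit-effect, unit-noise series --
a signal-to-noise ratio in the range typical of behavioral SCED data.  The
generator emulates the *shape* catalogue of the prototypical patterns and
a simple error process; it does not emulate bounded scales, floor/ceiling
effects, or response-guided phase changes, so passing tests demonstrate
correctness of the machinery and calibration under this model, not
robustness on any particular real dataset.

`simulate_rejection_rate()` is the validity/power harness: each replicate
draws the actual division uniformly (as the design prescribes), generates
data with the true effect at that division, and runs the test.  Under the
null the rejection rate of an exact test equals
$\lfloor \alpha m\rfloor/m$ -- in particular, exactly 0 when
$\alpha < 1/m$, which is why small randomization spaces cannot reach
conventional significance.

## Problem sizes used in the test suite

The shipped tests enumerate schemes up to a few thousand divisions
(e.g. $7! = 5040$ tier orders), verify pseudovalues against an independent
loop-written brute-force oracle for series of up to 10 occasions across all
eight prototypes, and run the null-validity check with 2000 Monte-Carlo
replicates on a ten-division start-point scheme -- sizes chosen so the
whole suite documents the method's properties while remaining quick enough
to run routinely.

## Limitations

* Only equiprobable randomization schemes are covered; restricted or
  response-guided assignment rules would need their own enumeration.
* Changing-criterion designs are out of scope: their established
  criterion-distance procedures already fit that design's logic.
* The package reports exact p-values and ranks, not randomization-based
  confidence intervals (test inversion is not implemented).
* Statistical power with few admissible divisions is intrinsically
  limited; the harness makes this easy to quantify but cannot remedy it.
* Choosing the response function after inspecting the data invites
  confirmation bias.  The scans are exploration tools; any data-driven
  choice should be reported as such, and the adjustment options used when
  scan p-values are treated as probabilistic statements.
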