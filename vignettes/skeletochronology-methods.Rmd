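---
title: "Methods: back-calculation, LAG chronology and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: back-calculation, LAG chronology and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelchron)
```

## The back-calculation model

Sea turtle humeri retain one line of arrested growth (LAG) per year in
cortical bone. The diameter of a LAG records the bone's size when growth
paused, and the body proportional hypothesis (BPH) maps bone size to body
size: an individual's straightline carapace length (SCL) deviates from the
mean allometric bone–body curve by a constant proportional factor
throughout life. Anchoring that factor at dead recovery (the only time the
bone and the body are measured together) gives

$$L(D) = \frac{L_{op} + b\,(D - D_{op})^{c}}{L_{op} + b\,(D_{final} - D_{op})^{c}}\;L_{final},$$

implemented in `back_calculate_length()`. The assumptions are (i) annual
LAG deposition, (ii) a stable allometric relation over the sizes analysed,
and (iii) individual proportionality. Three structural consequences are
used as correctness oracles throughout the test suite: $L(D_{final}) =
L_{final}$ exactly, strict monotonicity in $D$, and linear scaling in
$L_{final}$. The analytic inverse (`invert_length_to_diameter()`) is used
by the simulator and to reconstruct diameters from published SCL
estimates; inverse round-trips are required to hold to 1e-9 cm.

Extrapolation beyond the section edge ($D > D_{final}$) is an error, not a
warning: marks outside the measured section have no physical meaning, and
silent extrapolation would corrupt growth rates.

### Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `hatchling_length_cm` ($L_{op}$) | average hatchling SCL | cm | 5.1 |
| `hatchling_diameter_mm` ($D_{op}$) | minimum hatchling humerus diameter | mm | 2.6 |
| `slope` ($b$) | allometric slope | cm mm$^{-c}$ | 3.127 |
| `exponent` ($c$) | proportionality coefficient | – | 0.928 |

The defaults are the published constants fitted for Hawaiian green turtles
over 36.4–97.9 cm SCL. Units are fixed globally — lengths in cm, diameters
in mm; a ~57.7 cm back-calculation corresponds to a mark diameter near
23 mm, which confirms the mm convention for the allometric constants. The
exponent is validated to lie in $(0, 2]$: values far from 1 are
biologically implausible for this allometry, and non-positive values break
monotonicity.

## Calendar-year assignment

Years are assigned counting back from the outermost LAG
(`assign_lag_years()`). Because deposition is seasonal (spring), the year
of the outermost LAG depends on where the stranding date falls in the
annual cycle:

* stranding after the deposition window has closed (`window_end_doy`,
  default day 135 ≈ May 15): the current year's LAG is present;
* stranding within the window: the current year's LAG is present only if
  there is *little to no differentiation* between the final LAG and the
  bone edge, operationalised as edge growth
  $D_{final} - D_{outermost} \le$ `edge_growth_threshold_mm` (default
  0.05 mm — roughly two weeks of juvenile bone growth, configurable
  because the underlying rule is qualitative);
* stranding before the nominal deposition day (`nominal_doy`, default 91 ≈
  April 1, the midpoint of the after-December-to-mid-May window): the
  outermost LAG belongs to the previous year.

This rule is inherently ambiguous for turtles stranding inside the window
a few weeks after their own deposition date: measurable edge growth then
exists even though the current year's LAG is present. No season-based rule
can resolve that case without additional evidence; simulator-based
recovery checks therefore use strandings after the window (day-of-year
182–350), where the rule is determinate, and the limitation is inherited
by any real-world application to spring strandings.

Double LAGs — two closely spaced lines deposited in one annual cycle — are
carried as flagged adjacent pairs and collapsed to the outer line
(`collapse_double_lags()`). Doubles in consecutive years form even-length
flagged runs, read as consecutive pairs; an odd run (an unpaired line) is
a structural error. Automatic detection of doubles from spacing statistics
is deliberately out of scope: flags are expert inputs.

The LAG "deposited closest" to a tagging or injection date is selected by
nominal deposition date (April 1 of the assigned year), minimising
absolute day distance with ties broken toward the later LAG — a fixed,
deterministic choice; the later mark shares more of its growth season with
the target date. When the nearest plausible year precedes the earliest
retained LAG, the tagging-era mark lies inside the resorption core and the
caller is signalled to fall back to the OTC mark diameter
(`otc_fallback_length()`).

## Validation statistics

Paired differences (measured − estimated SCL) are rounded
half-away-from-zero to 0.1 cm — the reporting resolution of field SCL —
*before* any statistic, so the statistics operate on exactly the values a
reader of the comparison table sees. (Base R's `round()` is
round-half-even, hence the explicit half-away rule.)

`wilcoxon_signed_rank()` is the classical paired-sample exact test:

* zero differences are dropped (Wilcoxon's original rule, not Pratt's);
  with three zero pairs among ten this is what yields an effective
  $N = 7$;
* absolute differences are ranked with midranks for ties;
* the statistic is $T = \min(T^+, T^-)$;
* the two-sided p-value is exact for $N \le 25$: the null distribution of
  $T^+$ over all $2^N$ equiprobable sign assignments of the observed
  midrank vector is computed by convolution (mathematically identical to
  enumeration; the test suite verifies it against a literal $2^N$
  brute-force oracle and against `wilcox.test()` in the tie-free case),
  and $p = P(T^+ \le T) + P(T^+ \ge N(N{+}1)/2 - T)$, capped at 1;
* for $N > 25$ a normal approximation with tie-corrected variance and
  continuity correction takes over.

Rank conservation ($T^+ + T^- = N(N{+}1)/2$) is asserted property-style,
and the empirical size of the exact test at $N = 7$ under a symmetric null
is checked over 10,000 Monte-Carlo replicates against the nominal 0.05
level (the exact test is conservative at this $N$: the largest achievable
rejection region below 0.05 has true size 6/128).

The mean absolute difference is reported both over all analysed turtles
and excluding OTC-fallback estimates, whose error path differs (no
LAG-selection step). Standard errors divide the sample SD (n−1) of the
absolute values by $\sqrt{n}$.

## OTC timing inference

An OTC injection leaves a fluorescent line at a known date. Comparing the
SCL back-calculated from the OTC mark (size at injection) with the SCL
back-calculated from the calendar-matched LAG (size at deposition)
classifies each turtle: LAG before, coincident with, or after the
injection (`classify_deposition()`). Coincidence tolerance defaults to
0.1 cm, the SCL reporting resolution — the data cannot distinguish marks
closer than that.

`infer_deposition_window()` aggregates classifications into a seasonal
window. Deposition is an annual cycle, so bounds are positions in the year
(month/day) and order is cyclic, taken relative to an anchor — the
circular mean of the coincident injection days:

* lower bound (exclusive): the latest injection, in season order, whose
  LAG came after it — deposition had not yet happened then. Injections
  near the antipode of the season constrain nothing at the annual scale
  (the following LAG is trivially after them), so only injections
  preceding the upper bound count;
* upper bound (inclusive, "deposited by"): the latest coincident
  injection — coincidence pins deposition to approximately that date.
  With no coincident turtle, the earliest injection whose LAG preceded it
  is used instead.

Turtles whose LAG predates an earlier injection are evidence of
*individual variability* in timing; they are reported per-turtle rather
than allowed to tighten the population window, which is how a
spring-bounded window coexists with one turtle whose LAG predated a late
April injection. A bound with no supporting turtle is `NA`
(undetermined).

## The growth simulator

`simulate_population()` exists to make every pipeline stage testable
against known truth. Growth is modelled on the bone-diameter axis — a
monotone von Bertalanffy trajectory
$D(t) = D_{op} + (D_\infty - D_{op})(1 - e^{-kt})$ — and mapped to SCL
through the BPH allometry with an individual lognormal proportionality
factor. Modelling on the bone axis (rather than simulating SCL and
inverting) guarantees the back-calculation assumptions hold *exactly*, so
recovery tests are sharp: with measurement noise off, the pipeline must
return zero error everywhere, and does (to floating round-off).

What it emulates: individual asymptotic sizes spanning the study's
44–86 cm working range ($L_\infty \sim N(95, 8)$ cm, $k = 0.08$/yr —
typical slow green turtle growth); one LAG per year at a spring
day-of-year ($N(91, 10)$); occasional closely spaced doubles (p = 0.1,
0.05–0.15 mm inside the annual mark — "closely spaced" is not quantified
anywhere, so the gap is configurable); a resorption front advancing
linearly with age (0.35 mm/yr) that deletes early LAGs; OTC injections
recorded exactly (fluorescent marks are read directly under UV); and
Gaussian measurement error on lengths (0.2 cm) and diameters (0.05 mm).
Tagging defaults to coinciding with a LAG deposition event — field seasons
and spring deposition overlap, and this choice makes the noise-free
pipeline exactly unbiased rather than biased by within-year growth between
deposition and capture.

What it does not emulate: within-year modulation of growth rate (growth is
smooth between deposition events), fibropapilloma growth suppression (the
flag is carried but inert), observer-specific measurement bias, and any
biological model of resorption (the linear front is a convenience, not a
claim). Passing recovery tests therefore show the pipeline is correct
*under its own assumptions*; they cannot show the assumptions hold in real
bones.

Noisy diameters are redrawn (up to 200 attempts) until the profile remains
strictly increasing below the section diameter — measurement error on a
physical ring cannot reorder rings. All draws derive from a single integer
seed, with per-turtle substreams so individual turtles reproduce when the
population size changes.

## Problem sizes and numerical choices

The test suite and the acceptance script use: the full ten-turtle bundled
dataset for every published-value check; 40–50 simulated turtles for
noise-free exactness and year recovery; 200 turtles (injections uniform
over the year, deposition day fixed at 91) for deposition-window recovery
— the individual day-of-year spread is switched off there because with it
the inferred lower bound legitimately tracks individual deposition dates
rather than the population mean; 1,000 turtles for the
mean-absolute-difference convergence check against its folded-normal
expectation $2\sigma/\sqrt{\pi}$ (tagging and recovery errors are
independent, so their difference has SD $\sigma\sqrt{2}$), asserted to 8%
relative — three Monte-Carlo standard deviations plus a small allowance
for the 0.1 cm reporting grid and the slightly sub-unit ratio of
LAG-to-final SCL; and 10,000 replicates for the exact test's size.

Other fixed numerical choices: reported SCLs are rounded to 0.1 cm only at
the reporting layer (internal values stay at full precision); date spans
are converted to years by day-count / 365.25; degenerate inputs
(all-zero difference vectors, empty profiles, single-value summaries) are
errors with explicit messages rather than silent `NA`s — except in the
pipeline, where an all-zero difference vector (the noise-free simulator
case) downgrades the Wilcoxon test to a logged note.

## Known limitations

* Spring-stranded individuals with measurable edge growth shortly after
  their own deposition date cannot be year-assigned correctly by any
  season rule (see above).
* The deposition window is bounded by the available injection dates; with
  few turtles it is a coarse interval, and individual variability means
  single animals can deposit outside it.
* The exact Wilcoxon p-value is conditional on the observed midrank
  pattern; with heavy ties at tiny $N$ the test is strongly conservative.
* Back-calculated SCLs inherit any error in $L_{final}$
  proportionally; the validation statistics absorb this into the paired
  comparison rather than modelling it separately.
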