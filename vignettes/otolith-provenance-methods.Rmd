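---
title: "Methods: otolith-isotope provenance analysis and isoscape assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: otolith-isotope provenance analysis and isoscape assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otoprov)
```

## The scientific procedure

`otoprov` infers the nursery origin of small pelagic fish from stable
isotopes micromilled along the otolith growth axis.  The physical basis is
a pair of linear empirical relations: otolith δ¹⁸O (‰ VPDB) decreases with
ambient temperature and increases one-to-one with seawater δ¹⁸O, and
seawater δ¹⁸O (VSMOW) is linear in salinity within a region.  A fish that
spends its first summer in a strongly warming coastal sea therefore writes
a marked ontogenetic *decrease* into its otolith δ¹⁸O; a fish that drifts
poleward into cooling waters writes a flat or increasing profile.  The
package turns that contrast into a classification and a geolocation.

The pipeline stages, and the assumptions each one makes:

**Window rescaling.**  Micromill profiles are heterogeneous (segment
widths 30–160 μm, 5–30 days of growth each), so per-fish values are
rescaled to two fixed ontogenetic windows: larval 0–60 dph and juvenile
106–120 dph, both closed intervals.  A segment contributes to a window iff
the *median* of its estimated age range lies inside the window, and
contributing segments are averaged with weights proportional to the width
of the milling area in μm.  No partial-overlap proration is attempted: the
median rule is a literal, deterministic criterion, and the weighting metric
is spatial because milling width is a spatial property.  A day-span
weighting is available as an option (`weight = "day_span"`); for profiles
whose growth rate is roughly constant across a window the two are nearly
identical, and both are tested.  Fish analysed at a 72 °C carbonate
digestion are first shifted by −0.09 ‰ to the 25 °C scale; the correction
is a one-shot linear shift and the dataset carries a guard flag so it
cannot be applied twice (a silent double shift would be undetectable
afterwards).

**Radius–age mapping.**  Fish without daily-increment readings get segment
ages from a piecewise-linear curve through the mean otolith radius at each
observed age of increment-read fish from the same cohort, defined as the
same capture year, season and region, with season taken as the calendar
quarter (the natural coarsening when "season" is otherwise undefined).
Sampling noise can make mean radius non-monotone in age; a
pool-adjacent-violators step restores monotonicity before interpolation.
Queries outside the anchor hull are clamped with a warning rather than
extrapolated, since growth outside the observed range is unconstrained.
The same curve imputes the otolith radius at 60 dph where increments are
missing; this imputation is shared within a cohort and therefore adds no
discriminative information, which is the conservative choice.

**Threshold classification.**  For each year-class the threshold is the
*maximum* juvenile-window δ¹⁸O over the reference set: age-0 fish captured
inside the coastal system plus age-1 fish from the southernmost region
(West Kyushu), whose profiles show the full seasonal decrease.  Fish at or
below the threshold are locals; strictly above, nonlocals.  The at-or-equal
convention matches the definition of the reference maximum and fixes the
probability-zero boundary case deterministically.  Age-0 fish captured
inside the system without a juvenile measurement are locals by capture
location; age-1 fish without one are left to the discriminant.  The
package extends the discriminant route to age-1 West Kyushu fish lacking a
juvenile value as well — the source procedure enumerates only the two
northern regions and is silent here, and sending such fish through the
same discriminant treats all measurement-incomplete age-1 fish uniformly.

**Linear discriminant.**  A pooled-covariance (homoscedastic Gaussian)
two-class discriminant on larval δ¹⁸O, larval δ¹³C and otolith radius at
60 dph, trained on threshold-labeled fish of all year-classes that have
both the juvenile measurement and the increment reading.  Priors default
to training class frequencies, which is what mainstream implementations do
by default and what the asymmetric per-class accuracies of such analyses
imply; features enter unstandardized because linear discriminants are
affine-equivariant; exact score ties go to `local`, mirroring the
threshold convention.  Accuracy is estimated by leave-one-out
cross-validation with per-fold refitting of both the model and its priors,
reported both overall and per *predicted* class (of the fish predicted
local, how many truly were).

**Group statistics.**  The three groups (locals, nonlocals,
Pacific-offshores) are compared on the larval feature vector with Wilks'
Λ = det(E)/det(E+H) converted to Rao's F: df₁ = p(k−1),
t = sqrt((p²(k−1)²−4)/(p²+(k−1)²−5)) (t = 1 when the denominator is
non-positive), df₂ = t[(n−1)−(p+k)/2] − (p(k−1)−2)/2.  Wilks/Rao is the
fixed statistic choice because its degrees-of-freedom pair is the one
consistent with p = 3 features and k = 3 groups.  At p = 1 the formula
collapses exactly to one-way ANOVA, which the tests exploit as an oracle.
The pre-test battery is the standard one for small-group field data:
Shapiro–Wilk per variable×group, Mardia skewness/kurtosis per group,
pairwise correlations plus variance-inflation factors, Box's M with its
chi-square approximation, and the Brown–Forsythe (median-centered) Levene
variant — robustness defaults chosen where the source is silent.
Kruskal–Wallis uses mid-ranks with the tie-correction factor
1 − Σ(t³−t)/(N³−N); all-tied data give H = 0, p = 1 rather than an error.
Games–Howell uses q = |x̄ᵢ−x̄ⱼ| / sqrt((sᵢ²/nᵢ+sⱼ²/nⱼ)/2) with
Welch–Satterthwaite degrees of freedom and the studentized range
distribution over all k groups; at k = 2 it reduces to Welch's t-test
(Q₂,ν = √2·|t|), another oracle the tests assert.  The studentized-range
probabilities come from R's own `ptukey`; a brute-force double numerical
integration of the defining integral backs it as an independent accuracy
check (1 × 10⁻⁴) in the test suite.  Annual recruitment series are
compared on first differences (year-to-year changes), removing shared
decadal trends before the Pearson correlation; at least three consecutive
overlapping year pairs are required.  Complete-case analysis is used
throughout — no imputation anywhere in the statistics.

**Isoscape assignment.**  For each assumed hatch date (default an
arithmetic grid every 3 days from April 15 to May 15, the peak spawning
window; February and June single-month scenarios are ordinary
configuration changes) and each ontogenetic window, the gridded 10 m
temperature and salinity are averaged per cell over the window days — day
0 being the hatch date, so the larval window spans 61 days — and the two
linear relations map the means to a predicted otolith δ¹⁸O per cell.
Averaging the environment first and transforming second is the default
because the windows are defined on mean conditions; since both relations
are linear the transform-then-average alternative (available as a switch)
is identical on complete data and differs only under missing data.
Missing-data propagation is strict by default — a cell missing any day of
the window is missing in the mean — because relaxing it silently biases
window means toward the covered season near coastlines; a minimum-coverage
fraction can be configured instead.  A cell is a candidate nursery area
iff its prediction falls in the closed band mean ± 1 SD of the observed
group; per-date Boolean masks are aggregated by elementwise counting, so
darker (higher-count) cells match more hatch dates.  The fractionation
slope/intercept and the per-region salinity relations are *inputs*, not
package constants: the shipped defaults (−0.18 ‰/°C, 2.7 ‰; 0.42 ‰/psu,
−14.3 ‰) are documented placeholders of realistic magnitude for temperate
NW-Pacific waters, used by the tests and the synthetic generator only, and
must be replaced by species- and region-calibrated coefficients for real
inference.

## The synthetic-data generator

The generator exists so that every stage is testable without external
downloads, and it doubles as the package's study design.  It emulates:

* a seasonal environment T(lat, day) = base − gradient·(lat − lat₀) +
  amplitude·cos(2π(doy − 227)/365) plus a small smooth noise surface
  (base 23 °C, 0.6 °C/degree northward, amplitude 4 °C, noise 0.1 °C),
  and salinity 34.2 psu with an optional less-saline coastal patch;
* three provenance groups with fixed movement templates — locals resident
  in warm coastal cells, nonlocals and Pacific-offshores drifting from
  warm southern starts to cold northern waters over 120 days — whose
  rendered δ¹⁸O trends are decreasing for locals and flat-to-increasing
  for the drifters;
* group δ¹⁸O moments defaulting to the observed values for the system the
  package was developed around: locals larval −0.7 ± 0.4 ‰ and juvenile
  −1.5 ± 0.4 ‰, nonlocals −0.3 ± 0.2 and −0.2 ± 0.3 ‰, Pacific-offshores
  −0.1 ± 0.3 and 0.1 ± 0.3 ‰;
* micromilling at 30–160 μm segment widths with Gaussian analytical noise
  of 0.10 ‰ (inside the 0.06–0.13 ‰ instrumental precision range), linear
  radius growth of 5 μm/day with a lognormal per-fish multiplier
  (σ = 10%), and a Table-1-like sampling layout (age-0 summer–autumn
  captures in three coastal regions, age-1 late-winter–spring captures,
  an offshore age-0 group), with configured fractions of age-1 fish
  missing the juvenile milling (30%) or the increment reading (15%) so
  the discriminant and radius–age paths are always exercised.

Group mean growth multipliers (locals 1.0, nonlocals 1.25, offshores 1.2)
make the radius-at-60 dph feature separate locals from nonlocals clearly
but imperfectly; together with the overlapping larval δ¹⁸O moments this
reproduces the empirically observed discriminability — LOOCV accuracy in
the high 80s% with asymmetric per-class precision — rather than a
trivially separable cohort.  δ¹³C is modelled as pure noise around nearly
equal group means, because the real groups do not differ significantly in
δ¹³C and no environmental δ¹³C model is warranted.

Two rendering regimes matter for interpretation.  By default
(`calibrate_moments = TRUE`) each fish's forward-modelled daily series is
shifted by a smooth ontogenetic correction (linear in age between the two
window midpoints) so that its window means equal the configured group
targets plus per-fish biological deviates; the environment then supplies
only within-window structure, and the cohort reproduces the printed
moments exactly up to sampling.  With `calibrate_moments = FALSE` the
otolith records the raw forward model of the occupied cells, which is
what the geolocation experiments need: observed values must carry the
signature of the cells the fish actually occupied.  The generator
discretizes growth by whole days (day i occupies radius [r(i), r(i+1))),
so "window truth" is the growth-weighted mean over the days whose
deposits fall inside the window's radius span.

What the generator deliberately does **not** emulate: hydrodynamic
realism (no currents, eddies or advection fields), behavioural movement,
otolith crystallography or vital effects beyond an additive offset,
region-dependent seawater relations, or measurement drift.  Passing tests
therefore demonstrate the *correctness of the computational method* under
the assumed statistical structure — they do not validate the empirical
coefficient values, and real-data inference stands or falls with the
calibration coefficients supplied as configuration.

## Numerical choices and degenerate inputs

* Threshold/boundary ties: `juvenile δ¹⁸O == threshold` is local; exact
  discriminant score ties are local.  Both are probability-zero events
  fixed for determinism.
* Singular pooled covariance (constant or collinear features) is an error
  naming the likely cause, not a silent pseudo-inverse.
* Kruskal–Wallis with all values identical returns H = 0, p = 1;
  Games–Howell with zero variance in both groups returns p = 1 on equal
  means and a flagged degenerate p = 0 otherwise.
* MANOVA requires every group to exceed the feature count; the assumption
  battery marks any cell whose group is too small as not-computable
  instead of failing.
* Radius–age curves resolve non-monotone anchor means isotonically and
  clamp out-of-hull queries with a warning.
* Grids are cell-centered, latitude increasing northward, longitude
  eastward; fields sharing one grid per run, no regridding.
* All simulation randomness flows from one master seed through per-stage
  substreams, so stage outputs are reproducible independently of each
  other; identical configuration and seed give byte-identical CSVs.

## Problem sizes

The shipped tests and the acceptance script run the default cohort of 220
fish over three year-classes on a 17 × 21-cell 1° environment grid, the
geolocation experiment with 40 fish on a 33 × 25-cell 0.5° grid with 11
hatch dates, 2000 null replicates for the MANOVA size calibration, and
1000 replicates for the Levene size check — sizes at which the full suite
completes in well under a minute while keeping Monte-Carlo bands tight
enough to be meaningful.

## Known limitations

* The threshold rule is a hard classifier; no mixed-stock or probabilistic
  assignment is offered, matching the hard-assignment design it mirrors.
* The assignment mask is an interval-membership map, not a likelihood
  surface; cells just outside the ± 1 SD band vanish rather than fade.
* Isotopic overlap between environments is irreducible: distinct regions
  with similar temperature–salinity fields produce indistinguishable
  otolith values, so a mask is a set of *candidate* areas, never a proof
  of residence.
* The radius–age "mean relationship" is taken piecewise-linear through
  anchor means; if the true relation is strongly curved between observed
  ages, segment age estimates inherit that bias.
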