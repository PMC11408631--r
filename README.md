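# otoprov

Otolith-isotope provenance analysis and isoscape assignment for small
pelagic fish.

## The problem

Stock assessments usually assume that the recruits of a management unit
hatched and grew inside it.  For populations like the Japanese sardine
(*Sardinops sagax melanostictus*), where the Sea of Japan / East China Sea
(SJ-ECS) unit sits beside a much larger Pacific unit, that assumption can
fail silently: age-1 fish may immigrate from nurseries far outside the
sampled coastal system.  Otoliths record the fish's environmental history
chemically — otolith δ¹⁸O decreases with ambient temperature and increases
with seawater δ¹⁸O (itself linear in salinity) — so micromilled δ¹⁸O/δ¹³C
profiles along the otolith growth axis distinguish fish that experienced
the strong seasonal warming of a coastal nursery from fish that did not.

`otoprov` packages that workflow as reusable, tested stages:

1. **Profile windows** — correct the acid-fractionation offset between
   carbonate digestion temperatures (−0.09 ‰ for 72 °C-analysed δ¹⁸O),
   map milling distances to ages via per-cohort radius–age curves, and
   rescale heterogeneous micromill segments to two ontogenetic windows,
   larval (0–60 dph) and juvenile (106–120 dph): a segment contributes to
   a window iff the median of its age range falls inside it, and
   contributing segments are averaged weighted by milling width.
2. **Provenance classification** — per year-class, the *threshold* is the
   highest juvenile-stage δ¹⁸O among reference fish known to have grown in
   the coastal system (age-0 SJ-ECS captures and age-1 West Kyushu);
   fish at or below it are *locals*, above it *nonlocals*.  Fish without a
   juvenile measurement are classified by a pooled-covariance linear
   discriminant on three larval features (δ¹⁸O, δ¹³C, otolith radius at
   60 dph), with the class score
   ln π_c + μ_cᵀΣ⁻¹x − ½ μ_cᵀΣ⁻¹μ_c and leave-one-out cross-validation.
3. **Group statistics** — Wilks Λ = det(E)/det(E+H) MANOVA with Rao's F
   approximation, an assumption battery (Shapiro–Wilk, Mardia, VIF,
   Box's M, Brown–Forsythe Levene), tie-corrected Kruskal–Wallis,
   Games–Howell pairwise tests on the studentized range distribution, and
   a first-difference Pearson correlation for annual recruitment series.
4. **Isoscape assignment** — predicted otolith δ¹⁸O grids from gridded
   10 m temperature/salinity (netCDF), per assumed hatch date (default
   every 3 days, mid-April to mid-May) and window; cells whose prediction
   falls within the observed mean ± 1 SD band of the nonlocals are
   candidate nursery areas, and per-date masks aggregate to match counts.
5. **Synthetic data** — a generator for environments, fish trajectories
   and full cohort datasets with the statistical structure the analysis
   assumes, so everything above runs and is tested without any download.

## Worked example

```r
library(otoprov)

gen <- generate_cohort(sim_config(), seed = 42)  # 220 synthetic fish
ds  <- acid_correct_dataset(gen$dataset)
sv  <- extract_stage_values(ds)

rules <- compute_thresholds(sv)
rules
#>   year_class threshold_permil n_reference
#> 1       2013       -1.1552146          19
#> 2       2014       -0.8489854          15
#> 3       2015       -0.6614703          23

sv <- assign_by_threshold(sv, rules)
model <- fit_lda(sv)
cv <- loocv_lda(sv)
cat(sprintf("LOOCV: %d of %d correct (%.0f%%)\n",
            cv$n_correct, cv$n, 100 * cv$accuracy))
#> LOOCV: 88 of 95 correct (93%)
cv$by_predicted
#>   predicted n_predicted n_correct precision
#> 1     local          66        63 0.9545455
#> 2  nonlocal          29        25 0.8620690

sv <- classify_unlabeled(model, sv)
group_stats_report(sv)
#> MANOVA (Wilks): Lambda = 0.3553, F(6, 260.0) = 29.37, p = 8.81e-27
#>   KW larval_d18O          H = 67.56, df = 2, p = 2.13e-15
#>   KW larval_d13C          H = 3.11, df = 2, p = 0.211
#>   KW radius_at_60dph_um   H = 63.16, df = 2, p = 1.93e-14
```

The thresholds are the per-year-class juvenile-δ¹⁸O cutoffs (‰ VPDB) with
their reference-set sizes.  LOOCV reports, per *predicted* class, how many
predictions were correct — here 95% of predicted locals and 86% of
predicted nonlocals truly were, reflecting the designed overlap of the
larval features.  In the statistics block the three groups (locals,
nonlocals, Pacific-offshores) separate strongly on larval δ¹⁸O and otolith
radius while δ¹³C does not discriminate, which is the structure the
generator builds in.

The whole flow, including isoscape assignment and all output tables, also
runs from one configuration:

```r
run_pipeline(list(seed = 42, out_dir = "run1"))
# or: Rscript inst/scripts/otoprov-run.R --config run.yaml
```

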