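---
title: "Methods: nitrogen budgets of peri-urban mangrove soils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrogen budgets of peri-urban mangrove soils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and numerical choices
behind `mangroveN`, in the spirit of a methods appendix: what each
stage computes, which parameters matter and why their defaults are what
they are, what the synthetic generator does and does not emulate, and
where the design was genuinely open.

## Budget arithmetic and unit conventions

A dated core slice carries depth interval (cm below the sediment
surface, positive downward, half-open `[top, bottom)`), a modelled
calendar date, dry bulk density (g cm⁻³), and N and C mass fractions.
Fractions — not percents — are the internal representation everywhere;
percent appears only at the file interfaces, where it is converted on
read and write. This removes the classic silent ×100 bug from all
downstream arithmetic.

* Slice N stock: `BD × thickness × fN × 100` Mg ha⁻¹ (the 100 converts
  g cm⁻² to Mg ha⁻¹). Stocks are additive over any partition of a
  core's slices.
* Accumulation rate: `SAR × BD × fN × 1000` g m⁻² y⁻¹ with SAR in
  mm y⁻¹; 100 g m⁻² y⁻¹ = 1 Mg ha⁻¹ y⁻¹. The two formulas are
  unit-coherent: one year of deposition at the SAR forms a slice whose
  stock equals the rate.
* Molar C:N uses atomic weights 12.011 and 14.007.
* Slice thickness is taken at face value — the age models behind the
  input dates are *apparent* (they fold in compaction and diagenesis),
  so no compaction correction is applied here.

Deposition periods default to recent 1970–2016 (46 y) and historic
1930–1970 (40 y). Period membership is by slice date with half-open
intervals, so a slice dated exactly 1970 belongs to the recent period
only; the convention is arbitrary (the underlying studies do not state
one) but guarantees the two periods partition 1930–2016 slices with no
double counting. Period stocks are divided by period length before
recent-vs-historic comparisons, since 46- and 40-year windows would
otherwise differ mechanically.

### Depth extrapolation

Profiles of N density (Mg ha⁻¹ per cm) decay with depth roughly
exponentially. To extend a ~28–37 cm inventory to 50 or 100 cm, the
package fits `ln(density) = a + b·depth` by least squares and adds the
analytic integral of `exp(a + b·z)` from the deepest observation to the
target. What exactly should be log-transformed was an open choice; we
model the *density* profile (rather than accumulation-rate profiles)
because it integrates in closed form — which gives an exact oracle for
testing — and reproduces the qualitative flattening of depth-averaged
stocks with deepening target. An accumulation-based variant is the same
function applied to rate densities. Non-positive densities are a domain
error (the log is undefined); a non-negative fitted slope triggers a
warning because extrapolating growth downward is almost certainly wrong.

## Bootstrap design

Per core and period, 1,000 with-replacement resamples of the measured
values give replicate means; the estimate is the mean of replicates and
the 95% bounds are the empirical 2.5th/97.5th percentiles. Percentiles
interpolate linearly between order statistics (R's default type 7); the
quantile rule is not stated in the underlying methods and the choice is
immaterial at B = 1000.

For derived quantities (accumulation, stock) each replicate draws one
SAR, one bulk density and one %N independently and uniformly from the
same core and period — deliberately *not* from the same depth — and
applies the formula. The replicate statistic is that single derived
value. An alternative reading (each replicate averages several paired
draws) is implemented via `draws_per_replicate` but is not the default:
the single-draw form matches the stated procedure and yields wider,
more honest intervals. Site estimates pool the replicate vectors of the
duplicate cores (2,000 values) and recompute percentiles; when the two
cores disagree the pooled bounds widen, which is the intended behaviour
for spatial comparisons.

Significance is overlap-based: two quantities differ when their closed
95% intervals are disjoint; a shared endpoint counts as overlap
(conservative). Percentile bootstrap at n ≈ 15 slices is approximate —
simulated coverage of a 95% interval sits near 92%, and the test suite
asserts the 90–98% band rather than nominal coverage.

Reproducibility: every stochastic function takes a seed, and the
pipeline derives per-core substreams from `(seed, core_id)` so that the
order in which cores are processed can never change a result.

## Estuary-wide upscaling

Site values are upscaled to the estuary in three steps per iteration:
draw one value per site, interpolate to every mangrove mask cell by
inverse-distance weighting, convert Mg ha⁻¹ to per-cell mass and sum.
One hundred iterations give the mean and standard error of the totals
(the SE shrinks as 1/√n, which the tests check at 100 vs 400).

* **IDW power.** Default 2; the source methodology does not state its
  exponent. IDW is a convex combination, so interpolated values always
  lie within the range of the drawn site values, and a query at a site
  returns that site's value exactly.
* **Skewed draws.** Within-site value distributions are right-skewed,
  so draws use a two-piece (Fernández–Steel) skew normal with shape ξ,
  re-centred and rescaled to hit the requested mean and sd exactly;
  ξ = 1 reduces to the normal. Default ξ = 1.5, a moderate right skew
  consistent with the generator's core values. Draws are truncated at
  zero (negative stocks are unphysical); the truncation-induced mean
  shift is computed by numerical integration of the skewed density and
  corrected only when it exceeds 1% of the target mean (it is logged
  whenever correction occurs). For realistic stock distributions the
  zero-mass is negligible and no correction fires.
* **Mask and resolution.** The native land-cover mask is a 2 m grid
  over 2,313 ha; the package treats resolution as configuration. The
  default synthetic mask is an ~750 ha ellipse at 20 m cells (~19,000
  cells), a desk-scale stand-in; rectangular-mask refinement tests show
  the deterministic total moves < 0.5% when cells are halved, so coarse
  cells do not bias totals appreciably.

Aboveground stand N is `biomass × Σ proportion × species N content`
with defaults 0.26% (*A. germinans*), 0.157% (*L. racemosa*), 0.205%
(*R. mangle*) and 0.31% (non-mangrove); unknown species fall back to
the non-mangrove value.

## Food-nitrogen flow model

The substance-flow model is population-linear: food N input =
population × per-capita food demand × 2.45% N; exports split 38%
municipal solid waste (of which 5.96% is composted, the rest
landfilled), 44% wastewater exported to the ocean after primary
treatment, 18% septic. Human stock change is assumed zero, so the four
flows balance the input to 10⁻⁹ relative — an enforced invariant. The
per-capita demand (286.1 kg person⁻¹ y⁻¹) and the compost share are
back-derived from the published watershed totals (5,390 Mg over 769,000
persons; 122 of 2,046 Mg MSW), because the exact upstream figures are
printed only in supplementary material; both are plainly flagged as
derived defaults in `flow_config()`. One published site cell (1.1 Mg
for 517 persons) is inconsistent with the per-capita model (it implies
~3.6 Mg); the package follows the model and documents the discrepancy
rather than reproducing the cell. The child-stock check (20% of the
population gaining 2.5 kg y⁻¹ at 2% N) quantifies the neglected human
retention: ~7.7 Mg y⁻¹, under 0.5% of wastewater flows.

## Porewater chemistry

DIN = NH₄⁺ + NOₓ with non-detects set to zero by default (the more
conservative variability estimate) or to the detection limit
(0.05 µM default); the factorial comparison is required by test to give
identical significance calls under both policies. Molar N:P is
DIN/PO₄³⁻, reported to one decimal, matching conventional reporting.
Site and season effects are evaluated by a two-way fixed-effects
decomposition with interaction on `ln(x + dl)` — the offset applied
uniformly so zeros are defined and the transform is monotone — with
Shapiro–Wilk residual normality reported and all pairwise
site-within-season and season-within-site contrasts Bonferroni-adjusted
at family level 0.05 (via `stats::aov` and `emmeans`). Replicate counts
per cell are not stated in the source; the synthetic fixture uses n = 5
per site and season, enough for the contrasts to be defined and small
enough to stay honest about power.

## Isotope depth profiles

δ³⁴S profiles are fitted against slice-midpoint depth by OLS, linear
and quadratic. Under automatic selection the quadratic form is kept
when its quadratic term is significant at 0.05 (the "best fit"
criterion was unstated; a t-test on the added term is the simplest
defensible rule). A numerically negligible quadratic coefficient —
total contribution below 10⁻⁸ of the data scale across the profile — is
treated as absent before testing, so noiseless linear data select the
linear form. Cross-site term comparisons hold the familywise error at
5%: each term's interval is computed at Bonferroni level
`1 − 0.05/m`, with `m` defaulting to the number of unordered site pairs
times the terms each pair shares (which comparisons "count" was
ambiguous in the source; the default is the most inclusive reading).
Terms differ when the adjusted closed intervals are disjoint; comparing
a quadratic term against a linear fit returns "not comparable".

δ¹⁵N adds no new machinery: period means and recent-vs-historic calls
go through the same bootstrap and overlap comparison as %N.

## The synthetic generator

`generate_core()` reproduces the sampling design: 1-cm slices over
0–3 cm then 2-cm slices to 37 cm (real cores ran 37–50 cm); a linear
age-depth relation per period anchored at the 2016 collection surface,
with the period SARs setting the recent (≈ 0–18 cm at estuary-mean
SAR) and historic (≈ 19–28 cm) depth brackets; right-skewed draws of
bulk density and %N with period-specific moments, truncated to
physical ranges; C fractions from a site molar C:N; δ¹⁵N as period
mean plus noise; δ³⁴S from a site quadratic profile plus noise. The
default five-site pattern spans the study's contrasts: a dredged
high-urban site (dense soil, low %N, surface-depleted δ³⁴S), a clogged
sewage-influenced site (SAR 6.2 mm y⁻¹, surface-enriched δ³⁴S,
P-rich porewater), a settling-basin lagoon (bulk density 0.18 g cm⁻³,
%N 1.24), a dredged-inlet lagoon with large within-site variability,
and an isolated hypersaline forest (molar C:N 12, porewater NH₄⁺ over
1,000 µM). Template envelopes (bulk density means 0.1–1.1 g cm⁻³, SARs
1–7 mm y⁻¹, %N means 0.3–2%) are the observed ranges of such systems
and are enforced at construction.

With `noise = 0` every draw equals its mean, so the full pipeline must
reproduce the generator's ground truth *exactly* — the end-to-end
identity test. What the generator does **not** emulate: nonlinear
apparent age models (real age-depth curves bend; linearity within
periods is enough to test period logic), radionuclide activities,
hydrological realism, spatial autocorrelation of soil properties beyond
the site means, and core-to-core correlation. Passing tests therefore
demonstrate correctness of the computations under the stated
statistical structure, not fidelity of any particular field system.

## Problem sizes and numerical tolerances

The default simulation scale — 5 sites × 2 cores, 37 cm cores, 1,000
bootstrap replicates, 20 m cells (~19,000-cell mask), 100 interpolation
iterations — runs the full pipeline in seconds and is the scale at
which all reported synthetic results are computed. Coverage
experiments use 500 repetitions at n = 15. Exact identities
(zero-noise recovery, IDW conservation, additivity) are asserted at
10⁻⁹–10⁻¹²; the analytic extrapolation integral at 10⁻⁶; Monte-Carlo
checks at 3–4 standard errors of the relevant estimator. Comparisons
against published numbers are held at their printed precision.

## Known limitations

* Dates and SARs are inputs; no age-depth modelling is performed, and
  uncertainty in dating is not propagated (the random-pairing bootstrap
  absorbs depth-to-depth variability but not systematic age error).
* The percentile bootstrap slightly under-covers at two cores per site;
  pooled site bounds are descriptive, not calibrated intervals.
* IDW with five support points is an interpolation convenience, not a
  geostatistical model; no kriging variance is available.
* The flow model is annual-average and population-linear; it does not
  model food provenance or treatment-plant processes.
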