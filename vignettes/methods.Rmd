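---
title: "Methods: small-area wood-burner estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area wood-burner estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

woodburnr estimates where residential wood burners are, at small-area
resolution, from Energy Performance Certificate (EPC) registers, and
validates those estimates against ambient PM2.5 measurements. This vignette
documents the statistical model behind each stage, the parameter defaults
and why they hold, and what the test evidence does and does not establish.

## 1. From certificates to properties

An EPC register holds one row per certificate, not per property, and free
text rather than coded heat sources. Ingest proceeds in fixed order:

1. **Deduplication.** Byte-identical rows (after whitespace normalisation)
   are removed; colliding certificate ids with differing fields keep the
   later inspection date; rows without a certificate id cannot be
   deduplicated and are rejected with a reason.
2. **Classification.** Case-insensitive fixed-substring search over the
   main and secondary heat-source descriptions. Wood keywords (wood, log,
   logs, biomass, pellet, wood chip) are a subset of the solid-fuel
   keywords (plus solid fuel, coal, anthracite, smokeless, multi-fuel,
   peat), so `wood_fuel` implies `solid_fuel` by construction. The keyword
   lists are data, not code: a YAML ruleset can replace them per register.
3. **Harmonisation.** Property type × built form maps onto Census 2021
   accommodation categories (detached / semi-detached / terrace / flat /
   other); tenure maps onto owner-occupied / private rented / social
   rented, with a "new dwelling" transaction overriding tenure as
   new-build.
4. **Linkage.** A UPRN lookup attaches LSOA, ward, local-authority and
   region codes. The lookup must be a function of UPRN — duplicates are a
   hard error, because silent many-to-many joins are the classic way such
   analyses go wrong.
5. **Latest certificate.** Within each UPRN the latest inspection date
   wins; date ties break by greatest certificate id, so the flag is
   deterministic.

## 2. Census post-stratification

The register is a biased sample of the housing stock: owner-occupied and
older detached houses — exactly the properties most likely to have a wood
burner — enter the register at lower rates than flats and rentals. The
correction is post-stratification within LSOA × property-type strata:

\[
\widehat{N}_{ls} = \hat p_{ls} \cdot n^{census}_{ls},
\qquad
\hat p_{ls} = \frac{\text{wood-flagged EPCs in stratum}}{\text{EPCs in stratum}}
\]

Strata with fewer than 20 certificates (`min_epc = 20`) are suppressed —
excluded from both numerator and denominator — because a rate from a
handful of certificates transfers noise, not signal, onto the Census
total. An optional `"borrow"` mode substitutes the pooled local-authority
rate instead; the default is exclusion because borrowing trades variance
for bias in exactly the areas where the data are weakest.

Two reporting metrics follow:

- **Prevalence** (% of houses): houses only — detached, semi-detached,
  terrace — because flats essentially never have a registered burner and
  including them would dilute the quantity of interest.
- **Concentration** (burners per km²): all property types, divided by land
  area, the exposure-relevant quantity.

Both are stored as numerator/denominator pairs so aggregation up the
hierarchy (ward, LAD, region) is exact: parent prevalence is the ratio of
summed numerators to summed denominators, and totals are conserved to
floating-point precision (tested at 1e-9 relative). For choropleth
display, values are truncated at the 5th/95th percentiles (quantile
type 7) so a few extreme areas do not flatten the colour scale.

## 3. Temporal trends

Annual prevalence uses **all** certificates, not just the latest per
property, because a property's heat source can change between
certificates; restricting to latest certificates would smear installation
timing. IMD deciles are computed within urban and rural strata separately
(decile 1 = most deprived, ties broken by LSOA code), so urban/rural
composition differences do not masquerade as deprivation gradients. The
repeat-certificate analysis groups properties by their total number of
certificates (2–4; 5+ excluded as too sparse) and tracks prevalence by
certificate order within group — a within-property design that removes
cross-sectional composition effects.

## 4. Monitor validation

The exposure at a monitoring site is the estimated burner count within a
circular buffer (defaults 500 m, 1 km, 2 km) or the site's 1 km grid
square. Because estimates are areal, counts are apportioned by
intersection area under a uniform-density assumption. The geometry is
exact, not rasterised: disc–polygon intersection areas come from Green's
theorem with circular-segment clipping, and rectangle clipping is
Sutherland–Hodgman. Unit tests pin these against analytic cases (half and
quarter discs) and Monte-Carlo oracles to 4 standard errors.

The wood-smoke signal statistic is the **peak/off-peak difference**: mean
PM2.5 during evening burning hours (7pm–1am) minus the daytime mean
(5am–5pm), within season (winter = DJF, summer = JJA) and day type
(weekday/weekend), requiring at least 24 valid hours on each side.
Associations are Spearman correlations — the validation claim is ordinal,
and log-scaling the exposure then provably cannot change the result (rank
invariance is tested exactly on 1,000 datasets).

Confidence intervals are BCa bootstrap (default B = 10,000), resampling
**sites** as the sampling unit. The implementation is in-package (bias
term z0 from the fraction of bootstrap statistics below the estimate,
clamped to ±4 when degenerate; jackknife acceleration; adjusted
percentiles, quantile type 7) and is cross-checked in the test suite
against the reference implementation in the boot package. The
winter-minus-summer correlation difference uses paired resampling: each
bootstrap draw resamples whole site rows, so both seasonal correlations
are evaluated on the same resampled sites, which respects the pairing in
the data. Housing density within 1 km serves as a negative control
exposure. Calibration note: BCa coverage is verified at 0.93–0.97 for a
Normal mean (n = 50); for a strongly skewed Exponential mean at the same
n, both this implementation and the boot package cover ≈0.90 — a
documented small-sample property of BCa itself, not an implementation
artefact.

## 5. Socio-economic association

LSOA prevalence (a proportion) is modelled with beta regression: logit
link, constant precision φ, maximum likelihood via BFGS with analytic
gradient from logit-scale least-squares starts, standard errors from the
observed information, CIs = estimate ± 1.96 SE. Boundary zeros are
compressed with \((y(n-1)+0.5)/n\). The fit is verified against an
independent optimiser (nlm, different algorithm and start) to 1e-4
relative agreement, and planted coefficients — including an IMD effect of
−0.012 per unit on the logit scale — are recovered within 3 SE in ≥95% of
simulations at n = 5,000. Models are fitted pooled (with an urbanicity
indicator) and stratified urban/rural; a covariate constant within a
stratum (the smoke-control flag in rural areas) is dropped from that
stratum with a message. Descriptive outputs are a prevalence-decile table
of covariate means and region-stratified covariate-decile points for
scatter plots.

## 6. The synthetic scenario

Every input the pipeline reads can be generated with known ground truth.
Defaults are the study conditions and were fixed by design, before any
acceptance evaluation:

- **Geography**: a 12×12 grid of 1 km² LSOAs; contiguous urban block
  (columns 1–6) containing a smoke-control sub-block (columns 1–3); wards
  2×2 cells, LADs 4×4, regions 8×8. IMD ~ Gamma(2, scale 10) (mean 20,
  right-skewed like the real index); median age truncated-Normal, higher
  rural; percent-white logit-Normal, higher rural.
- **Stock and selection bias**: ~410 properties per LSOA across five
  types. EPC inclusion by type — detached 0.40, semi 0.60, terrace 0.80,
  flat 0.90, other 0.50 — reproduces the register's key pathology:
  coverage is lowest exactly where burners are most common.
- **Wood-burner model**: logit(p) = −3.2 − 0.012·IMD + 0.02·age −
  0.5·urban + type effect (detached +1.0, terrace −0.45, flat −2.5). This
  puts overall prevalence near 8–9% with a detached:terrace prevalence
  ratio ≈3.5 — the published magnitude structure — and uses the published
  IMD logit slope as the planted truth.
- **Certificates**: 1–4 per property (70/22.5/6/1.5%), dates uniform over
  the 2009–2025 window, monotone wood-burner installations between
  certificates at rate 0.05, exact-duplicate rows planted at 3%, 2% of
  UPRNs withheld from the lookup. Free text is rendered from templates in
  which every wood property's text contains exactly one wood keyword —
  classification is exactly invertible by design, so classification error
  never contaminates tests of downstream stages. A `noisy_text` mode adds
  keyword-free distractor strings for robustness tests.
- **Monitoring**: 60 urban-background monitors at cell centroids (plus 5
  non-background sites that must be filtered out), two years of hourly
  PM2.5: seasonal background 8 + 3·cos(2π(doy−15)/365.25), Gaussian noise
  σ = 2, 5% missing, and a wood term κ·density (κ = 0.05 per burner/km²)
  added only on peak hours in DJF. The diurnal-cycle amplitude defaults to
  **zero** so the planted peak/off-peak difference equals κ·density
  exactly in expectation — any non-zero diurnal term common to both hour
  sets would cancel anyway, but zero makes the recovery test sharp rather
  than approximate.

The generator is deterministic per seed (byte-identical output files,
tested), and emitted Census totals equal truth totals exactly.

## 7. What the tests establish — and what they do not

The acceptance suite shows that, under the generator's assumptions, the
pipeline recovers what was planted: the Census correction reduces
prevalence RMSE relative to uncorrected register rates and is nearly
unbiased (|bias| < 0.3 pp over 500 LSOAs); the winter-evening signal is
detected (winter weekday R > summer R, paired BCa CI excluding 0 in ≥80%
of 200 noise replicates); the planted amplitude is recovered within 5%;
and the beta-regression coefficients are recovered at nominal coverage.
In-table arithmetic on published counts reproduces every printed
percentage of the characteristics table.

None of this validates the substantive field findings: synthetic
properties are spatially uniform within cells, monitors sit at cell
centroids, there is no meteorology, no traffic co-pollution, no spatial
confounding between deprivation and monitor placement, and text is
invertible by construction. Passing here means the machinery is faithful,
i.e. that applying it to a real register would measure what it claims to
measure — not that the real-world effect sizes are correct.

## 8. Problem sizes and runtime

Defaults aim at desk-scale determinism: the 144-LSOA default scenario
generates in ~2 s (monitoring included); the 500-LSOA correction study
runs in ~15 s; a full pipeline run with B = 10,000 bootstrap replications
completes in under a minute. The acceptance suite (including 200
end-to-end monitoring replicates) runs in ~10 minutes.
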