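---
title: "Plot-level forest carbon estimation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plot-level forest carbon estimation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nficarbon)
```

`nficarbon` reimplements the plot-level estimation chain of Nepal's
national forest inventory as a tested, reusable pipeline: tree-level
allometric aboveground biomass (AGB) expanded to per-hectare plot
values through the concentric circular sample plot (CCSP) design, and
0–30 cm soil organic carbon (SOC) stocks from composite core samples.
This vignette is the package's own account of the models it implements,
the parameters that matter, and the choices made where the field
protocol left the design open.

## Tree volume and biomass

Stem volume over bark follows the log-linear allometric form used by
the national volume tables,

$$\ln V = a + b\,\ln d + c\,\ln h,$$

with $d$ the diameter at breast height (DBH, cm, measured at 1.3 m at
0.1 cm precision), $h$ the total tree height (m), and $a, b, c$
species-specific coefficients (`stem_volume()`). Stem biomass is
$B_s = V \cdot D$ with $D$ the air-dried wood density (kg m⁻³), and
total tree biomass adds branch and foliage components through
species-specific component-to-stem ratios,
$B = B_s + r_b B_s + r_f B_s$ (`stem_biomass()`,
`total_tree_biomass()`).

**Component policy by tree status.** The inventory includes standing
live and dead trees, broken trees and stumps, but does not state which
biomass components each carries. The package default — a documented
choice, switchable via the `policy` argument — is: live trees carry
stem + branch + foliage; standing dead trees stem + branch (foliage
assumed shed); broken trees and stumps the partial stem only.

**Broken stems and stumps.** For a tree cut or broken at height $z_c$,
the stem volume is taken from stump height (0.15 m) to $z_c$ along a
taper profile (`broken_stem_volume()`). The national taper-curve
parameters are not publicly reproduced, so the package defaults to a
parabolic profile — relative diameter $1 - z/h$, hence cross-sectional
area $(1-z/h)^2$ — and always rescales the profile so that its
full-stem integral equals the allometric total volume. Two
consequences: (i) unbroken-tree biomass is exactly independent of the
profile choice, and (ii) the partial volume is a pure fraction
$(1 - z_1/h)^3 - (1 - z_2/h)^3$ of total volume under the default
profile, which the tests use as a closed-form oracle against the
quadrature implementation (`stats::integrate` at a relative tolerance
of 1e-12). Any other profile can be plugged in as a function of
relative height.

**Species fallback.** National tables provide coefficients for major
species and average values for the rest; correspondingly, unknown
species codes fall back to a table-average species row unless
`fallback = FALSE`, in which case they are an error naming the plot
and species.

## CCSP expansion to per-hectare AGB

Each plot is a set of nested circles in which progressively larger DBH
classes are measured:

| radius (m) | DBH class (cm) | area (m²) |
|-----------:|---------------:|----------:|
| 4  | 5.0–9.9   | 50.27   |
| 8  | 10.0–19.9 | 201.06  |
| 15 | 20.0–29.9 | 706.86  |
| 20 | ≥ 30      | 1256.64 |

Areas are stored at full precision $\pi r^2$; the 2-dp printed values
above are reproduced within 0.01 m² but are not used in arithmetic
(their own roundings are mutually inconsistent at 2 dp). DBH classes
are half-open $[\min, \max)$ with the upper class winning at the
printed boundaries — a tree recorded at exactly 20.0 cm belongs to the
15 m ring — consistent with class labels like "20.0–29.9" at 0.1 cm
recording precision. A tree on the ring of area $A$ represents
$10000/A$ trees per hectare, and plot AGB is

$$\mathrm{AGB} \;=\; \sum_i B_i \,\frac{10000}{A_{\mathrm{ring}(i)}} \Big/ 1000 \quad (\mathrm{t\,ha^{-1}}).$$

Records with statuses outside {live, dead, broken, stump} (fallen
deadwood, climbers) and trees below the 5.0 cm threshold are filtered
out and tallied, never silently dropped. No slope correction of plot
areas is applied: the field protocol we follow does not describe one,
and this is a known limitation on steep terrain.

## Soil organic carbon, 0–30 cm

Four pits per plot are cored (100 mm corer, 37 mm cutting-edge
diameter; the cylinder at the cutting edge gives the 107.5 cm³
sub-sample volume; the 40 mm upper diameter is metadata only) and
pooled into one composite sample per depth layer (0–10, 10–20,
20–30 cm). Per layer:

1. **Fine-fraction bulk density**: oven-dry < 2 mm mass divided by
   composite volume minus the coarse-fraction (> 2 mm) volume measured
   by water replacement — stones are assumed void of organic carbon
   (`bulk_density_fine()`).
2. **Total organic carbon**: Walkley–Black OC% × 1.33 (partial
   wet-combustion recovery correction), as a mass fraction
   (`total_oc_fraction()`).
3. **Volumetric carbon density**: the product of 1 and 2 (`soc_ff()`).
4. **Stoniness adjustment**: × $(100 - \mathrm{Stone\%})/100$ using the
   field-observed volumetric stoniness (`adjust_stoniness()`). The
   source protocol prints this formula as
   $(100 - \mathrm{Stone\%}/100)\cdot \mathrm{SOC_{FF}}$, which is
   dimensionally inconsistent (it would inflate stocks by a factor
   near 100); the package implements the standard coarse-fragment
   correction, which is the identity at 0% stones and zero at 100%.
5. **Layer stock**: × thickness × 100 (1 g cm⁻² = 100 t ha⁻¹), and the
   three layers sum to the 0–30 cm plot stock (`layer_stock()`,
   `plot_soc()`).

The organic (litter) layer is excluded from SOC. The number of pits is
4 by design but configurable (pits on rock can be missing). One
stoniness value per plot × layer is accepted; whether the original
workflow recorded it per pit or per composite is ambiguous in the
protocol.

## Design-based summaries

Plots sit in clusters (4 per cluster in the Terai, 6 in the mountain
regions) laid out on a 4 km grid, with physiographic regions as strata.
`cluster_design_summary()` estimates the mean as the stratum-weighted
mean of cluster means and the standard error from the between-cluster
variance of cluster means within strata:
$\mathrm{se}^2 = \sum_h W_h^2 s_h^2 / m_h$. Stratum weights are equal
by default — the original estimator's weighting is not documented, and
this is recorded as a simplification; area weights can be supplied.
Strata with fewer than two clusters join the mean but are excluded from
the variance with a warning. The relative error,
$100 \times 1.96 \times \mathrm{se}/\mathrm{mean}$, is the 95%
confidence half-width as a percentage of the mean; with singleton
clusters the whole estimator collapses to the ordinary standard error
of the plot-level mean, which the tests verify against `sd(x)/sqrt(n)`.

## The synthetic inventory generator

`gen_inventory()` emulates the inventory's structure so that every
stage is testable without any download: clusters on the 4 km grid
(plots 300 m apart along an L-shaped track — within-cluster geometry is
metadata only), per-plot tree lists, species allometry tables, and
three-layer soil composites. Key defaults, chosen once as a plausible
mid-hill broadleaf stand:

* stand density 400 stems ha⁻¹ above the 5 cm threshold;
* DBH ~ Weibull(shape 1.3, scale 18 cm) truncated to [5, 150] cm
  (right-skewed, uneven-aged);
* height $h = 1.3\, d^{0.75} e^{\varepsilon}$,
  $\varepsilon \sim N(0, 0.15^2)$;
* status probabilities live 0.85, dead 0.06, broken 0.06, stump 0.03;
* fine-fraction bulk density 0.8–1.4 g cm⁻³, surface OC 1–3.5%
  declining ×0.6 per layer, stoniness 0–40%.

Trees are drawn **per DBH class** with Poisson intensity
`stems_per_ha × P(class) × class subplot area`, so small trees are
sampled on small subplots and the expansion-factor arithmetic is
exercised nontrivially. A consequence is that the raw tree list is
size-biased by design; the generator's DBH distribution is recovered by
the expansion-weighted mean, which is what the convergence test checks
(within 3 standard errors at ≥ 10,000 stems). Determinism is strict:
one master seed, with per-plot substreams derived by stable hashing of
the plot id, so generation order can never change a single value, and
reruns are byte-identical end to end.

The generator also carries its own **ground truth**: per-plot AGB and
SOC computed from its own tree and soil records through the same
estimation functions the pipeline uses. Recovery tests can therefore
demand exact agreement for AGB and 1e-9 t ha⁻¹ for SOC. Two honest
caveats about what passing tests show:

* The synthetic allometry coefficient ranges ($a \in [-4.5, -2.0]$,
  $b \in [1.5, 2.2]$, $c \in [0.6, 1.1]$) are stand-ins on the scale of
  national tables whose log-linear outputs are litre-scale, while the
  volume interface is declared in m³; synthetic per-hectare AGB is
  therefore roughly three orders of magnitude above real stands. This
  affects realism of magnitudes, not any arithmetic the tests verify.
* The landscape has no spatial autocorrelation, no remote-sensing
  covariates, and no measurement error beyond the models above, so
  passing tests demonstrate correctness of the estimation arithmetic,
  not field realism.

**Empty plots.** A measured plot with no tree in any class is
represented by an absence of rows in the tree table, which the pipeline
cannot distinguish from a plot that was never measured for AGB; such
plots get a missing AGB, while the generator's ground truth records 0.
At the default stand density the case has probability ~e⁻¹⁸ per plot
and never arises in practice.

## Numerical and interface choices

* Taper quadrature: `stats::integrate`, relative tolerance 1e-12, so
  the integration-consistency identity (cut at the tip = full stem
  minus the 0–0.15 m stump segment) holds to 1e-9 relative.
* A cut point at or below stump height yields 0 m³ with a warning.
* Missing pools are written as **empty CSV fields** (never 0, never a
  literal "NA") in the published 5-column schema
  `plot_id,longitude,latitude,agb_t_ha,soc_t_ha`; numbers are written
  at fixed 6-dp so write → read → write is byte-identical.
* Coordinate bounds (longitude 80.0–88.3, latitude 26.3–30.5) are
  validated on read for real-extent data and switchable off for
  synthetic fixtures.
* One log line per pipeline stage reports counts in, filtered, and out,
  so filtering behaviour is auditable.

## Problem sizes

The test suite exercises the full chain on a 1,008-plot synthetic
inventory (168 mountain clusters) — against independent brute-force
per-tree and per-layer oracles on every plot — plus smaller focused
fixtures; the bundled `scripts/acceptance.R` runs a two-stratum
inventory (40 Terai + 60 Middle Mountain clusters, 520 plots). These
sizes were chosen as comfortably large enough to exercise every code
path and design stratum.

## Known limitations

* No belowground biomass, no carbon-fraction conversion of AGB (the
  output is biomass, matching the published dataset), no litter or
  fallen-deadwood pools, no depth extrapolation beyond 30 cm.
* No slope correction of plot areas.
* No national-total extrapolation: that requires forest-area weights
  outside the plot data.
* Whether dead trees' branch ratios should be reduced is unknown; the
  component policy is a knob, not a claim.
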