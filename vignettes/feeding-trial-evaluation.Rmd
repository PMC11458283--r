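---
title: "Marker-based digestibility and nutrient retention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based digestibility and nutrient retention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedeval)
```

## The problem

Formulating fish feeds around locally available protein sources requires two
numbers per ingredient and nutrient: how much of the ingested nutrient the
fish can absorb (the apparent digestibility coefficient, ADC) and how much of
it ends up as body tissue (the nutrient productive value, NutrPV). Neither is
observable directly for an ingredient, because fish cannot be fed a raw
ingredient alone. The standard workaround is the reference-diet substitution
trial: a nutritionally complete reference diet is fed alongside test diets in
which a fixed dry-matter (DM) fraction of the reference mash -- conventionally
30% -- is replaced by the ingredient of interest, and the ingredient's
coefficients are recovered algebraically from the two diets' coefficients.
`feedeval` implements the complete quantitative analysis of such a trial,
plus a generator of synthetic trials with known ground truth so that every
estimator in the chain can be validated by parameter recovery.

## Composition arithmetic

All concentrations are stored on a DM basis in g/kg, the unit of proximate
feed analysis; percent views are derived on demand. This avoids silently
mixing as-is and DM bases, the classic unit error of feed evaluation
(`read_composition_table()` converts flagged as-is rows on ingest). Optional
analytes that were not determined are `NA`, never 0 -- zero is a legal
concentration.

Two quantities are defined by difference rather than assayed:
nitrogen-free extract `NFE = 1000 - CP - CL - CF - ash` (the carbohydrate
fraction) and organic matter `OM = 1000 - ash`. The package treats these as
exact identities: `nfe_by_difference()` plus its four components always
returns 1000, and a negative closure is an error naming the offending
inputs, not a clamped zero. The bundled reference dataset closes exactly for
13 of its 14 diets; one poultry by-product diet's published analytes close 3
g/kg below its published NFE, which the test suite documents rather than
hides.

Mixture prediction (`predict_mixture_profile()`) is linear in the inclusion
fractions, with the indigestible marker dosed separately at its formulated
level (default 5 g/kg DM). The prediction is the *formulated* composition;
laboratory analysis of the manufactured diet deviates by assay and mixing
error, so agreement is a soft consistency check -- the bundled diets agree in
crude protein within 5% relative, except two bone-rich poultry meals that
assay up to ~8% above the recipe.

## The digestibility model

With an indigestible marker (here TiO~2~) mixed homogeneously into the feed,
the ratio of marker to nutrient concentrations between feed and feces
estimates the absorbed fraction without total feces collection:

$$\mathrm{ADC}\,\% = \left[1 - \frac{M_{feed}}{M_{feces}}\cdot
  \frac{N_{feces}}{N_{feed}}\right]\times 100 .$$

The estimate is *apparent* because endogenous fecal losses are not separated
from undigested feed. Assumptions: the marker is neither absorbed nor
secreted, feed and feces are sampled on the same DM basis, and the collected
feces are representative of total egesta (settling collection systematically
differs from stripping; coefficients from the two methods are not directly
comparable). Estimates may legitimately fall outside 0--100% through assay
error; the package reports them verbatim with a warning and never clamps.

### Ingredient-level back-calculation

If nutrient absorption from the reference fraction is unchanged by the
substitution (the additivity assumption), the test diet's coefficient is the
nutrient-weighted mean of its parts, and the ingredient coefficient follows
by the affine inversion

$$V_{ing} = V_{test} + \left(V_{test} - V_{ref}\right)
  \frac{f_{ref}\,D_{ref}}{f_{ing}\,D_{ing}},$$

where $D_{ref}$, $D_{ing}$ are the nutrient concentrations of the reference
diet and the ingredient and $f_{ref}/f_{ing}$ the DM inclusion fractions
(nominal 0.7/0.3 by default, configurable; a recipe that displaces part of
the mash with the marker, 700:298.5:5, still uses the nominal constants, and
the exact fractions only matter for mixture prediction). The same formula,
with retention coefficients in place of ADCs, gives the ingredient-level
nutrient productive value -- `ingredient_adc()` and `ingredient_nutrpv()`
are one shared implementation, `back_calculate()`.

The slope $1 + f_{ref}D_{ref}/(f_{ing}D_{ing})$ is the error amplifier of
the design: for an ingredient nearly devoid of the nutrient (say 16 g/kg
lipid against a 174 g/kg reference), a one-point error in the diet-level
ADC moves the ingredient value by more than 25 points. This is why lipid
coefficients of low-lipid ingredients (feather meals, blood meal) are
reported with huge SDs or negative values in real trials, and why the
package's worked-example comparison excludes them from numeric judgement as
"rounding-sensitive" (ingredient crude lipid ≤ 20 g/kg DM) while covering
them with a sensitivity test instead.

### Replicate pairing

Diet-level ADCs are computed per replicate aquarium and then summarized
(mean, sample SD). For the back-calculation the package defaults to pairing
each test-diet replicate with the *reference-diet mean* of the same run
(`pairing = "pair-to-mean"`), because reference and test aquaria are
unpaired experimental units; `"pair-by-block"` pairs i-th with i-th for
strictly blocked layouts, and `diet_means = TRUE` reproduces a back-
calculation from tabulated means only. Because the map is affine, all three
agree exactly in the mean; they differ only in the dispersion they
attribute to the ingredient (the mean-only mode has none).

## The retention model

Comparative slaughter measures retention as a whole-body balance: fish
pooled at stocking give the initial body nutrient concentration, which is
scaled to each aquarium's stocked biomass (proportional scaling is the only
dimension-consistent rule when all aquaria are stocked from one batch); fish
slaughtered at the end give the final mass. Then

$$\mathrm{NutrPV}\,\% = 100\,\frac{\mathrm{final} - \mathrm{initial}}
  {\mathrm{consumed}}$$

for nitrogen (NPV) and lipid (LPV). Negative values -- net mobilization --
are legitimate and preserved. NPV may be computed directly on a crude-
protein basis: the CP-to-N factor 6.25 cancels in the ingredient-level
ratio because $D_{ref}$ and $D_{ing}$ scale identically.

Treatments are also expressed *relative* to the reference diet of their run
(`relative_to_reference()`, reference mean = 100%), the scale on which the
same ingredient can be compared across runs (e.g. with and without dietary
acidification).

## The statistics workflow

`compare_groups()` reproduces the branching inference customary for
replicated aquarium trials and records every decision:

1. Shapiro--Wilk normality per group (default; pooled-residual testing is
   available). The nonparametric branch fires if *any* group fails. Groups
   of n < 3 cannot be assessed and are treated as passing, with the gap
   logged. A zero-variance group forces the nonparametric branch with a
   warning.
2. Homogeneity: the variance F-test for two groups, Levene's test
   (`car::leveneTest`, mean-centered -- the classic Levene statistic) for
   more.
3. Two groups: Student's t (normal, homogeneous), Welch's t (normal,
   heterogeneous), Wilcoxon rank-sum otherwise. More groups: one-way ANOVA
   with Tukey's HSD; Welch's ANOVA with Bonferroni-adjusted pairwise Welch
   t-tests when variances are heterogeneous (a case the conventional
   workflow leaves unstated); Kruskal--Wallis with Dunn's test under
   non-normality. Dunn's test uses a tie-corrected normal statistic with
   Bonferroni adjustment by default (no adjustment is prescribed by
   convention; the choice is configurable and logged).
4. Pairwise p-values are rendered as a compact letter display
   (insert-and-absorb): two groups share no letter exactly when they differ
   at `alpha`. The display is verified in the test suite against every
   significance pattern for up to five groups and a large sample for six.

The aquarium-as-random-effect screening sometimes applied to such designs is
deliberately out of scope; the workflow is fixed-effects, which is the
appropriate reduction when no aquarium effect is present.

## The synthetic-trial generator

`simulate_trial()` inverts both estimators to produce data with known truth:

* **Feces** (`simulate_feces()`): the feces DM is assembled from
  indigestible residues, $(1-\mathrm{ADC}_i/100)\,C_i$ per nutrient, plus
  the inorganic carry-over (ash and marker), renormalized to 1000 g/kg.
  Crude fiber is implicitly part of the OM residue and treated as
  indigestible. Because marker and nutrient renormalize by the same factor,
  the construction is an exact inverse of `diet_adc()` at cv = 0 -- the test
  suite demands agreement to 10^-9^ percent. True diet-level ADC vectors
  must be physically realizable (each in [0, 100]; protein + lipid residues
  within the OM residue); ingredient-level truths outside 0--100% still
  arise through mixing and back-calculation.
* **Growth** (`simulate_growth()`): final body nutrient = initial +
  retained share of intake, exactly invertible at cv = 0.
* **Diet-level truths** follow additive nutrient mixing of the reference
  and ingredient truths, which makes the substitution back-calculation
  exact -- the additivity assumption of the design is built into the
  generator, so recovery failures isolate estimator defects, not model
  mismatch.

Noise is multiplicative Gaussian per analyte per replicate, parameterized
by a CV, because proximate assays report relative precision; an additive
mode is available, and a separate `biological_cv` component (default 0)
lets between-aquarium variation be attributed explicitly. The default
`cv = 0.02` is a fixture choice calibrated so that simulated diet-level ADC
SDs span the magnitudes tabulated in replicated trials (roughly 0.01--2.5
percentage points); it is not a measured assay CV. Defaults mirror the
emulated design: 70:30 substitution, TiO~2~ at 5 g/kg DM, 4 replicate
aquaria per diet, 15 fish per aquarium, 56-day schedule at 2% of stocked
biomass per day. Intake is deterministic (no growth-compounded ration, no
refusals, no mortality); the generator emulates the measurement process,
not husbandry. What passing recovery tests show is therefore that the
estimators are correct and well-calibrated *under the design's own
assumptions* -- they cannot show that additivity, marker homogeneity or
settling-collection representativeness hold in a real tank.

```{r example}
ref <- proximate_profile(dry_matter = 909, crude_protein = 434,
                         crude_lipid = 174, crude_fiber = 88,
                         crude_ash = 32, gross_energy = 23.4)
ings <- list(poultry_meal = proximate_profile(
  dry_matter = 938, crude_protein = 696, crude_lipid = 118,
  crude_ash = 143))
p <- trial_parameters(
  ref, ings,
  ingredient_adc = rbind(poultry_meal = c(CP = 89, CL = 98, OM = 81)),
  ingredient_nutrpv = rbind(poultry_meal = c(N = 46, CL = 58)),
  cv = 0.02, seed = 42)
a <- analyze_trial(simulate_trial(p))
summary(a)
```

## Numerical and reporting choices

* Internal computation is at full double precision; report formatting
  rounds half away from zero (`round_half_up()`), matching how trial
  tables print 87.5 as 88.
* Back-calculated coefficients recomputed from *integer-rounded* published
  diet means carry a documented agreement band of ±1.5 percentage points
  (`reproduce_worked_examples()`); by-difference composition identities are
  exact.
* Coefficients outside 0--100% are never clamped; they are reported
  verbatim and logged as warnings in the analysis object.
* Division-domain degeneracies (zero feces marker, nutrient-free diet or
  ingredient, zero reference mean) raise classed errors rather than
  returning infinities.
* Seeded simulation uses R's default RNG stream; one integer seed
  reproduces a trial bit-identically.

## Problem sizes in the validation suite

The test suite validates the estimators at the emulated design size (4
replicate aquaria, 15 fish): exact inversion at cv = 0; unbiasedness of the
recovered ingredient coefficients over 200 simulated trials at cv = 0.02
(mean error below 0.5 percentage points); and the type-I error of the
statistics workflow over 10,000 null data sets of 4 normal groups with
n = 4, which must stay inside 0.05 ± 0.01 at alpha = 0.05. These sizes keep
the full suite to a few minutes while leaving Monte-Carlo error well below
the asserted bounds.

## Known limitations

* Energy and phosphorus digestibility are not modeled (no marker-based
  energy ADC), nor are stripping-method corrections.
* The additivity assumption is not testable from a single substitution
  level; trials with graded inclusion would be needed.
* The generator does not simulate water quality, mortality, refusals, or
  amino-acid-level growth; its biological realism is limited to the
  measurement chain.
* Mixed-effects modelling of aquarium effects is out of scope.
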