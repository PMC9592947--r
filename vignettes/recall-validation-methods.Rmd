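---
title: "Validating 24-hour recall against weighed food records: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating 24-hour recall against weighed food records: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallval)
```

## The problem

A 24-hour dietary recall (24HR) asks a respondent to reconstruct everything
they ate the previous day; a weighed food record (WFR) weighs it as it
happens. The WFR is treated as the benchmark, and the question is how
accurately each of two interviewer-administered 24HR modalities — one per
study arm, each respondent contributing one WFR day and one 24HR day —
reproduces it, at the group level (do mean intakes agree?), at the
individual level (how many respondents land near their own benchmark?), and
per unit cost.

`recallval` implements that comparison end to end: reference-data linkage,
intake computation, quality control, the statistical battery, and the
costing framework, together with a synthetic-data generator whose known
error structure lets every stage be checked by parameter recovery.

## From coded records to intakes

Each consumed item is a food, a standard recipe, or a non-standard recipe
described inline. Quantities are either direct grams or a portion-size
estimation method (PSEM) reference — photo, proxy weight, or standard unit
— resolved as `grams_per_unit × n_units`, with fractional units allowed
("half a bottle").

A recipe's nutrient density per 100 g prepared is

$$d_k = \frac{100}{W}\sum_i g_i \, c_{ik}/100,$$

with ingredient grams $g_i$, compositions $c_{ik}$ per 100 g and total
prepared weight $W$. Nutrients are conserved: no retention or yield factors
are applied (the reference data carries none), so the dish's total nutrient
content equals the sum over raw ingredients — a property the tests verify on
randomly generated recipes. Non-standard recipes go through exactly the same
formula using their inline ingredient lists.

Missing food-composition cells are *missing, not zero*: they contribute 0 to
any sum they enter while raising a per-nutrient flag that propagates from
food to recipe to daily total, and they are reported separately as FCT
completeness (the percentage of consumed foods with a non-missing value per
nutrient). This mirrors the reporting convention of validation studies,
which publish completeness alongside results rather than imputing.

A mixed dish's entire energy is attributed to the GIFT food group of the
dish itself, not disaggregated to its ingredients; the recipe table
therefore carries a `gift_group` column (a deliberate extension of the
minimal schema), and a dish without one — always the case for non-standard
recipes — defaults to its dominant-energy ingredient's group.

## Quality control

Days with energy below 500 kcal (2092 kJ) or above 5000 kcal (20920 kJ)
are flagged as implausible; 24HR days differing from their WFR partner by
more than 1000 kcal are flagged for review. All three comparisons are
*strict* inequalities — a day at exactly 500 kcal passes — read literally
from the stated convention. The default policy excludes a respondent only
when the *WFR* day is implausible and retains (but logs) everything else;
whether the plausibility bounds also apply to 24HR days is not specified by
the convention, so flags are raised for both sources but only WFR flags
exclude. Both the triggering kinds and source are configurable in
`qc_policy()`.

Skewness correction uses the natural log whenever a vector is strictly
positive and the cube root otherwise (zeros occur, e.g. zero vitamin C
days). The choice is zero-driven rather than normality-test-driven because
only the *family* of transforms is conventionally fixed, not a selection
rule; both transforms are strictly increasing, so ranks and band
memberships are unaffected.

## The statistical battery

**Equivalence (TOST).** With paired log differences
$d_i = \ln(\text{24HR}_i) - \ln(\text{WFR}_i)$ and a 10% bound, the
equivalence margin is $\theta = \ln(1.1)$ and the test rejects
non-equivalence when both one-sided t-tests do; the reported p is
$\max(p_1, p_2)$ and $p < 0.05$ declares the geometric means equivalent
within ±10%. The bound is *symmetric on the log scale*, $\pm\ln(1.1)$
around zero: the asymmetric alternative $(\ln 0.9, \ln 1.1)$ would treat
over- and under-estimation differently and is rejected for symmetry. Pairs
with a zero on either side cannot enter a log-scale test; they are excluded
from that nutrient's test and tallied (`n_zero_excluded`). Degenerate
inputs (all differences identical) short-circuit to an exact decision
($|\bar d|$ vs $\theta$, p reported as 0 or 1).

**Bland–Altman.** Differences are `24HR − WFR` (positive bias =
overestimation); limits of agreement are bias ± 1.96 sd.

**Difference-in-differences.** Reported mean differences use the WFR as
minuend. The modality contrast — mean(WFR − 24HR) in one arm minus the
other — is fitted as the source × arm interaction of a random-intercept
mixed model (`nlme::lme`, REML) on the stacked two-row-per-respondent data,
on the *untransformed* scale, since the quantity of interest is a
difference in kcal or grams. On balanced complete pairs the interaction
t-test coincides with a pooled two-sample t-test on the per-respondent
differences (containment df = N − 2); the tests exploit this closed-form
equivalence as an independent oracle at tolerance 1e-6. When every
respondent has an identical difference (noise-free data) the model is
degenerate and the contrast is returned exactly instead.

**Error bands.** Percentage error is $100(\text{24HR}_i -
\text{WFR}_i)/\text{WFR}_i$; bands are cumulative and *boundary-inclusive*
(an error of exactly ±10% counts as within ±10%), with respondents beyond
±50% split into over- and under-estimators, so
within±50 + over + under = 100 exactly.

**Food groups.** Per GIFT group, median (IQR) energy shares under each
method and a paired *signed-rank* test on within-respondent share
differences. The test is paired by design, hence signed-rank (the rank-sum
label sometimes attached to this comparison does not fit paired groups);
zero differences are dropped, the exact null distribution is used for ≤ 25
nonzero untied pairs and the normal approximation (continuity-corrected)
otherwise. Groups consumed by fewer than 10% of respondents under either
method keep their medians but have the p-value suppressed — small consumer
counts make the test unreliable.

**Sample size.** The design-stage Fisher-z calculation
$n = \lceil ((z_{1-\alpha/2} + z_{\text{pow}})/q)^2 + 3 \rceil$,
$q = \operatorname{atanh}\rho_1 - \operatorname{atanh}\rho_0$, gives 104
per arm for $\rho_0 = 0.6 \to \rho_1 = 0.75$ at 80% power. Non-response
inflation is a configurable multiplier, default 0.125 so that the inflated
n is 117; note that "approximately 12% non-response" is ambiguous between
$104 \times 1.125 = 117$ and $104 / 0.88 \approx 118.2$ — the
multiplicative reading is used. The formula is validated in the tests by
brute-force simulation (bivariate normal, $\rho = 0.75$, ≥ 10,000
replicates), which attains ≥ 79% empirical power at n = 104.

No multiple-testing correction is applied anywhere: each nutrient's test
is reported as-is, matching standard practice for these validation tables.

## Costing and cost-effectiveness

Ledgers are activity-based (reference-data preparation, survey preparation,
training, execution, data entry, cleaning/processing) with time rows in
person-days valued at wages (respondent time at the minimum wage) and
non-time rows; `total = time + non-time` holds by construction. Accuracy is
computed on *group means* — the ratio of the 24HR arm mean to the WFR mean,
`error = 100·|1 − ratio|` capped at 100, `accuracy = 100 − error` — not as
a mean of individual errors, read literally from the "ratio of the average
estimate" definition; the cap keeps cost-per-point ratios defined. The
composite nutrient measure is the plain mean of the ten per-nutrient
accuracies. Borrowing scenarios scale only the CAPI modality's
reference-data-preparation quantities by (1 − fraction), leave PAPI
untouched and hold accuracy constant, so CAPI ratios improve weakly and
monotonically in the borrowed fraction.

## What the generator emulates — and what it does not

`sim_config()` defaults are the emulated study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_per_arm` | 116 | the emulated study's arm size |
| `menu_size` | 40 foods | small rural food environment |
| `mean_items_per_day` | 8 | staple-based diet, few distinct items |
| `omission_prob` | 0.10 | typical recall omission rates |
| `intrusion_prob` | 0.10 | matched to omissions |
| `portion_bias` | 1.05 | mild systematic portion overestimation |
| `portion_cv` | 0.30 | individual portion-recall noise |
| `recipe_swap_prob` | 0.05 | near-neighbour recipe misclassification |
| `outlier_prob` | 0.03 | ~3.5% of field respondents were excluded |
| `psem_fraction` | 0.30 | share of recalls via portion-size methods |

The 24HR day is generated *conditionally on* the WFR day — the design is
paired, and so are all the statistics. Portion noise is
`portion_bias × exp(N(−cv²/2, cv))`: the lognormal term has mean exactly 1,
so `portion_bias` alone controls the expected gram ratio and group-level
gram accuracy recovers `100 − 100·|1 − b|` exactly at cv = 0 and up to
Monte-Carlo error otherwise. Days follow a staple pattern (2–4 cereal
servings plus weighted non-cereal items), yielding ~2,000–2,300 kcal/d with
roughly 80% of energy from cereals, as in a rural West African diet; group
sampling weights are normalised by menu counts so the dietary mix does not
depend on menu composition. Outliers are injected by rescaling a
respondent's whole WFR day beyond the 500/5000 kcal bounds, exercising the
exclusion path. Arms alternate deterministically, emulating balanced
randomisation. PSEM re-expression reproduces grams exactly (fractional
units), so it exercises the conversion path without adding error — which is
why `zero_noise_config()` also sets `psem_fraction = 0` to make the 24HR
records literally identical to the WFR records.

Not modelled: within-person day-to-day variation (each respondent has one
day per method, so "usual intake" is out of reach by design), seasonality,
intra-household allocation, correlated omission of specific food types,
interviewer effects, and energy-adjustment of nutrients. Passing the
recovery tests therefore shows the *pipeline arithmetic and inference* are
correct under a plausible error structure — not that any real 24HR
instrument achieves these accuracies.

## Numerical conventions and problem sizes

Energy is stored in kcal with kJ derived at 4.184 kJ/kcal. Keys are
case-sensitive strings; the pen-and-paper sentinel codes `9999`/`99 999`
("not in the food book") are rejected at load, since they must be resolved
to real codes upstream. Oracle agreement is asserted at 1e-9 (TOST vs
closed-form t CDF) and 1e-6 (mixed-model DiD vs pooled t); band identities
at 1e-9. The test suite runs the detection experiment at 111 respondents
per arm over 200 seeds (a 30% portion bias must be declared non-equivalent
for energy in > 95% of runs) and the power simulation at 10,000 replicates;
the end-to-end worked example uses the full 116-per-arm default. These
sizes keep the whole suite at a few minutes on a single core while leaving
Monte-Carlo error well below the margins being tested.

## Known limitations

* Reference data carries no retention/yield factors or edible-portion
  coefficients; recipes conserve raw-ingredient nutrients.
* The dish-level GIFT attribution convention makes food-group shares
  sensitive to how mixed dishes are classified; an ingredient-level
  disaggregation would change Table-4-style results.
* The mixed-model DiD equals the pooled t only on balanced complete pairs;
  with missing days the model is still valid but the closed-form oracle no
  longer applies.
* The toy cost ledger is illustrative: real ledgers (currency conversions,
  inflation adjustment) must be prepared upstream in a single currency.
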