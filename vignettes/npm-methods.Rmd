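---
title: "Profiling CPCF purées and meals: model, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling CPCF purées and meals: model, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcfnpm)
```

## The problem and the model

Commercially produced complementary foods (CPCF) — packaged purées and
ready-to-eat meals marketed for children aged 6–36 months — are benchmarked
in market surveys against nutrient and promotion profile models (NPMs):
rule sets that decide from label information whether a product is suitable
for promotion for this age group. `cpcfnpm` implements such an adapted NPM
for the purées/meals category. The unit of analysis is one unique product
label; everything the model needs is read off the package: the ordered
ingredient list (with optional percentages by weight), the nutrient
declaration panel, the product name, the texture, and a set of coded label
features (age statements, claims, spout messages, breastfeeding messaging).

The pipeline has four stages, each an exported function:

1. **Categorization** (`categorize()`) — one of nine subcategories from
   ingredient composition, product name and texture.
2. **Nutrient assessment** (`assess_nutrients()`) — six requirements with
   per-subcategory thresholds, plus the high-sugar front-of-pack tri-state.
3. **Labelling assessment** (`assess_labelling()`) — seventeen requirements
   in five groups with per-category applicability.
4. **Aggregation** (`summarize_market()`) — per-subcategory and overall
   pass proportions, high-sugar shares among sugar-declaring products, and
   median [IQR] nutrient summaries.

## Categorization: precedence and the "largest ingredient" convention

The nine subcategory definitions are prose, and are mutually exclusive only
under an ordering. The implemented precedence runs from most to least
specific predicate:

1. Texture splits chunky meals from purées.
2. Chunky products split on whether meat or fish is the *first food named*
   in the product name ("Salmon and pea risotto" → meat/fish chunky meal;
   anything else → vegetable chunky meal, the residual chunky class).
3. Puréed products containing meat or fish are meals, split the same way on
   the first-named food ("Chicken and potato pie" vs "Hearty shepherd's
   pie", which names no lexicon food at all).
4. Cheese named front-of-pack (no meat/fish) → puréed meal with cheese.
5. Dairy the largest ingredient class → dairy-based dessert.
6. The vegetable-only composition test: vegetables/legumes plus water
   ≥ 95 % of stated weight, zero fruit, ≤ 5 % everything else.
7. Vegetables/legumes/cereals largest with > 5 % cereal or pseudocereal →
   vegetable purée with cereals.
8. Fruit largest → fruit purée.

A puréed product matching none of these is an error naming the failed
predicates — on real data that is a prompt to extend the ingredient
lexicon, not a silent residual class.

Two conventions fill gaps the definitions leave open. *Largest ingredient*
compares percentages **summed by ingredient class** (so yogurt 40 % beats
apple 35 % + oats 25 % on the dairy-vs-fruit and dairy-vs-grain
comparisons); the prose states the "greater than the sum" reading only for
the dairy definition, and we apply the summed comparison uniformly rather
than guess different rules per class. When any percentage is unstated,
*largest* falls back to the first-listed ingredient (ingredient lists are
declared in descending weight), and the 95 %/5 % composition tests evaluate
false — conservative, and faithful to what a label-only assessment can
know.

All term matching is case-insensitive longest-phrase matching against an
editable YAML lexicon (`load_ingredient_lexicon()`); "whole milk yogurt" is
dairy even though "milk" alone would match too. Unmatched ingredients are
class `other` and count against the vegetable-only composition test.

## The nutrient rules

Thresholds ship as a versioned YAML profile (`load_profile()`), one block
per subcategory; an alternative profile supports sensitivity analyses.

* **Added sugar**: presence/absence from the ingredient list against a
  sweetener lexicon with four classes — mono-/disaccharides,
  syrups/nectars/honey, fruit juice or juice concentrate/powder, and
  non-sugar sweeteners. Lemon and lime juice are excluded from the juice
  rule, and the exclusion overrides any juice-pattern match. Whole fruit
  and fruit purée are *not* added sugars here; fruit is governed by the
  separate fruit-content requirement. Grams of added sugar are never
  quantified — the model is presence-based.
* **Fruit content**: ≤ 5 % summed fruit weight (dairy desserts and meals),
  or no added fruit at all (vegetable purées). Fruit present without a
  stated percentage fails the 5 % rule as "undeclared".
* **Energy density**: ≥ 60 kcal/100 g, not applicable to chunky meals. A
  kJ declaration converts at 4.184 kJ/kcal (the profile text does not state
  a factor; this is the thermochemical standard).
* **Sodium**: strictly below the limit on *both* scales, mg/100 kcal and
  mg/100 g (50 mg, or 100 mg where cheese is named front-of-pack in the
  subcategories that permit the relaxation; cheese-in-name is detected with
  the cheese lexicon). A salt declaration converts as salt g × 1000 / 2.5;
  when both sodium and salt are declared, sodium wins and salt is only the
  fallback.
* **Total fat**: ≤ 4.5 or ≤ 6 g/100 kcal by subcategory.
* **Protein** (meal classes only): ≥ 3 or ≥ 4 g/100 kcal; where a meat or
  fish source is named in the product name, the summed weight of
  ingredients of that class must also reach 8 % or 10 % of the product. A
  named source without stated percentages fails as undeclared; a product
  naming no protein source is assessed on protein density alone.

Comparison directions follow the printed operators verbatim: ties pass at
`≥`/`≤` thresholds and fail at `<` thresholds. The boundary behaviour is
pinned by tests at every threshold.

**Missing declarations fail.** Any product lacking the information needed
for an applicable requirement fails that requirement with reason
`undeclared` — including indirect cases (sodium declared but energy not:
the per-100 kcal side cannot be computed). This mirrors how label surveys
treat non-declaration as non-compliance. Booleans absent from input remain
unknown (`NA`) rather than silently false for the same reason.

**High sugar.** The percentage of energy from total sugar uses the Atwater
carbohydrate factor (4 kcal/g; the standard general factors 4/4/9 are
assumed, as the profile invokes "the Atwater system" without printing
factors). At or above the subcategory threshold (40/30/30/20/15 % of
energy) the product requires a front-of-pack warning. The state is
tri-valued — `warning_required`, `not_required`, `sugar_undeclared` — and
never enters the pass/fail verdict; market shares are reported among
sugar-declaring products only. By default the *declared* energy is used;
`energy_source = "atwater"` recomputes energy from declared macros as a
sensitivity option, but since labels in this schema declare no total
carbohydrate, that recomputed energy is a lower bound and the option should
be read accordingly.

## The labelling rules

The seventeen requirements are grouped: breastfeeding protection (5),
claims (5), name/ingredient-list clarity (4), spout messages (2), age
restriction (1). Applicability is structural: the fruit-percentage
requirement applies only to fruit-containing products, the water-percentage
requirement only when water is an ingredient, the protein-percentage
requirement only to the four meat-fish/chunky meal classes, spout messages
only to puréed products with a spout, and the 12-month maximum-age
statement only to puréed classes. Inapplicable requirements are excluded
from group and overall verdicts entirely.

Claims are classified into five classes by configurable regular-expression
patterns tried in fixed order (disease risk reduction, nutrient function,
nutrient content, non-permitted compositional, else "other"); the order
resolves texts that would match several classes. A record may also carry an
explicit class, which is honoured without reclassification. Because every
claim has exactly one class, a product passes all five claims requirements
exactly when it carries no claims at all. Two label features are
deliberately input booleans rather than inferred: "marketed as suitable
under 6 months" (coded from imagery, outside a text pipeline's reach) and
"recommends bottle feeding".

## Aggregation conventions

Every percentage in the report tables is
`round_half_up(100 * n / denominator, 1)` with the denominator recorded
explicitly; half-up matches the printed style of survey tables
(`base::round()`'s round-to-even would disagree on exact ties), and raw
fractions are retained in the JSON output. Inapplicable products leave a
requirement's denominator; high-sugar shares exclude sugar-undeclared
products; nutrient summaries cover declaring products only. Quartiles use
linear interpolation between order statistics (`stats::quantile()` type 7,
the R default), one documented convention applied everywhere. No
inferential statistics are computed — the reports are descriptive, like the
surveys they mirror.

## The synthetic market generator

`generate_market()` exists because survey label datasets are not
redistributable. It emulates the study conditions of a 459-product
Southeast Asian market:

* the subcategory mix (42/245/25/22/9/51/30/34/1 of 459);
* per-subcategory nutrient values drawn lognormal with the median anchored
  to the published per-100 g medians and sigma fitted to the published IQR
  (`sigma = log(q3/q1) / (2 * qnorm(0.75))`) — strictly positive and
  right-skewed, as label quantities are. Energy is not summarized in the
  published tables, so its anchors are this package's choice, set once so
  that each subcategory's energy-density pass rate is plausible (vegetable
  purées mostly below 60 kcal/100 g, dairy desserts mostly above);
* violation prevalences per requirement (defaults from the published
  overall failure proportions) and declaration missingness (defaults from
  the published "n declaring" counts).

Ground truth is exact by construction: the Bernoulli draw decides each
product's intent, and the label is then built to realize that intent with
certainty — names from per-subcategory templates so first-named-food logic
is exercised, percentages summing to 100, injected sweetener ingredients,
fruit at 8 % (violation) or ≤ 5 % (compliant), named protein at or below
the weight floor, nutrient values rejection-sampled inside or outside the
admissible region (with a deterministic fallback safely away from the
boundary). One constraint is structural: a fruit ingredient would void the
vegetable-only purée definition itself, so fruit-content violations are
never injected there and a config requesting them is rejected as
infeasible. All randomness flows from a single seeded stream, so a seed
reproduces the market byte for byte.

What the generator does **not** emulate: real ingredient diversity and
multilingual label text (a fixed template vocabulary is used), unstated
ingredient percentages (always stated; the unstated-percentage code paths
are covered by unit tests instead), correlations between nutrients beyond
those induced by the thresholds, per-serving-only declarations, and
data-entry noise. Passing the ground-truth recovery and oracle-equivalence
tests therefore demonstrates that the rule engine implements the stated
rules exactly — not that the lexicons would cover any particular real
market's vocabulary; on real data the lexicons are the component expected
to need extension.

## Verification strategy and problem sizes

Three independent routes check the implementation:

1. **Reference arithmetic** — the packaged summary counts of the reference
   market (the only public artefact of the survey) are pushed through the
   same rounding/aggregation arithmetic and must reproduce every printed
   overall proportion exactly (`verify_reference_arithmetic()`).
2. **Ground-truth recovery** — a seeded 2,000-product market must be
   recovered exactly, requirement by requirement, and injected prevalences
   must land within three binomial standard errors.
3. **Oracle equivalence** — a straight-line re-implementation of the rules
   in the test suite (own vocabulary, own threshold table, no shared code)
   must agree with `assess_nutrients()` on 1,000 generated products.

Test problem sizes (2,000 for recovery, 1,000 for the oracle, 5,000
fruit purées for the distribution anchor, 64 = 2^6 exhaustive verdict
patterns) were chosen as the package's own trade-off between statistical
resolution and a test suite that runs in a couple of minutes on one CPU.

## Known limitations

* Label text is assumed already extracted and in English; OCR, translation
  and photo handling are out of scope.
* The lexicons are seeded from the profile's worked examples plus common
  label vocabulary; they are starting points, editable per market.
* The model covers the purées/meals category only; dry cereals, snacks,
  drinks and other CPCF categories have different requirement sets.
* Micronutrients (iron, zinc) are not part of the six requirements and are
  not assessed.
* Whether the original survey compared summed or single-ingredient fruit
  weight for the fruit-purée "largest ingredient" test is not recoverable
  from its report; the summed-by-class convention used here is documented
  above and applied uniformly.
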