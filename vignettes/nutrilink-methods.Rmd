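---
title: "Methods: nutrient-threshold and fuzzy-name linkage of branded foods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient-threshold and fuzzy-name linkage of branded foods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrilink)
```

## The linkage problem

A branded-product table carries, per product, a marketing-style name
(subcategory plus brand), energy, and seven nutrients — carbohydrate,
protein, total fat, saturated fat, sugar, fiber (g per 100 g) and sodium
(mg per 100 g; tables reporting salt instead are converted at 393 mg
sodium per gram of salt). A reference food-composition table carries
generic food descriptions with the same nutrient fields. The task is to
propose, per product, a short list of nutritionally and nominally
plausible reference foods for expert adjudication.

Two structural assumptions underlie everything downstream:

* **Common basis.** All profiles are interpreted per a common reference
  mass (100 g or 100 mL). The package never rescales; comparing profiles
  directly is only meaningful if the inputs already share a basis.
* **Shared blocking key.** Both tables carry a food-category label from
  a common scheme. Candidate generation is restricted to foods sharing
  the product's group. This is classic record-linkage blocking: it cuts
  the comparison space and suppresses spurious cross-category matches,
  at the cost of missing matches for heterogeneous categories (a known
  limitation; `blocking = FALSE` disables it).

## Nutrient distance

Nutrient contents are compared as **shares of energy**:
$\mathrm{share}_X = 100 \cdot g_X f_X / E$ with kcal-per-gram factors
$f$. The distance for a caloric nutrient is the absolute difference of
shares in percentage points; for sodium (no caloric share) it is the
absolute relative difference with the product in the denominator,
applied only when the product's sodium is non-zero. Shares are robust
across caloric density: an absolute gram difference treats a 15 kcal
drink and a 500 kcal snack incomparably, and relative gram differences
explode for near-zero contents.

The difference formulas are taken as magnitudes even though the printed
one-sided forms are signed: thresholds are stated as maxima, and a
signed comparison would wave through arbitrarily discrepant candidates
on one side.

The energy factors are configurable because share-of-calories
computations presuppose them but no single convention is universal. The
defaults are Atwater-style — carbohydrate 4, protein 4, total fat 9,
saturated fat 9, sugar 4, fiber 2 kcal/g — a deliberate reconstruction:
saturated fat and sugar inherit their parent macronutrient's factor, and
fiber gets the conventional 2 kcal/g fermentation value. Any analysis
that needs a different convention passes its own `energy_factors()`.

## The filter cascade and its parameters

One *sift* applies, in fixed order: the macro-share filter
(carbohydrate, protein, total fat; all three simultaneously below
`macro_threshold`), the secondary-share filter (fiber, saturated fat,
sugar below `secondary_threshold`), the sodium filter
(`sodium_threshold`, a fraction), an optional minimum fuzzy score, and
an optional fuzzy-match optimization keeping only the top scorer(s).
Filters 1–4 commute set-theoretically; filter 5 does not, which is why
the order is normative and fixed.

Comparison conventions, both switchable and both logged in the
candidate output:

* Nutrient thresholds are **strict** (`<`): "below a threshold" read
  literally. A difference exactly at the threshold is rejected.
* The minimum fuzzy score is **inclusive** (`>=`): a floor of 50 admits
  a score of 50. "Exceeds" could be read strictly; inclusive is chosen
  so a printed integer floor admits its own value, and
  `fuzzy_inclusive = FALSE` restores the strict reading.
* `Inf` (config spelling `"inf"`) disables a threshold. A disabled
  filter passes missing values through; a *binding* filter fails any
  candidate missing the field it needs — the conservative choice, since
  silent passes would inflate suggestion sets.

The shipped presets (`first` 20/10/0.5 with fuzzy optimization;
`first_plus` 60/60/0.5 with fuzzy floor 50 and no optimization; `second`
40/40/0.5; `third` all-∞ with optimization) encode a
tight-to-loose progression in which the tight pass minimizes nutritional
error and the later passes trade specificity for coverage.

## Fuzzy string scoring

The score is the **partial token sort ratio** on a 0–100 integer scale.
Both strings are normalized (lowercased; every non-alphanumeric
character becomes a space; whitespace collapsed), tokens are sorted in
plain byte order (no locale collation, for determinism), and the shorter
string is scored against every same-length window of the longer one
(plus the full string), keeping the maximum Ratcliff/Obershelp ratio
$100 \cdot 2M/(|a|+|b|)$, where $M$ is the total length of matching
blocks under the recursive longest-common-block decomposition.

Numerical and degenerate-input choices:

* **Exhaustive windows.** Mainstream libraries use anchor heuristics
  that differ across versions; enumerating every window makes the score
  an exact maximum and pins the semantics. Food names are short, so the
  cost is irrelevant.
* **Rounding** is half-up to the nearest integer, not banker's
  rounding, so scores are stable across platforms.
* **Empty strings:** both empty scores 100, exactly one empty scores 0
  (the "no similarity" endpoint); totality matters because subcategory
  strings can normalize to empty.
* **Symmetry tie-break.** The greedy matching-block decomposition is
  directional, and equal-length pairs could score asymmetrically in
  rare tie cases; arguments are therefore put in a canonical order
  (length, then byte order) before scoring, making the score symmetric
  by construction.

The normalization convention itself is a reconstruction (upstream
descriptions of the scheme do not specify pre-processing); it follows
the cited scheme's usual practice.

## Scheduling across sifts

`run_schedule()` implements the routing plan. Ineligible products —
zero energy (the share filters divide by energy) or a missing required
field — go directly to manual matching. "Required" is derived from the
schedule: a nutrient is required if any sift in the schedule binds a
finite threshold over it, which makes the eligibility rule testable
instead of an enumeration frozen in code. Eligible products run the
initial sift; zero-match products walk the zero-match chain until they
gain a suggestion or the chain ends; single-match products *of the
initial sift only* are re-run through the augmentation sift, whose
output **replaces** the original suggestion even when empty.
Replacement (not union) is the normative mode; `retain_fallback` is
available but changes the semantics: with it, no product can lose its
suggestion to the augmentation sift's fuzzy floor. Products that gain
level ≥ 1 in the zero-match chain are final — they never enter
augmentation, which exists to widen *tight* single matches, not to
second-guess the loose sifts.

Every sift records a flow row with `entered = out_zero + out_one +
out_many`; the conservation identity and the exactly-once partition of
products across final levels (plus direct-to-manual) are asserted on
every pipeline test.

Candidates are ranked ascending by the **maximal nutritional
difference**: the largest of the six share differences and, when
applicable, the sodium relative difference × 100. Mixing percentage
points with relative percent on one scale is the most literal reading
of "take the largest of these differences"; it is ambiguous enough that
`sodium_in_ranking = FALSE` excludes sodium from the ranking (the
filters are unaffected). Ties in the ranking break by food id in byte
order so reports are deterministic.

## Adjudication statistics

The expert stages are bookkeeping only — no rater behavior is modeled.
Agreement rates are plain percentages, as is standard for this style of
two-rater validation (chance-corrected coefficients can be computed from
the same decision logs but are not part of the reported tables):

* *selection agreement*: identical algorithm-stage verdicts (same food,
  or both refusals);
* *manual-needed agreement*: agreement on the refuse-vs-select
  dichotomy;
* *manual selection agreement*: identical manual-stage verdicts, with
  "unmatchable" counting as a verdict.

Identical verdicts imply dichotomy agreement, so manual-needed ≥
selection holds on every possible log — the package proves this
property-style over random logs. Decision logs accept later
`resolution_round` rows to record tie-breaking, which are excluded from
the two-rater rates. Report percentages are rounded half-up to one
decimal.

Accuracy tables follow the two denominators that matter: *algorithm
accuracy* (products whose adjudicated pick is among the suggestions,
over products with at least one suggestion, by category and match
level) and *process accuracy* (products matched by either stage, over
all products). The subcategory → category rollup is user-supplied (an
example mapping ships in `inst/extdata/`) because fine marketing
subcategories are too many for interpretable tables and the raw
top-level categories too few.

`threshold_sweep()` reproduces the threshold-selection diagnostic:
counts of nutrient-filter survivors per product (fuzzy filters off,
since they would mask the thresholds' effect), summarized as boxplot
percentiles of √count across a threshold grid. With fuzzy optimization
off the per-product counts are monotone in every threshold, which the
suite asserts.

## The synthetic benchmark

`generate_linkage()` produces both tables plus the ground truth. Scale
defaults — 10 blocking groups, 20 reference foods and 10 products per
group — keep a full pipeline run in seconds while preserving the
structural features that matter: category-clustered nutrient profiles,
pool sizes comparable to a product's realistic candidate count, and
name vocabularies private to each group. Fractions of degenerate
products default to roughly the rates a curated branded-product table
exhibits: 2.5% with no true counterpart, 3% zero-energy, 3% with a
missing nutrient.

Reference foods draw log-normal nutrient profiles around per-group
archetypes; energy is *derived* from the macronutrients as
$E = 4C + 4P + 9F$. Matched products are clones of a reference food
with each nutrient multiplied by an independent log-uniform factor in
$[1/(1+p),\, 1+p]$, energy re-derived from the perturbed macros. This
makes the key guarantee analytic rather than empirical: every share's
perturbed-to-true ratio lies in $[(1+p)^{-2}, (1+p)^2]$, shares are
bounded by 100 (50 for fiber), so with $p = 0.03$ every share deviation
is below $100\,(1.03^2 - 1) \approx 6.1$ pp — strictly inside the 10 pp
secondary threshold — and the sodium deviation below 0.03. Hence
*suggestion recall is exactly 1* under the tight thresholds with fuzzy
filters off, and the suite asserts equality, not approximation. The
default amplitude is $p = 0.10$: large enough that the tight sift loses
some true foods (exercising the multi-sift routing), small enough that
the schedule recovers most of them.

Product names are the source food's tokens passed through token-level
corruption — shuffle (which the token-sorted score ignores by design),
drop, insert — plus an appended brand token (which the partial/windowed
score tolerates). Setting all corruption probabilities and the brand
probability to zero yields products identical to their source foods,
the configuration under which the full default schedule must achieve
recall 1 (identity names score 100, passing the augmentation sift's
floor of 50).

What the generator does **not** emulate: real marketing vocabulary and
its abbreviations, correlated nutrient reporting errors, rounded label
values, within-category brand clusters, or heterogeneous categories
whose products straddle blocking groups. Passing tests therefore
demonstrate the algorithm's mechanics and its recovery envelope, not
field accuracy on any real database pair.

## Problem sizes and runtime

The test suite runs the oracle-equivalence suites at 1,000 random sift
instances (≤ 20 candidate foods each) and several hundred string pairs
against the brute-force window oracle, plus an exhaustive scan of all
short-string pairs over a three-letter alphabet; property suites
(monotonicity, agreement inequality) use 500 cases each. The acceptance
script runs three full benchmark generations and pipelines (100
products, 200 reference foods each) and 200 simulated decision logs.
These sizes were chosen so the whole suite completes in a few minutes
on one CPU while keeping every estimate's denominator large enough to
be meaningful.

## Known limitations

* Suggestion quality is bounded by the blocking assignment; a product
  in a heterogeneous category can have its best counterpart in another
  group, and no cross-group rescue is attempted.
* The nutrient screen is conservative by design: one share beyond a
  threshold rejects a candidate outright; there is no weighted or
  learned combination of the filters.
* Only the seven nutrients and energy are compared; micronutrient
  closeness of a match is unknown.
* The sodium term's presence in the ranking scale mixes units (see
  above); rankings with and without it should be compared when sodium
  drives decisions.
* Agreement statistics assume exactly two first-round raters per
  product; richer designs must be reduced to rater pairs.
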