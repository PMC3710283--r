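---
title: "Validating point-of-interest databases against field censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating point-of-interest databases against field censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poivalid)
```

## The measurement problem

Studies of the food environment — and of built-environment exposures
generally — usually characterize neighborhoods from secondary
point-of-interest (POI) databases rather than from fieldwork: a commercial
or governmental file listing each business with a name, a street address, a
geocoded coordinate and one to six 4-character industry classification
codes. Those files are imperfect. Outlets are missing, listed outlets have
closed, names and categories are wrong, and geocoding scatters records
across areal-unit boundaries. Whether such errors matter depends on how
exposure is measured: a density of outlets per census tract is insensitive
to a wrong business name or to a coordinate that stays inside the tract,
while an exact distance-to-nearest-outlet measure is not.

`poivalid` implements a validation workflow for this situation. Given a
database listing, a field census of the same areal units, and the unit
polygons, it classifies every record into a *disposition*, tallies
confusion counts under two matching philosophies, and computes three
families of validity measures, each with per-unit values, weighted
overall values, confidence intervals and a qualitative rating, plus
chi-square tests of variation across unit groupings and outlet
categories. A seeded synthetic-foodscape generator with closed-form
expected metrics makes the whole pipeline testable without any external
data.

## Disposition taxonomy and the matcher

Records are compared only within their areal unit (candidate pairs across
units are never formed; cross-unit geocoding errors are handled separately,
below). A database/field pair can agree or disagree on three attributes —
normalized street address, normalized name, observed/listed category —
which yields five pair dispositions:

| stage | address | name | category | disposition |
|------:|:-------:|:----:|:--------:|:------------|
| 1 | = | = | = | matched |
| 2 | = | ≠ | = | name error |
| 3 | ≠ | = | = | location error (within unit) |
| 4 | = | = | ≠ | category error |
| 5 | = | ≠ | ≠ | error in both name and category |

Unpaired database records are *not found* (listed but absent in the
field); unpaired field records are *unlisted*. An unlisted field outlet
that exists in the complete database under the right name and address but
geocoded outside its true unit is reclassified *ill-extracted*: the
spatial extraction, not the database content, missed it
(`find_ill_extracted()`).

Names count as "the same" when their token-set Dice similarity
(`name_similarity()`, 2·|A∩B| / (|A|+|B|) over normalized word sets) is at
least the configurable threshold, 0.85 by default. The threshold is the
operational stand-in for the human judgment a field observer applies; it
is logged in every report. Normalization (`normalize_text()`,
`normalize_address()`) case-folds, strips accents and punctuation, and
removes apartment/suite designators, so the address key is street number
plus street name.

Because several records can share an address or a name, assignment is a
matching problem, not a lookup. The matcher maximizes the vector of stage
counts *lexicographically* — as many perfect matches as possible, then as
many name errors among the remainder, and so on — exactly, by dynamic
programming over subsets within each connected component of the candidate
graph. A pure stage-by-stage greedy pass is not equivalent: a greedy
stage-2 choice can block a stage-3 pair elsewhere in the component. On
random small cases the implementation agrees with a brute-force
enumeration of all assignments (tested). Ties among optimal assignments
are broken per database record in id order by lowest stage, then lowest
field record id, so results are independent of input row order. Components
whose smaller side exceeds 12 records fall back to a deterministic greedy
sweep; in real listings components are almost always single pairs.

## Traditional and relaxed measures

Two confusion-count modes (`confusion_counts()`):

* **traditional** — only stage-1 pairs are true positives; any name,
  location or category discrepancy makes the database record a false
  positive and the field record a false negative;
* **relaxed** — name errors and within-unit location imprecision are
  forgiven (stages 1–3 are TPs); category errors, phantom listings and
  missed outlets still count against the database.

Sensitivity is TP/(TP+FN), the share of field outlets the database lists;
PPV is TP/(TP+FP), the share of listed outlets that exist. Conservation
holds by construction: TP+FP equals the listed total and TP+FN the field
total, in both modes, and relaxed measures can never be worse than
traditional ones (tested as an invariant).

For pairs with a category mismatch, the FP is tallied in the
database-listed category cell; the FN cell is configurable
(`category_attribution`), defaulting to the listed category as well —
the convention under which, within every category, field total = listed −
not found + unlisted + ill-extracted holds exactly.

Ill-extracted outlets stay false negatives in both modes: relaxation
tolerates only *within-unit* imprecision, and a record geocoded into the
wrong unit distorts two units' densities. Setting
`treat_ill_extracted_as = "tp"` answers the counterfactual "what if
cross-unit geocoding errors were repaired", which is exactly the gain a
geocoding-audit-and-fix pass would deliver.

## Representativity

When exposure is a per-unit density by outlet category, a missed
convenience store (FN) and a phantom convenience store (FP) in the same
tract cancel in the density. The *representativity* of a unit's listing
captures this compensation. The package's default form is

```
representativity = (Σ_c TP_c + Σ_c min(FP_c, FN_c)) / (Σ_c TP_c + Σ_c FN_c)
```

with the sums over outlet categories *c* within one unit, on relaxed
counts. Each category's misses are offset by that category's phantoms,
capped at full compensation, so the value always lies between the relaxed
sensitivity and 1 (tested as an invariant).

An alternative, `variant = "as_printed_abs"`, replaces `min(FP, FN)` with
`|FP − FN|`. This form appears in the validation literature, but it is
anomalous and the package keeps it only for auditability: it equals 1
whenever a unit has no FPs at all, no matter how many outlets are missed,
and exceeds 1 as soon as FP > 2·FN in a cell (the function warns rather
than clamps). There is also a parity obstruction: Σ|FP−FN| always has the
parity of FP+FN and is at least |ΣFP − ΣFN|, so for many observed margins
the absolute-difference form cannot reach the values the capped form
attains — the test suite demonstrates this by exhaustively enumerating
every allocation of the FP and FN margins over units for three category
margins where only the capped form is feasible. That enumeration is why
`compensated_min` is the default.

Representativity must always be read together with its spatial tolerance
(here: "stays within the same areal unit"); with a smaller unit or a
distance-based rule the measure becomes stricter.

## Aggregation, intervals, labels

Overall values are averages of unit-level values weighted by the number of
outlets per unit — each measure's own denominator (field count for
sensitivity and representativity, listed count for PPV). Under this
weighting the overall value equals the pooled ratio of summed counts, so
unit-level and whole-study arithmetic agree exactly (property-tested on
random tables). Units with an undefined value (zero denominator) are
excluded from numerator and denominator alike.

Three confidence-interval methods are exposed: a truncated Wald interval
(default), the Wilson score interval (better near 0 and 1), and a
between-unit interval — weighted mean ± z times the weighted between-unit
standard error with the effective number of units (Σw)²/Σw² — for when
unit-to-unit heterogeneity, not binomial noise, dominates. Published
validation studies rarely state their interval method, so no single choice
can be canonical; the method is recorded in every report.

For comparability with the descriptive vocabulary used across validation
studies, `qualitative_label()` maps values to *poor* (≤ 0.30), *fair*
(≤ 0.50), *moderate* (≤ 0.70), *good* (≤ 0.90) and *excellent* (> 0.90),
half-open on the left. The scale is indicative only.

## Variation tests

`build_contingency()` lays sensitivity or PPV out as a binary
encountered/not-encountered outcome across strata (unit groupings such as
socioeconomic tertile or predominant language, or outlet categories), and
`chi_square()` applies Pearson's test of independence without continuity
correction, flagging expected cells below 5; `combine_rows()` merges
sparse strata first (e.g. mega-markets into chain supermarkets). Fisher's
exact test is deliberately not provided: its conditioning on fixed margins
is wrong for this design, where every margin — how many outlets are
listed, found, or missed — is itself an observation. Type-I error of the
chi-square at the nominal 5% level is checked by seeded simulation in the
test suite.

## The synthetic foodscape generator

`generate_scenario()` draws a ground truth — areal units on a unit-square
grid with alternating language and SES attributes, Poisson outlet counts
per unit, categories from a configurable mix — and corrupts it into a
listing by applying independent per-record errors in a fixed order:
omission, category confusion, name error, within-unit location jitter,
cross-unit geocoding shift; phantom entries and duplicate entries (half of
them with an administrative name suffix) are appended afterwards. Shifted
records leave the extracted listing (they are geocoded outside every
validated unit) but stay in the full database, so the ill-extracted search
can recover them. Every applied error is recorded in a truth log, and
identical seeds give byte-identical scenarios without disturbing the
caller's RNG stream.

Default rates (omission 0.22, phantom fraction 0.16, name error 0.12,
within-unit location error 0.01, cross-unit shift 0.07, category confusion
0.07, duplicates 0.05) emulate a commercial POI file validated about a
year after release in a dense city: roughly a fifth of true outlets
missing, a sixth of listed outlets gone, name discrepancies on one listed
outlet in eight, and a few percent each of category and geocoding errors.
The category mix defaults to a census dominated by full-service
restaurants. The phantom parameter is defined as the expected *fraction of
the final listing* that is phantom, which is the quantity a PPV audit
reports; phantoms are therefore appended per unit with Poisson counts at
rate q/(1−q) per retained record.

`expected_metrics()` gives the closed-form expectations implied by that
process (ω omission, q phantom fraction, ν name, λ location, γ shift,
ε mean category-confusion mass):

* traditional sensitivity (1−ω)(1−γ)(1−ε)(1−ν)(1−λ);
* relaxed sensitivity (1−ω)(1−γ)(1−ε)(1−ν·λ) — a record with *both* a
  name and a location error shares no key with its field counterpart and
  cannot be paired at all, hence the ν·λ term;
* traditional PPV (1−q)(1−ε)(1−ν)(1−λ) and relaxed PPV (1−q)(1−ε)(1−ν·λ).

The test suite runs 200 seeded scenarios of about 5,000 outlets each
(25 units, Poisson mean 200) and requires each estimated measure to sit
within three Monte-Carlo standard errors of its closed form, plus exact
recovery (all measures 1) on a zero-error scenario. Those sizes give the
binomial noise floor (≈0.007 per scenario) a comfortable margin over the
residual O(1/n) ratio bias in PPV.

What the generator deliberately does **not** emulate: real street
geography (units are grid squares), spatially or temporally correlated
errors (real turnover clusters by neighborhood), typo-level name noise
(names are either identical or entirely different, so the similarity
threshold is exercised by the fixture and unit tests, not by the
generator), and multi-code listings. Passing the recovery tests therefore
shows that the estimator chain is unbiased under independent errors, not
that any particular real database has these error rates.

## The built-in demonstration foodscape

`demo_foodscape()` is a deterministic 12-unit fixture with a fully known
error profile — 410 listed against 484 field outlets; 264 perfect matches,
50 name errors, 3 within-unit location errors, 16 category errors, 12
errors in both, 65 listed-but-absent, 105 never-listed and 34
ill-extracted — fixed per outlet category and per unit grouping. The
per-disposition category totals are spread over the six (language × SES)
unit cells by a proportional largest-remainder allocation with a
margin-repair pass (a northwest-corner rule was rejected because it leaves
several units empty), then split between the two units of each cell, so
every marginal rolls up exactly and all twelve units are populated. Names
and addresses are synthesized unique tokens, so the matcher recovers the
intended dispositions exactly. Running the pipeline on it yields
traditional sensitivity 0.545 and PPV 0.644, relaxed sensitivity 0.655 and
PPV 0.773, and significant between-category variation of the relaxed
measures — the arithmetic the acceptance script recomputes.

The overall representativity of a foodscape depends on the unprinted
unit-by-category cross-tabulation, so the fixture fixes one (the
proportional allocation); its overall compensated value (≈0.84 here) is a
property of that allocation, not a reproduction target — which is also why
the per-category attainability tests above are enumeration-based rather
than value-based.

## Numerical and degenerate-input choices

* Point-in-polygon containment combines an even-odd ray test
  (`mgcv::in.out`) with an explicit on-segment check at relative tolerance
  1e-9, because ray-crossing algorithms are unreliable exactly on edges;
  boundary points count as inside, so records on shared tract edges are
  never dropped. If overlapping polygons both contain a point, the first
  unit in file order wins with a warning.
* Rows with unparseable coordinates are returned as rejects with their row
  numbers, never silently dropped: a validation study must account for
  every record.
* Zero-denominator cells yield `NA` with a message and are excluded from
  weighted aggregation; an all-undefined aggregate is `NA`, not an error.
* The true-negative cell of the confusion table is carried as `NA` and
  never computed: in an open business universe "absent from both list and
  field" has no denominator, so specificity and NPV are out of scope.
* Duplicate removal is identity-based (same normalized address, names
  equal or differing by an administrative token such as "office" or
  "fax", grouped transitively); typo-level near-duplicate collapse is
  deliberately not performed — that is the matcher's job, with a
  similarity threshold, not the deduplicator's.
* Categorization rules are applied most-specific-first (mega-markets,
  chains, natural-food, fruit-and-vegetable, specialty, bakeries,
  convenience, groceries, then the three service categories), each rule
  claiming records by code prefix plus whole-token name keyword; a record
  claimed once is never offered to a later rule, and remnants fall back to
  a per-code default. The shipped ruleset encodes common Quebec/Canada
  brand vocabulary and is fully user-overridable; the priority order is a
  documented package choice, and `explain_category()` traces every rule
  decision for audit.

## Limitations

The package validates listings against a census of areal units that were
themselves sampled by some design; it does not model that sampling, so
overall values generalize only as far as the unit sample does. The
between-unit interval treats units as a simple weighted sample. Name
similarity is a blunt instrument for multilingual business names; the
threshold deserves sensitivity analysis in any real study
(`match_config()` makes that one argument). And representativity is a
density-oriented measure: for proximity-based exposure it should not be
used at all.
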