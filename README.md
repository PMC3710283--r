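# poivalid

Field validation of secondary point-of-interest databases, for
food-environment and built-environment epidemiology.

Commercial and governmental business listings (each record: name, street
address, geocoded coordinate, 1–6 four-character industry classification
codes) are the workhorse data source for measuring neighborhood exposure
to food outlets. Before such a file is used to compute densities or
distances, its agreement with the ground needs to be quantified.
`poivalid` implements that validation end to end:

* **Categorization** of database records into eleven outlet categories
  (mega-markets, chain supermarkets, grocery, convenience, bakeries,
  fruit-and-vegetable, specialty, natural-food stores; fast-food,
  full-service restaurants, cafés) by prioritized code-prefix +
  name-keyword rules with no-reuse-after-assignment, plus duplicate
  removal (administrative "office"/"fax" listing variants) and
  point-in-polygon assignment of records to areal units (census tracts).
* **Disposition matching** of database records against a field census
  within each unit: matched, name error, location error (within unit),
  category error, error in both, not found, unlisted, and ill-extracted
  (present in the full database under the right name and address but
  geocoded outside its true unit). The assignment maximizes the
  disposition-count vector lexicographically and is exactly optimal per
  connected component of the candidate graph.
* **Three metric families** from the resulting confusion counts:

  - *traditional* sensitivity TP/(TP+FN) and PPV TP/(TP+FP), where any
    name/location/category discrepancy is a mismatch;
  - *relaxed* versions that forgive name errors and within-unit location
    imprecision;
  - *representativity*, a per-unit measure that additionally lets false
    positives compensate false negatives within the same outlet category:
    `(Σc TPc + Σc min(FPc, FNc)) / (Σc TPc + Σc FNc)` on relaxed counts
    (an absolute-difference variant `(TP + |FP−FN|)/(TP+FN)` is available
    for auditability; it is anomalous — see the vignette).

  Overall values are unit-level values weighted by each measure's own
  denominator (equal to the pooled ratio), with Wald / Wilson /
  between-unit confidence intervals and the conventional
  poor–fair–moderate–good–excellent rating scale.
* **Variation tests**: Pearson chi-square on encountered/not-encountered
  contingency tables across unit groupings (SES, language) and outlet
  categories, with row merging for sparse strata. Fisher's exact test is
  deliberately not offered (its fixed-margins assumption fails for this
  design).
* **A synthetic foodscape simulator** with independent, seeded error
  processes (omission, category confusion, name error, location jitter,
  cross-unit geocoding, phantoms, duplicates) and closed-form expected
  metrics, used for parameter-recovery testing of the whole pipeline.

## Worked example

`demo_foodscape()` builds a deterministic 12-tract foodscape with a fully
known error profile: 410 listed outlets against 484 observed in the field
(264 perfect matches, 50 name errors, 3 location errors, 16 category
errors, 12 both, 65 listed-but-absent, 105 never listed, 34
ill-extracted), with fixed per-category and per-grouping margins.

```r
library(poivalid)

fx <- demo_foodscape()
report <- run_validation(fx$db_listing, fx$field_truth, fx$units,
                         full_db = fx$full_db)
report
#> Point-of-interest validation report
#>   traditional sensitivity      0.545 [0.501-0.590] (moderate, n=484)
#>   traditional ppv              0.644 [0.598-0.690] (moderate, n=410)
#>   traditional representativity 0.841 [0.808-0.873] (good, n=484)
#>   relaxed     sensitivity      0.655 [0.613-0.697] (moderate, n=484)
#>   relaxed     ppv              0.773 [0.733-0.814] (good, n=410)
#>   relaxed     representativity 0.841 [0.808-0.873] (good, n=484)
```

Reading: the database finds 54.5% of the outlets that exist (sensitivity)
and 64.4% of its entries exist in the field (PPV) — "moderate" on the
conventional scale. Forgiving name errors and within-tract location
imprecision lifts these to 65.5% and 77.3%. Letting same-category false
positives stand in for false negatives within each tract (the right
accounting when exposure is a per-tract density) gives a "good"
representativity of 0.841 on this fixture's allocation. Variation across
outlet categories is significant only for the relaxed measures:

```r
v <- report$variation
v[v$grouping == "category", c("mode", "measure", "statistic", "df", "p_display")]
#>   mode        measure     statistic    df p_display
#> 1 traditional sensitivity      13.0     9 0.164
#> 2 relaxed     sensitivity      34.1     9 <0.001
#> 3 traditional ppv              12.7     9 0.177
#> 4 relaxed     ppv              29.9     9 <0.001
```

The same workflow runs from files (CSV listings + GeoJSON units) through
`cmd_validate()`, or from the shell:

```sh
poivalid validate --db db.csv --field field.csv --units units.geojson --out results/
poivalid simulate --scenario scenario.yaml --seed 42 --out sim/
```

(the `poivalid` script is installed under `inst/cli/`). Synthetic
scenarios are configured with `scenario_params()` and validated against
`expected_metrics()`:

```r
p <- scenario_params(omission_rate = 0.2, phantom_rate = 0,
                     name_error_rate = 0, category_confusion = 0,
                     within_unit_location_error_rate = 0,
                     cross_unit_geocode_rate = 0)
expected_metrics(p)[["sensitivity_relaxed"]]
#> [1] 0.8
```

## Further reading

The methods vignette (`vignettes/validating-poi-databases.Rmd`) documents
the disposition taxonomy and matcher, the two confusion modes, both
representativity variants and why the capped-compensation form is the
default, the aggregation and interval choices, the chi-square design, the
synthetic error model with its closed forms, and the package's numerical
and degenerate-input conventions.
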