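# hedgekit

Tools for developing and validating Boolean literature **search filters**
(*hedges*) against gold-standard-labelled corpora of bibliographic records.

A search filter is a pre-built Boolean query — e.g. for the paramedic /
emergency medical services literature, a field with no MeSH term of its
own — that users AND with their topic query to restrict retrieval to the
field. Developing one means building a hand-screened reference set,
measuring candidate terms one at a time, and OR-combining them under an
explicit objective. hedgekit implements that whole pipeline:

* **Records**: read/write MEDLINE tagged exports (`read_medline()`,
  `write_medline()`), reference-set preparation with duplicate and
  no-abstract exclusion (`prepare_retrieval_set()`), and dual-screening
  bookkeeping with third-reviewer adjudication (`reconcile_labels()`,
  `apply_adjudication()`).
* **Filter language**: an Ovid-MEDLINE-syntax parser/serializer
  (`parse_filter()`, `serialize_filter()`) and evaluator (`retrieve()`)
  supporting `.tw`/`.sh` field tags, phrases, truncation (`*`), and
  `OR`/`AND`/`NOT` with standard precedence.
* **Metrics**: 2×2 contingency tables (`contingency()`) and performance
  statistics (`performance()`) — for a table with cells *a* (relevant
  retrieved), *b* (irrelevant retrieved), *c*, *d*:

  sensitivity = a/(a+c), specificity = d/(b+d), precision = a/(a+b),
  NNR = 1/precision, accuracy = (a+d)/(a+b+c+d)

  where NNR, the *number needed to read*, is how many retrieved records
  must be screened to find one relevant record. `reconstruct_table()`
  inverts the formulas to audit published figures.
* **Development**: single-term analysis (`single_term_analysis()`,
  `summarize_single_terms()`) and greedy OR-combination with
  sensitivity- or specificity-maximising objectives and a floor on the
  other metric (`greedy_develop()`), plus a brute-force reference
  (`exhaustive_or_search()`).
* **Synthetic corpora**: a seeded generator (`generate_corpus()`) emitting
  labelled MEDLINE-like corpora with known term-occurrence structure, so
  every stage is testable end to end without external data.
* **Published filters**: the two paramedic hedges (sensitivity- and
  specificity-maximising) ship verbatim with their reported performance;
  `check_published()` audits their internal consistency.

## Worked example

Generate a labelled corpus at a realistic 20.5% prevalence (431 relevant,
1671 irrelevant records), analyse a small candidate pool, then develop a
sensitivity-maximising filter:

```r
library(hedgekit)

profiles <- list(
  term_profile("paramedic*.tw", 0.55, 0.02),   # p(term | relevant), p(term | irrelevant)
  term_profile("ems.tw",        0.30, 0.03),
  term_profile("Ambulances.sh", 0.30, 0.03),
  term_profile("prehospital.tw",0.35, 0.08))
g <- generate_corpus(corpus_spec(431, 1671, profiles, seed = 42))

single_term_analysis(lapply(profiles, `[[`, "term"), g$corpus, g$gold)
#>             term   a   b sensitivity specificity      nnr
#> 1  paramedic*.tw 229  35   0.5313225   0.9790545 1.152838
#> 2         ems.tw 143  44   0.3317865   0.9736685 1.307692
#> 3 prehospital.tw 142 120   0.3294664   0.9281867 1.845070
#> 4  ambulances.sh 129  49   0.2993039   0.9706762 1.379845

cfg <- development_config("sensitivity_maximising",
                          lapply(profiles, `[[`, "term"), floor = 0.5)
greedy_develop(cfg, g$corpus, g$gold)
#> <filter_development> objective: sensitivity_maximising, floor 0.5
#>   paramedic*.tw OR ems.tw OR ambulances.sh OR prehospital.tw
#> <performance> sensitivity 88.2%  specificity 85.8%  precision 0.615  NNR 1.63  accuracy 86.3%
```

Each single term is highly specific but weakly sensitive (the usual
pattern for subject vocabulary); OR-combining them lifts sensitivity from
53% to 88% at the cost of specificity, and a reader screening the
filter's output finds one relevant record per 1.63 retrieved (NNR).

Auditing the packaged published filters:

```r
check_published()
#> Published-filter internal consistency (reconstruction from class sizes and printed rates)
#>   paramedic_sensitivity  printed NNR 2.00, reconstructed 2.01 -> consistent
#>   paramedic_specificity  printed NNR 1.48, reconstructed 1.48 -> consistent
#>   prehospital            printed NNR 2.44, reconstructed 2.38 -> INCONSISTENT
#>   parse/serialize round trip: ok
#>   sensitivity-variant term superset: ok
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hedgekit.R", package = "hedgekit"))')" \
    check-published
```

Subcommands: `evaluate`, `single-terms`, `develop`, `generate`,
`reconcile`, `check-published`. See the header of `inst/cli/hedgekit.R`
for flags.

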