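---
title: "Developing and validating Boolean literature search filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating Boolean literature search filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedgekit)
```

## The problem

A literature search filter (a *hedge*) is a pre-built Boolean query that a
clinician or researcher ANDs with their own topic query to restrict
retrieval to a field — here, paramedic / emergency medical services (EMS)
literature, a field with no dedicated MeSH term. Because paramedics are
described differently across countries and decades ("ambulance driver",
"EMT", "extended care paramedic"), no single term retrieves the field:
filters must OR together many text words and subject headings, trading
**sensitivity** (share of relevant records retrieved) against
**specificity** (share of irrelevant records correctly excluded).

hedgekit implements the *second-generation* development methodology: build
a hand-screened gold standard, measure candidate terms one at a time,
OR-combine them under an explicit objective, and report 2×2 performance.

## The performance model

Crossing a filter's retrieval set against a completely screened reference
set gives the contingency table

|                | relevant | irrelevant |
|----------------|----------|------------|
| retrieved      | a        | b          |
| not retrieved  | c        | d          |

with sensitivity $a/(a+c)$, specificity $d/(b+d)$, precision $a/(a+b)$,
accuracy $(a+d)/(a+b+c+d)$ and the *number needed to read*
$\mathrm{NNR} = 1/\mathrm{precision}$ — how many retrieved records must be
screened to find one relevant record. When a filter retrieves nothing,
precision and NNR are reported as *undefined*, never coerced to 0 or
infinity. Accuracy has no single canonical definition in the filter
literature; the standard $(a+d)/N$ is implemented and documented as this
package's interpretation.

`reconstruct_table()` inverts these formulas: given class sizes and
published (rounded) sensitivity/specificity it rebuilds the integer cells
with half-up rounding, which lets printed figures be checked against one
another (see "Published filters" below). By construction the reconstructed
rates agree with the inputs to within $1/(2\,n_{\text{class}})$.

## The filter language

Filters are parsed from the Ovid MEDLINE dialect: atoms are terms with an
optional field tag, combined with case-insensitive `OR`, `AND` and unary
`NOT` (precedence `NOT > AND > OR`, left-associative, parentheses allowed).
Choices that were genuinely open, and how they were fixed:

* **Tokenization.** Text is case-folded and split on every non-alphanumeric
  character; digits are kept. Hyphenated forms therefore split, so
  `pre-hospital.tw` and `prehospital.tw` are distinct terms — exactly why
  published filters carry both spellings.
* **`.tw` scope** is title + abstract (the Ovid definition of *text word*).
  The record model carries no author keywords, so they are out of scope.
* **`.sh` semantics** are *unexploded*: the term must equal an assigned
  MeSH heading case-insensitively after stripping a `/qualifier` suffix
  (and a leading `*` major-topic marker). Explosion would require the MeSH
  tree, which the package does not ship; this is the documented switch
  point if one is added.
* **Truncation `*`** is a prefix match within a single document token,
  zero or more extra characters, allowed only on the final token of an
  atom; mid-word wildcards are parse errors.
* **Phrases** must occur as contiguous token runs; there is no stemming
  and no stop-word removal.
* **Untagged atoms** default to `.tw`. Unknown tags (`.mp`, `.ti`, …) are
  parse errors with a character position, not silently ignored.

`serialize_filter()` emits a canonical form (lower-case terms, upper-case
operators, parentheses only where precedence requires) whose re-parse is
structurally identical — a property the test suite checks on random trees
and on the packaged published strings.

Internally, matching works as a regular-expression search over a
normalised (single-spaced, tokenised) field string; the test suite
cross-checks it against an independent, regex-free token-loop scan.

## Filter development

The historical procedure — "terms were added and subtracted until
performance was optimal" — was manual. `greedy_develop()` formalises it as
deterministic greedy forward selection with backward pruning over pure-OR
filters (the published filters are pure OR; AND/NOT are supported by the
language but never emitted by the builder):

* **sensitivity_maximising**: repeatedly add the candidate with the
  largest sensitivity gain among those keeping specificity ≥ `floor`;
  stop when no candidate strictly improves sensitivity.
* **specificity_maximising**: OR-additions can only lower specificity, so
  a literal "add what improves the objective" would stop at the empty
  filter. The builder instead runs in constraint-satisfaction mode: while
  sensitivity < `floor` (the target recall), add the candidate that costs
  the least specificity; stop as soon as the floor is met.

Ties break by greater improvement in the non-objective metric, then fewer
retrieved records, then lexicographic term text; objectives compare raw
proportions, never rounded display values, to avoid tie artefacts. After
each addition, any term whose deletion leaves neither metric worse and
strictly improves one is removed — in the sensitivity-maximising case this
reduces exactly to "deletion does not reduce sensitivity and raises
specificity". A floor no term combination can meet yields an explicit
infeasibility result. The defaults (`floor = 0.5` on specificity when
maximising sensitivity, `floor = 0.9` on sensitivity when maximising
specificity, `max_terms = 25`) reflect the published trade-off: a broad
researcher filter tolerating moderate specificity, and a clinician filter
that keeps most of the recall.

Greedy selection over OR-subsets is not globally optimal in general;
`exhaustive_or_search()` enumerates all subsets up to a size cap as a
brute-force reference, and the tests report the greedy-vs-exhaustive gap
on an 8-term pool (≤ 4-term subsets, 200-record corpus). The trace returned
with every development run replays to the final filter exactly.

## The synthetic corpus generator

`generate_corpus()` emulates the *structure* of a screened reference set:
two exactly sized classes (defaults 431 relevant / 1671 irrelevant —
prevalence 20.5%), with each candidate term inserted independently per
record with a class-specific probability (`p_relevant` / `p_irrelevant`),
placed in title, abstract or MeSH according to its field. Under this model
a single-term filter has closed-form expected sensitivity `p_relevant` and
specificity `1 − p_irrelevant`, and an OR of occurrence-independent terms
has expected sensitivity $1 - \prod_i (1 - p_{\text{rel},i})$ — exact
oracles the Monte-Carlo tests verify at $n = 10{,}000$ within 99% binomial
confidence intervals.

Deliberate simplifications, and what they imply:

* **Independence.** Term occurrences are independent within a record; real
  vocabulary co-occurs heavily (records about paramedics mention several
  pool terms at once). Passing tests therefore validate the *bookkeeping
  and arithmetic* of the pipeline, not how well any filter will perform on
  real MEDLINE text.
* **Filler text** is drawn from a reserved vocabulary (`vx…q` words)
  constructed so it can never complete or prefix-match a candidate term,
  keeping the closed-form oracles exact; profile terms colliding with it
  are rejected. The oracles are exact only for pools whose terms share no
  tokens (otherwise one term's insertion could complete another's phrase);
  the bundled test pools respect this.
* Titles/abstracts are token soup, not natural language, and journal/year
  metadata is sampled uniformly — no journal or period stratification.

Generation is fully reproducible: the seed is mandatory, the caller's RNG
state is restored afterwards, and equal seeds give byte-identical MEDLINE
output files.

## Reference-set preparation and screening bookkeeping

`prepare_retrieval_set()` drops duplicates (record id is authoritative;
then a normalised-title-plus-year key, keeping the first occurrence — the
exact rule used by citation managers is not published, so this choice is
documented rather than claimed) and records with empty or whitespace-only
abstracts, reporting both exclusion counts; it is idempotent.
`reconcile_labels()` implements dual-screening bookkeeping: agreements
become final labels, disagreements are returned for third-reviewer
adjudication, single-reviewer coverage gaps are flagged. The human
judgement itself is, of course, out of scope.

## Published filters

The two paramedic filters ship verbatim (original capitalisation; parsing
normalises case): a 16-term sensitivity-maximising variant and its 14-term
specificity-maximising subset, differing by exactly
`emergency medical services.sh` and `out-of-hospital.tw`. The reference
set they were measured on (2102 screened records, 431 relevant) is not
publicly deposited, so their headline figures cannot be re-measured
directly; `check_published()` instead verifies *internal* consistency:
each filter's contingency table is reconstructed from the class sizes and
printed rates and the implied NNR compared with the printed one, at 2
decimal places or — when the printed value is a whole number — at integer
precision. On these figures the paramedic rows reproduce (implied NNR 2.01
≈ "2", and 1.48) while the pre-existing prehospital filter's row does not:
reconstruction implies NNR ≈ 2.38 against a printed 2.44. The toolkit
reports that discrepancy; it does not attempt to resolve it. The
prehospital filter's query string is published elsewhere and is not
packaged; only its performance row is.

## Numerical conventions

* Half-up rounding (`round_half_up()`) wherever printed tables are
  reconstructed; R's default banker's rounding is never used for that.
* Sample standard deviation (n−1) in single-term summaries; with a single
  result the SD is `NA` and flagged, not 0.
* Display precision mirrors the field's tables: percentages to 1 decimal
  place, NNR to 2; raw values are stored unrounded.

## Problem sizes

The bundled tests run corpora of 10–400 records for behavioural
properties, 100 random 15-record corpora for OR-monotonicity, a
10,200-record corpus for the Monte-Carlo oracle, and a 200-record corpus
with an 8-term pool for the exhaustive-search comparison; the acceptance
script develops filters on a full-scale 2102-record synthetic set with a
16-term pool. These sizes keep a complete run within a few minutes on one
CPU while leaving every statistical check well-powered.

## Limitations

* No MeSH explosion, `.mp`, adjacency operators, or limits — none occur in
  the packaged filters.
* The greedy builder emits pure-OR filters only.
* Synthetic corpora validate mechanics, not real-world filter
  performance; third-generation development (word-frequency or regression
  based term selection, external validation) is out of scope.

## A worked example

```{r}
profiles <- list(
  term_profile("paramedic*.tw", 0.55, 0.02),
  term_profile("ems.tw", 0.30, 0.03),
  term_profile("Ambulances.sh", 0.30, 0.03),
  term_profile("prehospital.tw", 0.35, 0.08))
g <- generate_corpus(corpus_spec(431, 1671, profiles, seed = 42))

single_term_analysis(lapply(profiles, `[[`, "term"), g$corpus, g$gold)

cfg <- development_config("sensitivity_maximising",
                          lapply(profiles, `[[`, "term"), floor = 0.5)
greedy_develop(cfg, g$corpus, g$gold)

check_published()
```
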