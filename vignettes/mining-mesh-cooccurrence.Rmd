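---
title: "Mining MeSH descriptor co-occurrence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining MeSH descriptor co-occurrence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshcooc)
```

## The problem

Every PubMed record is indexed with Medical Subject Headings (MeSH):
controlled descriptor terms, optionally refined by qualifier subheadings
(`"Telemedicine/trends"`). Because the indexing is controlled, simple exact
matching of descriptors against curated term lists yields a quantitative,
repeatable picture of a research field: which diseases digital-health
publications address, how attention moves over years, and which tools and
conditions are studied together. `meshcooc` implements that pipeline:

1. read bibliographic records (PubMed XML or MEDLINE nbib),
2. filter by date window, abstract availability, and affiliation,
3. match descriptors exactly against categorised vocabularies,
4. count occurrences, per-year trends, and record-level co-occurrences,
5. build a typed co-occurrence network with subnetwork extraction and
   Cytoscape-compatible export.

The motivating use case is the UK digital-health literature 2011–2021: a
search for publications tagged with any of eight digital-health phrases,
restricted to UK-affiliated records with abstracts, followed by exact
matching against a 26-term digital-health vocabulary and a disease list.

## Matching model

Matching is *exact at the whole-descriptor level* after normalization —
never substring matching, stemming, or MeSH-tree expansion. The descriptor
`"Telemedicine and Telehealth"` does not match the term `telemedicine`.
This is deliberate: tree expansion or fuzzy matching would change every
count and make results dependent on a thesaurus version. Normalization
(`normalize_term()`) only removes formatting noise: case, surrounding and
repeated whitespace, typographic dashes, and the `"/qualifier"` suffix.
Qualifier stripping means `"Telemedicine/trends"` counts as `telemedicine`
— headings are counted at descriptor level, with qualifier variants of one
descriptor collapsing to a single match per record.

A small caveat recorded here: word-cloud-style outputs are often described
as counting mentions "across abstracts", but all counting in this package
is via MeSH descriptors, never free text. The `wordcloud_frequencies()`
table is a descriptor-level frequency table.

## Counting model

The counting unit is the **record**, binary per record:

* `occ(t)` — the number of records whose descriptor set matches term `t`
  at least once;
* `cooc(a, b)` — the number of records matching both `a` and `b`; one
  record contributes at most 1 to any pair, however many descriptor
  variants repeat the terms.

This matches the interpretation "publications associated with a term", and
gives the invariants the tests enforce: `cooc(a,b) <= min(occ(a), occ(b))`,
permutation invariance in record order, and per-term year sums equal to
totals on fully-dated corpora. Records without a parseable year stay in the
corpus and in totals but contribute to no year cell; records are dropped by
`filter_corpus()` only when an explicit date window is in force, since
membership in the window cannot be established without a year.

Group aggregation (`aggregate_groups()`, e.g. pooling `infant` and `child`
into a children group) uses union semantics recomputed from the corpus: a
record matching several members still counts once. Summing member counts
would double-count such records.

Rankings (`top_k()`) order by count descending with ties broken by
ascending term in the C locale. The tie-break is arbitrary but fixed, so
outputs are reproducible across runs and platforms.

## Network model

`build_network()` turns the occurrence and pair tables into an undirected
igraph object: nodes are matched terms typed by their vocabulary category
(`disease`, `digital_health`, ...), node attribute `count` is the occurrence
count, edge attribute `weight` is the co-occurrence count. Defaults are
`edge_threshold = 1` (keep every observed pair) and
`include_isolated = FALSE`; both are configurable, and within-vocabulary
pairs (tool–tool, disease–disease) are counted by the same engine so the
network keeps all pair classes by default.

`first_degree_subnetwork()` implements neighbourhood extraction the way
Cytoscape's "select first neighbors, then new network from selection" does:
the node set is the seeds plus their direct neighbours, and the edge set is
the **induced subgraph** on that node set — neighbour–neighbour edges are
retained, not just seed-incident ones. Seed nodes are re-typed `"selected"`
so downstream styling can highlight them. Exports (GraphML, SIF, attribute
TSVs) are deterministic: vertices sorted by id, edges in canonical pair
order, so identical networks produce byte-identical files. SIF is
tab-delimited because MeSH terms contain spaces.

## The synthetic corpus generator

No public accession reproduces the original corpus (it was a dated search
of a live database), so the package is tested against a generative model
whose truth is known (`synthetic_config()`, `generate_corpus()`):

* each record draws a year from `year_weights`, an abstract flag, and a
  UK-marked affiliation with probability `uk_affiliation_p`;
* each vocabulary term is included independently with probability
  `marginal_p[t]`;
* each boosted pair `{a, b}` is co-injected with probability `q`, unioned
  with the independent draws;
* `noise_terms` descriptors drawn from a reserved alphabet
  (`"ZZ Synthetic Noise ..."`) are appended, guaranteed disjoint from every
  vocabulary term.

The pair co-injection design was chosen over a full log-linear dependence
model because its closed forms stay exact while still producing genuine
positive association. With `B(t)` the boosts touching `t`:

* inclusion: `pi(t) = 1 - (1 - p_t) * prod(1 - q)` over `q in B(t)`,
  so `E[occ(t)] = n * pi(t)`, `Var[occ(t)] = n * pi(t) (1 - pi(t))`;
* boosted pair with boost `q`:
  `P(a,b) = q + (1 - q) * pi_excl(a) * pi_excl(b)` where `pi_excl(t)` is
  `t`'s inclusion probability from all mechanisms *except the shared
  boost* — the marginal plus the term's other boosts. Because all
  mechanisms are independent and only the shared boost injects both terms
  at once, this is exact even when a term participates in several boosts;
* unboosted pair: `P(a,b) = pi(a) * pi(b)` (such a pair never shares a
  mechanism).

Recovery tests assert every observed count within 4 standard deviations of
its closed-form expectation. Under the model the per-term false-failure
probability is below 1e-4, so a fixed-seed suite of a few dozen assertions
is effectively deterministic while still being a real statistical check.

What the generator does **not** emulate: real MeSH indexing depth (records
here carry only vocabulary hits plus uniform noise), correlated yearly
trends per term (years and terms are independent), titles and abstract
text, multi-affiliation authorship, and MeSH hierarchy effects. Passing
tests therefore demonstrate correctness of counting, network construction
and serialization — not robustness to the messiness of live PubMed data
beyond what the parsers' fixtures cover (heterogeneous date formats,
missing PMIDs, qualifier variants, continuation lines).

## The literature-shaped scenario

`literature_scale_scenario()` is a ready-made configuration whose marginal
probabilities are proportional to the occurrence counts reported for the
mined UK corpus of 9,199 records — telemedicine 1367 down to
telerehabilitation 13 and digital divide 8 among the digital-health terms,
cerebrovascular disease 119 down to schizophrenia 30 among the sample
diseases. The 19 digital-health terms without an individually reported
count were fixed once at plausible mid-range values between those extremes
(20–260 per 9,199 records) and are not meant as estimates of the real
counts; their role is to populate the middle of the ranking. Five boosted
pairs mirror the prominent associations (telemedicine–hypertension,
telemedicine–diabetes, smartphone–obesity, mobile applications–obesity,
remote consultation–electronic health records). Year weights grow roughly
tenfold across 2011–2021, emulating the field's publication growth.

Defaults are `n_records = 3000` — about a third of the emulated corpus,
chosen so the end-to-end demo runs in seconds while the reported ranking
extremes (top term, bottom two) sit many standard deviations apart — and
`seed = 20211227`, the date stamp of the emulated search. At these
settings the demo's digital-health ranking places telemedicine first and
{digital divide, telerehabilitation} in the bottom two, mirroring the
reported qualitative ordering.

## Numerical and formatting choices

* **Determinism.** All randomness flows through one integer seed
  (`withr::with_seed`); all string orderings (rankings, canonical pair
  order, vertex order) use the C collation locale so results do not depend
  on the session locale.
* **Year extraction.** Structured `PubDate/Year` wins; otherwise the first
  four-consecutive-digit substring of the free-text `MedlineDate`
  (`"2012 Jan-Feb"` gives 2012); otherwise the year is absent. MEDLINE
  dates are too heterogeneous for stricter parsing, and the pipeline only
  bins by calendar year.
* **Affiliation matching** is case-insensitive substring over raw
  affiliation strings with default markers `"United Kingdom"` and `"UK"`.
  No geocoding is attempted; the UK restriction can equivalently be applied
  inside the query (`build_query()`) or post hoc (`filter_corpus()`).
* **TSV cache escaping.** Descriptor and affiliation lists are pipe-joined
  with backslash escapes for `\`, `|` and tab, making the cache lossless
  for arbitrary descriptor strings.
* **Duplicate records** across merged sources keep the first occurrence,
  with a warning — overlapping searches must not double counts.
* **Degenerate inputs.** Empty corpora, empty co-occurrence tables and
  empty networks are valid everywhere and serialize to valid (header-only
  or element-free) files.

## Limitations

* Exact descriptor matching misses synonym and entry-term variation;
  loading a vocabulary with alias rows (`alias,canonical`) is the supported
  mitigation, MeSH thesaurus expansion is out of scope.
* The disease vocabulary shipped is a ten-term sample for tests and demos;
  real analyses should supply a full curated list via `load_vocabulary()`.
* Live E-utilities harvesting is out of scope; `build_query()` produces the
  search expression for use with external tooling, and parsed exports are
  the supported input path.
* Gender is supported as a vocabulary category but no builtin list ships,
  since no gender-specific results are part of the reference analyses.
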