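---
title: "Field-specific article importance from degree-preserving citation nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-specific article importance from degree-preserving citation nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldrank)
```

## The problem

Citation-based importance metrics are usually computed once, on a global
network, and then compared across disciplines. But citation practices
differ between fields, and — more interestingly — the *same* article can
genuinely matter more to one community than to another. `fieldrank`
separates these two effects. It computes PageRank within field-specific
citation networks, and then asks, for every article, whether its PageRank
is higher or lower than expected given only its citation counts, by
comparing against an ensemble of degree-preserving random networks. The
residual — a permutation percentile — is comparable across fields, and the
difference of an article's percentiles in two fields measures its
field-specific affinity.

## Data model

The pipeline consumes two inputs: a dump of directed DOI-to-DOI citation
pairs (the dialect of the OpenCitations COCI CSV, or a minimal two-column
form) and a metadata sidecar mapping each DOI to its subject headings,
journal, language, and publication type. Headings live in a rooted
hierarchy in the style of the Medical Subject Headings (MeSH) tree;
"fields" are headings chosen from that hierarchy.

Citations are normalized at load: DOIs are case-insensitive so both
endpoints are lowercased and trimmed, self-citations are dropped, and
duplicate pairs collapse to one edge. Every network downstream is a simple
directed graph with edges running from the citing to the cited article, so
PageRank mass accumulates on influential papers. Networks are
edge-induced: an article with no qualifying citation is simply absent.
Only journal articles written in English enter networks.

## Field selection

Hierarchical subject vocabularies mix very broad and very narrow
headings. To extract a balanced field set, heading counts are first
annotated (by default *exploded*: an article tagged with a heading or any
of its descendants counts once toward the heading, the standard reading
for MeSH-style vocabularies; `explode = FALSE` restricts to direct tags).
The selection rule then walks each tree depth-first: a heading below the
DOI threshold (default 10000, the scale appropriate for a full citation
index; synthetic runs use small thresholds) contributes nothing; a heading
with two or more children that themselves qualify is replaced by recursion
into its children; otherwise the heading is selected and descent stops.
The result is always an antichain. Two readings of the rule are genuinely
open and both implemented: counts with or without descendant explosion,
and the treatment of a heading with exactly one qualifying child. We keep
the parent in that case — requiring *multiple* qualifying children to
descend — because a single dominant child plus small siblings is better
represented by the parent heading.

## Networks, nulls, and percentiles

For a field pair (A, B) the combined network keeps every citation whose
endpoints are each tagged with A or B, including citations that cross
between the fields — the cross-field edges are the point of the
construction. The null ensemble (default 100 replicates) randomizes this
combined network while preserving every node's in- and out-degree
exactly, using the directed three-edge swap: an existing directed path
`a -> b -> c -> d` is rewired to `a -> c`, `c -> b`, `b -> d`. Pair swaps
of two edges cannot reach the whole space of directed graphs with fixed
degree sequences, which is why the three-edge move is needed. A proposed
move is rejected when a replacement edge would be a self-loop or already
exists. The default effort is three successful swaps per edge
(`swaps_per_edge = 3`), configurable because rigid structures may need
more; an attempt cap (100 proposals per requested swap) prevents livelock
on graphs with few admissible moves.

Each shuffled replicate is then *split back* to a field: only edges whose
two endpoints are nodes of the true single-field network survive.
Shuffling can leave an article with no within-field edges, so articles
drop out of some replicates; the fraction of replicates an article is
missing from is its *missingness*, and articles missing from more than 5%
of replicates are filtered out as unstable. The percentile of an article
is the percent of replicates (among those where it is present) in which
its PageRank is strictly lower than in the true network: 100 means the
article beats its degree expectation everywhere, 0 means it always falls
short. Ties count as not-lower; the alternative denominator (all
replicates, absences counted as not-lower) is available via
`count_missing_as_not_lower`.

PageRank uses power iteration on the citing-to-cited direction with the
conventional defaults — damping 0.85, L1 convergence below
`tol * |nodes|` with `tol = 1e-6`, at most 100 iterations — and uniform
redistribution of dangling-node mass. Non-convergence is an error, never
a silent partial result.

## The stopping rule of the shuffler

A subtlety worth recording: the three-edge-swap proposal kernel is
symmetric — the reverse of a move is the same move applied to the rewired
path, selected with identical probability because out-degrees are
invariant — so the chain's stationary distribution is exactly uniform
over the reachable degree-fixed graphs. That guarantee attaches to the
chain in which *proposals* count as steps. Stopping instead after a fixed
number of *accepted* moves (the convention of published shuffling code,
and this package's default, since "swaps per edge" refers to performed
moves) samples the acceptance-conditioned jump chain, whose stationary
law is tilted toward states offering fewer rejections. On citation
networks of realistic size the acceptance rate is essentially constant
across states and the distinction is invisible; on toy graphs small
enough to enumerate it is measurable. `shuffle_network(count =
"attempts")` runs the exactly-uniform variant, and the package's sampling
tests use it on a small graph whose full 33-member degree-fixed space is
enumerable and swap-connected. Two further small-graph facts, verified
against an independent implementation of the same move: the reachable
component can be a strict subset of the degree-fixed space for special
degree sequences (for example 2-regular directed cycles), and neither
stopping rule can repair that.

## What percentile calibration does and does not mean

If the "true" network were itself just one more draw from the null, each
article's percentile is uniformly distributed — the package verifies this
marginal calibration by collecting one article's rank across many
independent ensembles. The *joint* distribution across articles in a
single ensemble is another matter: PageRank sums to one and dangling mass
is redistributed uniformly, so replicate-level fluctuations (how much
mass a particular shuffle concentrates on hubs, how much sits on dangling
nodes) move every article's comparison in the same direction. A histogram
of percentiles from one ensemble therefore concentrates wherever that
ensemble's true draw happens to land, and a one-shot uniformity test over
articles will reject even for a perfectly correct implementation. This
dependence cancels in the affinity difference between two fields scored
against the same ensemble, which is one reason the difference, not the
raw percentile, is the headline quantity.

## Journal metrics

A journal's field-specific score is the median PageRank of the field's
articles it published (even counts take the midpoint), ranked descending
with lexicographic tie-breaks. Journals need 25 articles within a field
pair to be scored, and dataset-wide summaries (top-journal frequency,
fields per journal) restrict to journals with 50 articles, both
configurable. Field pairs are analyzed only when they share at least 1000
eligible articles at full scale; synthetic runs lower this floor.

## The synthetic corpus generator

Because the real inputs are a billion-citation index and a curated
vocabulary, the package ships a generator that reproduces the features
the method actually relies on: two or more fields with a configurable
dual-tagging fraction (default 0.2), Zipf-distributed journal sizes
(exponent 1.2), and a sequential citation process — each article draws
`Poisson(lambda = 5)` references among earlier articles, within its own
field(s) with probability 0.9, choosing targets proportionally to
`(in-degree + 1)^gamma` with `gamma = 1` so in-degrees are heavy-tailed.
Citations only point backward in generation order, giving an acyclic
graph with realistic dangling structure (the oldest articles cite nothing
inside the corpus) and no self-citations. Planted field-favored articles
have their selection weight multiplied by a boost, but only when the
citing article belongs to the favored field; they are dual-tagged so they
appear in affinity tables. The recovery experiment — 2 fields, 400
articles per field, 100 replicates, 10 planted articles at boost 3 —
checks that the full pipeline ranks planted articles above background on
the affinity difference across seeds. The generator writes the exact
input formats of the loaders, so end-to-end runs exercise the real I/O
path.

What the generator does not emulate: temporal metadata, realistic venue
or year marginals, citation cartels, or the sheer scale of a real index.
Passing tests therefore demonstrate the machinery's correctness and
sensitivity at desk scale, not effect sizes on real literature.

## Numerical and design choices

* Medians of even-sized groups are arithmetic midpoints; all rank ties
  break lexicographically, so outputs are byte-reproducible.
* Percentile comparisons are strict (`<`); exact floating-point ties are
  measure-zero but the rule is fixed.
* All randomness flows from explicit seeds; ensemble replicate `i` uses
  `base_seed + i`, and `shuffle_network(seed =)` restores the caller's
  RNG state.
* Empty splits, empty ensembles, unknown headings, and non-convergence
  raise structured errors or warnings rather than propagating NA.
* Problem sizes in the test-suite experiments (150-400 articles per
  field, 30-101 replicates) were chosen as the smallest scales at which
  the statistical checks have power.

## Worked example

```{r example, eval = FALSE}
library(fieldrank)

pl <- synthetic_planted(n = 10, field_index = 1, boost = 3)
corpus <- generate_corpus(n_per_field = 400, planted = pl, seed = 101)
tree <- annotate_counts(generate_tree(2), corpus)
fields <- select_fields(tree, threshold = 100)$id

cfg <- pipeline_config(n_replicates = 100, min_shared_articles = 10,
                       seed = 201)
res <- run_field_pair(corpus, fields[1], fields[2], cfg)

head(res$affinity)          # planted articles rise to the top
res$pearson_r               # PageRank correlation between the fields
head(res$journals[[1]])     # field-specific journal ranking
```

## Known limitations

* The three-edge-swap chain mixes empirically, not provably; no spectral
  or coupling bound is computed.
* Percentiles from a single ensemble are jointly dependent across
  articles (see above); only differences and per-article comparisons are
  safe to interpret.
* The journal score inherits PageRank's scale, which depends on network
  size; scores are comparable within a field, not across fields.
* The eligibility filter (language, publication type) relies entirely on
  the metadata sidecar; the citation dump itself carries no such
  attributes.
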