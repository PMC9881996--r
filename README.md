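# fieldrank

Field-specific article importance in citation networks.

Citation metrics are usually computed globally, yet the importance of a
paper is not one number: an article central to microscopy may be
peripheral to nanotechnology even when both fields cite it. `fieldrank`
quantifies this. For a pair of fields it builds the combined directed
citation network over articles tagged with either field (citing article →
cited article, cross-field citations included), computes PageRank within
each field's own network, and then scores every article against an
ensemble of degree-preserving random networks generated with the directed
**three-edge swap** (`a→b→c→d` rewired to `a→c, c→b, b→d`, which preserves
every node's in- and out-degree exactly). The article's **percentile** is
the percent of shuffled replicates in which its PageRank falls below its
true value — 100 means far above what its citation counts alone predict, 0
far below — and the difference of its percentiles in two fields is its
**field-specific affinity**. Journals are ranked per field by the median
PageRank of their articles.

The package is intended for scientometricians and anyone studying
field-normalized impact: it covers corpus loading (OpenCitations-style
DOI-pair CSV plus a metadata sidecar), field selection from a MeSH-style
heading hierarchy by a recursive ≥-threshold rule, network construction
and splitting, null-ensemble generation, percentile and affinity scoring
with missingness filtering, journal metrics, and a synthetic corpus
generator (preferential attachment, cross-field citations, planted
field-favored articles) so the whole pipeline runs end to end without any
external data.

## Worked example

```r
library(fieldrank)

# two-field synthetic corpus with 10 planted field-1-favored articles
pl <- synthetic_planted(n = 10, field_index = 1, boost = 3)
corpus <- generate_corpus(n_per_field = 400, planted = pl, seed = 101)
corpus
#> citation_corpus: 3998 citations, 800 articles, 800 eligible

tree <- annotate_counts(generate_tree(2), corpus)
fields <- select_fields(tree, threshold = 100)$id
fields
#> [1] "H01.001" "H01.002"

cfg <- pipeline_config(n_replicates = 100, min_shared_articles = 10,
                       seed = 201)
res <- run_field_pair(corpus, fields[1], fields[2], cfg)

head(res$affinity, 5)
#>                doi  fieldA  fieldB percentileA percentileB difference
#> 1 10.5555/art00050 H01.001 H01.002          24          86        -62
#> 2 10.5555/art00051 H01.001 H01.002           1          55        -54
#> 3 10.5555/art00388 H01.001 H01.002          96          50         46
#> 4 10.5555/art00112 H01.001 H01.002          46          90        -44
#> 5 10.5555/art00169 H01.001 H01.002          94          53         41

res$pearson_r
#> [1] 0.996743
```

The affinity table lists articles shared by the two fields, sorted by how
asymmetric their importance is: `difference = percentileA - percentileB`,
so `-62` marks an article valued far above its degree expectation in
field 2 but not in field 1. The planted articles shift toward positive
differences (mean `+6.7` against a background of `-0.6` in this run), and
`res$journals` holds the per-field journal rankings by median PageRank.

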