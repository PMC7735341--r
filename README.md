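# songculture

Quantitative comparison of humpback whale song cultures from symbolic
transcriptions.

Male humpback whales sing a population-specific song with hierarchical
structure — units form phrases, repeated phrases form themes, themes in
stereotyped order form a song cycle — and all males on a breeding ground
converge on the same song within a year. Songs recorded in a migratory
corridor can therefore be matched to breeding-population songs to infer
migratory destinations, and year-to-year song change (gradual
*evolution* vs wholesale *revolution* with no shared themes) traces
cultural transmission between populations. This package implements the
full comparison pipeline for researchers working with transcribed song:

* **Sequence similarity** — Levenshtein distance and the Levenshtein
  similarity index, `LSI(a,b) = 1 − LD(a,b) / max(|a|,|b|)`, with
  pairwise similarity matrices, median strings (the member of a set
  maximising its summed pairwise LSI) and within-set similarity
  (`levenshtein()`, `lsi()`, `similarity_matrix()`, `median_string()`).
* **Phrase-type verification** — each qualitative phrase type must be
  more similar within itself than to any other type
  (`verify_phrase_types()`).
* **Song matching** — sequence-aware LSI over theme strings (full data
  or per-recording median strings) and the order-free Dice similarity
  index `DSI(A,B) = 2|A∩B| / (|A|+|B|)` on theme presence
  (`song_lsi_matrix()`, `dsi_matrix()`).
* **Clustering with support** — UPGMA/single/WPGMA linkage on
  1 − similarity, linkage selection by cophenetic correlation (CCC),
  and a multiscale bootstrap yielding approximately-unbiased (AU) edge
  support from the weighted least-squares fit
  `qnorm(1 − BP) ≈ v·σ + c/σ`, `AU = 1 − Φ(v − c)`; AU > 0.95 marks
  stable divisions (`linkage_cluster()`, `cophenetic_correlation()`,
  `bootstrap_support()`, Newick export via `write_newick()`).
* **Unit-label validation** — random-forest agreement between
  qualitative unit names and 11 measured/derived acoustic parameters
  (1000 trees, mtry = 3), reporting the out-of-bag error, confusion
  matrix and variable importance (`derive_features()`,
  `rf_agreement()`).
* **Presence timelines** — daily percentage of duty-cycled files
  containing song per site, and the cessation rule requiring five
  consecutive fully recorded song-free days (`daily_presence()`,
  `cessation_date()`).
* **Synthetic corpora** — a generative model of multi-lineage song
  cultures (theme evolution, revolution, lettered phrase variants,
  symbol-level transcription noise) with full ground truth, so the
  whole pipeline is testable without audio (`table3_scenario()`,
  `generate_corpus()`, `generate_unit_features()`).

## Worked example

Simulate the default two-population scenario and run the pipeline
(`analysis/01…06` scripts do the same with commentary):

```r
library(songculture)

corp <- generate_corpus(table3_scenario(), seed = 1)
corp
#> Synthetic song corpus: 24 recordings, 316 phrase strings, 120 song strings, 16 themes

count_variant_themes(corp$phrases)
#> [1] 5

# phrase-type verification: no type should be flagged
verify_phrase_types(corp$phrases)
#> Phrase type verification over 21 types
#>   consistent: 21  flagged: 0

# linkage choice by cophenetic correlation
round(phrase_clustering_ccc(corp$phrases), 4)
#>          average           single weighted_average
#>           0.9675           0.9374           0.9598

# median song strings, UPGMA, multiscale bootstrap
bs <- bootstrap_support(song_groups(corp$songs), "median",
                        B = 1000, seed = 42)
partition_support(bs, corp$ground_truth$lineages$green)
#> $au
#> [1] 1
#> $bp
#> [1] 1
#> $found
#> [1] TRUE
```

The 16 themes and 5 variant-bearing themes are structural properties of
the scenario; the CCC values say average linkage represents the phrase
similarity structure best (anything above 0.8 is conventionally good);
and the AU = 1 on the lineage partition says the split between the two
song lineages — the revolutionary song versus everything else — is
recovered with maximal bootstrap support despite 5% per-symbol
transcription noise.

Unit-label validation brackets its two regimes:

```r
rf_agreement(generate_unit_features(2, 10, 100, seed = 31), seed = 31)$oob_error
#> [1] 0          # fully separable classes
rf_agreement(generate_unit_features(2, 0, 100, seed = 31), seed = 31)$oob_error
#> [1] 0.545      # indistinguishable classes: chance level
```

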