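---
title: "Methods: quantitative comparison of humpback whale song cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative comparison of humpback whale song cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songculture)
```

## The problem and the data model

Male humpback whales sing a population-specific, hierarchically
structured song: *units* (single continuous sounds) are produced in a
stereotyped order to form a *phrase*; a phrase repeated several times is
a *theme*; and the themes of one rendition follow a stereotyped order
forming a *song cycle*. Because all males on a breeding ground converge
on the same song within a year, the song recorded on a migratory
corridor can be matched to a breeding population's song and used to
infer migratory destination; and because songs change — gradually
(*evolution*, with themes carried over year to year) or wholesale
(*revolution*, a replacement song sharing no themes) — song comparison
also traces cultural transmission between populations.

This package works entirely at the symbolic level: transcribed unit
sequences (phrase strings), theme-ID sequences (song strings) and theme
presence/absence sets, held in plain CSV-backed data frames (see
`?"corpus-format"`). Audio analysis — detection, spectrogram reading,
unit segmentation — is out of scope; transcriptions are the input.

Two conventions matter downstream. Phrase types are an integer plus an
optional single uppercase variant letter (`2A`), and the theme ID is the
integer part, so variant phrases collapse onto one theme in song-level
analyses. Song strings record each theme once, in first-occurrence
order, however many times its phrase was repeated
(`song_string_from_theme_sequence()`).

## Sequence similarity: LD, LSI, median strings

The core statistic is the Levenshtein distance LD(a, b) — the minimal
number of unit-cost insertions, deletions and substitutions turning one
symbol sequence into the other; no transpositions, since only those
three operations define the metric used here. It is normalised into the
Levenshtein similarity index,

$$\mathrm{LSI}(a,b) = 1 - \frac{\mathrm{LD}(a,b)}{\max(|a|,|b|)},$$

a proportion in [0, 1] with 1 for identical sequences. We report
similarities throughout and convert to dissimilarity 1 − LSI only for
clustering. The dynamic programme is implemented in C++ (two-row table,
O(nm) time) because the pairwise matrices and bootstrap below need
millions of short-sequence comparisons; the test suite pins it against
an independent quadratic-space R implementation, exhaustively over a
small alphabet and on random longer pairs, and against `utils::adist`.

A set of strings (the renditions of one phrase type, or one recording's
song cycles) is condensed to its **median string**: the member whose
summed pairwise LSI to all the others is largest. Ties are broken by the
smallest input index, which makes results order-stable and means
duplicating the whole set never changes the winner. A singleton set is
its own median with score 0 and within-set similarity 1 by convention.
Within-set similarity is the mean of the off-diagonal upper triangle
only — including the unit diagonal would inflate the statistic.

Phrase-type assignments are verified by requiring each type's
within-type mean LSI to strictly exceed its mean LSI to every other
type (`verify_phrase_types()`); types failing this are flagged for
re-examination rather than silently reassigned.

## Song matching: sequence-aware and order-free

Songs are matched across locations and years two ways.
`song_lsi_matrix()` runs the LSI over theme sequences, with each theme
one symbol, either over every song cycle (`mode = "full"`, retaining all
variability) or over one median string per
location/year/song-type/recording group (`mode = "median"`, a point
estimate). `dsi_matrix()` computes Dice's similarity index on theme
sets,

$$\mathrm{DSI}(A,B) = \frac{2\,|A \cap B|}{|A| + |B|},$$

which ignores sequence information entirely and scores only theme
sharing. DSI here operates on themes (variant letters collapsed); a
phrase-type-level count would also be computable from the same tables,
but the presence tables are theme-keyed by design.

## Clustering, linkage choice and multiscale-bootstrap support

Similarity matrices are clustered agglomeratively on 1 − similarity via
`stats::hclust`: unweighted average linkage (UPGMA), single linkage, or
weighted average linkage (WPGMA, "mcquitty") for the weighted analysis.
The linkage is chosen by the cophenetic correlation coefficient — the
Pearson correlation between dendrogram-implied and input distances —
with values above 0.8 conventionally considered a good representation.
On both synthetic corpora and published use of these methods, average
linkage wins; single linkage chains (the package's tests construct a
4-item instance demonstrating the chaining effect). Average-linkage
heights are checked for monotonicity on every clustering test run.

Edge stability is assessed with a multiscale bootstrap implemented in
`bootstrap_support()`. The resampling unit is the individual string
within its group (a recording's song cycles): the data do not dictate
this uniquely — resampling matrix columns or whole recordings would
also be defensible — so it is recorded as a design choice; strings are
the natural observation unit behind an LSI matrix. For each resampling
ratio $r$, every group's members are resampled with replacement to
$\mathrm{round}(r \cdot n)$, the group-level matrix and tree are
recomputed, and BP(edge, r) is the fraction of replicates containing
the edge's exact leaf set. The approximately-unbiased value is then
obtained by weighted least squares on the normal-quantile transform:
with $\sigma^2 = 1/r$,

$$\Phi^{-1}\!\bigl(1 - \mathrm{BP}(\sigma^2)\bigr)
  \approx v\,\sigma + c\,/\,\sigma, \qquad
  \mathrm{AU} = 1 - \Phi(v - c),$$

where $v$ is the signed distance and $c$ the curvature of the cluster
boundary, and the weights are the binomial information
$B\,\phi(z)^2 / (\mathrm{BP}(1-\mathrm{BP}))$. AU > 0.95 is the
conventional stability threshold.

Numerical edge cases are handled explicitly: edges present in every
replicate at every scale get AU = 1; profiles with fewer than two
informative scales (all BP at 0 or 1 bar one) cannot support the
two-parameter fit and fall back to BP at $r = 1$, flagged `degenerate`;
with a single unit scale the method degrades to the ordinary bootstrap
and AU ≡ BP. The default scale set is ten ratios log-spaced over
[1/1.4, 1.4]; an even-length symmetric log grid cannot contain 1.0
exactly, so the grid point nearest 1 is snapped to 1.0, keeping the
plain-bootstrap scale in the set. Scales under which any group would
shrink below one member are skipped with a warning. One master seed
spawns an independent stream per scale, so results are identical for
identical seeds regardless of the order scales are processed in.

Two cluster targets are offered. `"median"` mirrors the point-estimate
analysis: leaves are recordings, each represented by the median string
of its resampled cycles. `"full"` retains within-recording variability
by using the mean cross-group pairwise LSI as the group-to-group
similarity. A dendrogram whose leaves are the individual strings
themselves cannot be bootstrapped this way — its leaf sets have no
stable identity under per-group resampling — which is why both targets
keep recordings as leaves; this is the one place the package
deliberately reshapes the "full dataset" analysis to make support
values well-defined.

## Unit-label validation by random forest

`derive_features()` turns measured unit parameters into the
12-parameter description (duration; bandwidth = high − low; peak, high,
low, start and end frequency; frequency trend = start ÷ end; frequency
range = high ÷ low; inflection count; pulse rate; qualitative name).
`rf_agreement()` grows a random forest (default 1000 trees, 3 variables
per split, via the `randomForest` package) predicting the qualitative
name from the 11 numeric parameters; the out-of-bag error measures how
well the subjective classification is supported by the measurements. No
class balancing is applied — the raw OOB rate is the quantity of
interest — and variable importance is the permutation-based mean
decrease in accuracy. Pulse rate of non-pulsed units is encoded as 0,
a choice the data model cannot avoid making since undefined pulse rates
have no numeric representation.

One caution established during testing: duplicating a dataset is *not*
OOB-neutral for overlapping classes, because every observation's
identical twin is in-bag for most trees and the OOB error collapses
toward the training error. Stability under duplication is therefore
only asserted for separable classes.

## Daily presence and the cessation rule

`daily_presence()` reduces duty-cycled file logs (one file per cycle,
graded 0 = no song, 1 = song at low signal-to-noise ratio, 2 = high-SNR
song) to the percentage of files per calendar day containing song of
any quality, per site. The denominator is always the number of files
recorded that day — never seconds of recording — and days without files
are absent rather than zero. Timestamps are taken as local recorder
time; no timezone conversion is applied.

`cessation_date()` implements the rule that song presence has ceased
when the last day with song at any site is followed by at least five
consecutive *fully recorded* song-free days. A full day is one whose
per-site file count reaches the duty-cycle-expected count (96 for a
900 s cycle) within a configurable tolerance; partial deployment or
retrieval days do not count toward the clear run, and a record that
ends before the run completes is reported as right-censored rather than
assigned a date. Whether the original analyses used recorded or
expected files as the denominator on partial days is not stated
anywhere we could verify, so the recorded-file denominator is declared
as this package's convention.

## The synthetic corpus generator

Because the underlying audio and its transcriptions are not
redistributable, every stage is exercised on corpora drawn from a
generative model of song culture (`generate_corpus()`). A *scenario*
fixes the cultural state — one row per population/year/song-type with a
lineage label and an ordered theme set — and the generator draws the
rest: phrase templates of 4–8 units from a 71-unit inventory, a second
consistently-used template (2 substitutions apart) for variant-bearing
themes, 3 recordings per scenario row, 5 song cycles and 2–4 phrase
repetitions per theme per recording, all transcribed through
symbol-level noise. The noise model applies substitution, insertion and
deletion per symbol (defaults 0.02/0.015/0.015, i.e. a 5% per-unit
error) — deliberately the same three operations the Levenshtein
distance counts, so noise magnitude maps directly onto expected LSI.

The shipped default, `table3_scenario()`, mirrors the published
two-population, three-year situation: 16 themes, five of them with
lettered variants, one lineage wholly replaced mid-season by the other
(a revolution with zero theme sharing) while the surviving lineage
evolves with at least one theme carried between consecutive states.
The scenario's theme sets and the identity of the five variant-bearing
themes are fixed structurally in the configuration rather than drawn at
random, so the corpus-level counts (16 themes, 5 variant themes) are
properties of the scenario and hold for every seed; which *unit
sequences* realise the themes, and every transcription, remain seeded
randomness. `random_scenario()` additionally provides the generative
mode: per-year theme gain/loss at a configurable evolution rate and
scripted revolutions drawing disjoint theme blocks, with an error when
the theme inventory is exhausted.

Synthetic unit measurements (`generate_unit_features()`) place class
means at mutual distance `separation` (in within-class standard
deviations) in a latent 8-dimensional space mapped onto the acoustic
parameters so that the invariants (positive frequencies, high ≥ low,
range ≥ 1, bandwidth = high − low) hold by construction; separation 0
makes classes indistinguishable, giving the chance-level oracle for the
random forest.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: acoustic measurement error structure, unequal
recording effort, singer identity (each recording is treated as an
independent individual, as in passive acoustic practice), hybrid songs,
and any within-year temporal drift other than the scripted
evolution/revolution events. Results on synthetic corpora validate the
machinery, not the biology.

## Problem sizes and reproducibility

The analysis scripts and tests run the default scenario (24 recordings,
~320 phrase strings, 120 song strings) with B = 1000 bootstrap
replicates at 10 scales; the parameter-recovery suite repeats this over
20 seeds and requires the lineage split to earn AU > 0.95 in at least
18 of 20 corpora. These sizes make the full pipeline a
few-minutes-on-one-core exercise while keeping every statistic in the
regime where its behaviour is interpretable. All randomness flows from
explicit integer seeds; the bootstrap's per-scale streams are derived
from the master seed so partial recomputation cannot silently change
results.

## Known limitations

* The published phrase-string dataset (n = 3183) is not redistributable
  here, so the published cophenetic correlations (0.92 average / 0.61
  single / 0.90 weighted) can only be recomputed once that file is
  supplied; the acceptance test for it fails until then, by design.
* AU values inherit the assumptions of the signed-distance/curvature
  model; profiles outside its regime are flagged degenerate rather than
  extrapolated.
* Dice similarity on very small theme sets is coarse (steps of
  2/(|A|+|B|)); interpret matrices over few-theme songs accordingly.
* The `"full"` bootstrap target averages cross-group similarities and
  is not the same dendrogram as clustering every individual string.
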