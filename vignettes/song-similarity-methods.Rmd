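---
title: "Quantifying humpback whale song similarity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying humpback whale song similarity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalesong)
```

## The data model

Humpback whale song is a nested hierarchy. A *unit* is a single sound
separated from its neighbours by silence; units in a stereotyped order form
a *phrase*; a phrase repeated any number of times is a *theme*; and themes
sung in a particular order compose the *song*. All males in a population
converge on a shared song type at any point in time, while the song itself
evolves continually, so comparing transcribed songs across populations and
years carries information about cultural contact between populations.

`whalesong` works on symbolic transcriptions. A corpus
(`song_corpus()`) holds one record per singer — population, year, an
arbitrary within-population-year id, and one or more *song cycles*, each an
ordered vector of theme labels. Theme labels are atomic tokens: an integer
core with an optional suffix (`s` for shifting themes whose phrases drift
progressively within a song, `E` for a recognizably evolved form of an
earlier theme). `"18"` and `"18E"` are different themes everywhere in the
package; no operation ever compares label cores. Phrase-level data
(ordered unit tokens per theme, population and year) ride along in a
phrase table.

Two packaged fixtures transcribe the published Gabon/Madagascar song
tables from the 2001–2005 field seasons: `table3_themes` (the median theme
sequence per individual singer; 31 singers) and `table2_phrases` (the
median unit sequence per phrase type per population-year; 67 phrase
strings). The fixture files are checksum-pinned in the test suite so any
drift from the transcription fails loudly. The source tables print 31
singer rows although the accompanying text reports n = 32; the fixture
follows the tables.

## Sequence similarity: the Levenshtein distance similarity index

The edit (Levenshtein) distance between two token sequences is the minimum
total cost of single-token insertions, deletions and substitutions turning
one into the other, computed by dynamic programming (in C++; the R surface
is `levenshtein_distance()`). Insertions and deletions always cost 1.

The *Levenshtein distance similarity index* (LSI) normalizes by the longer
sequence:

$$\mathrm{LSI}(a, b) = 100 \times \left(1 - \frac{LD(a,b)}{\max(|a|, |b|)}\right).$$

Dividing by the longer length is the convention that keeps the index in
[0, 100], makes 100 equivalent to identity, and sends unweighted
comparisons of equal-length sequences over disjoint alphabets to 0.

Two variants are used at different levels of the hierarchy:

* **Weighted LSI at the unit level** validates phrase-type groupings.
  Substitution costs come from the acoustic measurements: each unit type's
  standardized 10-feature measurement vector is summarised by its
  per-feature median (`unit_type_centroids()`), and the cost of
  substituting unit $i$ for unit $j$ is
  $(d_{ij}/d_{\max})^\beta$ — Euclidean centroid distance normalized by
  the maximum pairwise distance, so the most dissimilar pair costs exactly
  the indel cost of 1 (`substitution_costs()`). The exponent $\beta$
  defaults to 1 (costs are the normalized distances themselves);
  $\beta = 0$ collapses every off-diagonal cost to 1 and recovers the
  unweighted analysis. `group_phrases()` clusters phrase strings by UPGMA
  on $100 - \mathrm{LSI}$ and cuts at a similarity threshold (default
  70%), replacing the subjective judgement of what counts as "similar
  units in a similar position".
* **Unweighted LSI at the theme level** measures song similarity between
  singers. `singer_pair_lsi()` averages the LSI over all cross pairs of
  two singers' cycles; `self_similarity()` averages over a singer's own
  distinct cycle pairs (with a single recorded cycle the diagonal is set
  to 100 by convention, with a warning). `lsi_matrix()` assembles the
  singer-by-singer matrix with self-similarity on the diagonal.

`median_string()` returns the *set-median* of a collection — the member
minimizing the summed edit distance to all members. The unrestricted
generalized median is NP-hard and unnecessary for reproducing median song
tables; restricting to observed strings also keeps the result
interpretable. Ties break by shortest length, then lexicographic token
order, so the median does not depend on input order.

## Repertoire similarity: Dice's index

Dice's similarity index ignores sequence entirely and asks only which
types two singers share:

$$SI = \frac{2A}{B + C},$$

with $A$ the number of shared types and $B$, $C$ the two repertoire
sizes. `dice_matrix()` applies it at theme level (the union of distinct
theme labels over a singer's cycles) or, where phrase inventories exist,
at phrase level. The published analyses used full phrase-type
inventories; those were never deposited, so from the median-sequence
fixture only theme-level Dice is reproducible. This matters for the
extreme published values: the 2003 between-population bounds (36–62%) and
the 2004/2001/2005 maxima reproduce exactly from the medians, while the
2001/2002 minima and the 2004/2005 minima depended on the unpublished
full inventories and are documented as out of reach rather than asserted.

`between_population_range()` reports the min and max over all
cross-population singer pairs within a year, rounded half-up to whole
percentages — the form in which such ranges are conventionally printed
(`round()`'s round-half-even would turn 36.36 → 36 but 61.54 → 62 either
way; half-up is used for the convention's sake, via `floor(x + 0.5)`).

## Clustering, support and adequacy

`upgma(to_distance(m))` clusters the dissimilarity $100 - \text{similarity}$
(diagonal forced to 0 regardless of self-similarity) by average linkage.
UPGMA output is ultrametric, so the cophenetic correlation
(`cophenetic_correlation()`) recovers 1 exactly on ultrametric input; on
real matrices a CCC of at least 0.8 is conventionally read as the tree
representing the data adequately. The package computes the flag but never
filters on it. Equidistant merge candidates resolve to the lowest-index
pair, making trees deterministic.

### Multiscale bootstrap

`bootstrap_support()` attaches two support values per internal node:

* **BP**, the ordinary bootstrap probability: the fraction of replicates
  (at resampling ratio $r = 1$) in which the node's exact leaf set
  reappears.
* **AU**, the approximately unbiased probability from multiscale
  resampling: replicates are drawn at ten ratios
  $r \in \{0.5, 0.6, \ldots, 1.4\}$ (1000 replicates per scale by
  default), the per-scale recurrence frequencies are probit-transformed,
  $z(r) = \Phi^{-1}(1 - \mathrm{BP}(r))$, and fitted by weighted least
  squares to $v\sqrt{r} + c/\sqrt{r}$ with delta-method binomial weights;
  then $\mathrm{AU} = 100\,(1 - \Phi(v - c))$.

A similarity matrix has no independent observations to resample, so a
resampling convention is required: the matrix's rows are treated as the
features and its columns (the singers) as the objects. Each replicate
draws $\lceil rn \rceil$ rows with replacement and reclusters the singers
by UPGMA on the Euclidean distance between the resampled columns of the
dissimilarity matrix. The assessed tree is built by the same machinery at
full size, so replicate trees and the reference tree are directly
comparable; the realized ratios $\lceil rn \rceil / n$ are used in the AU
fit. This is the convention implied by feeding a similarity matrix to a
row-resampling clustering-support procedure, and it is isolated behind
`bootstrap_config()` so alternatives can be swapped.

Numerical guards: frequencies are clamped to $[1/(B+1), B/(B+1)]$ before
the probit transform (a frequency of exactly 0 or 1 has an infinite
quantile); a node recurring in every replicate at every scale is reported
AU = 100, and one never recurring AU = 0, the boundary cases the fit
cannot reach. Reported BP is the raw recurrence percentage. Significance
annotations use the conventional thresholds AU > 95 and BP > 70.

Calibration, checked in the test suite: on a two-block similarity matrix
(within-block 100, between 0) the true split recurs in every replicate
and both supports saturate; on iid uniform similarity noise at the size
of the packaged corpus (31 singers), fewer than 10% of internal nodes are
flagged at AU > 95 across 20 seeds.

## Acoustic features and classification-tree validation

`standardize_features()` centres and scales each numeric measurement
column (sample, $n-1$, standard deviation), dropping constant columns
with a warning. The schema names the ten standard unit measurements —
minimum/maximum/start/end/peak frequency (Hz), bandwidth (implemented as
max − min, in Hz), frequency range (min/max ratio), frequency trend
(start/end ratio), duration (s) and inflection count — and passes any
extra numeric columns through, so wider tables also work.
`fit_classification_tree()` refits the manual unit labelling with a
Gini-impurity recursive-partitioning tree, pruned by cost-complexity with
the subtree chosen by k-fold (default 10) cross-validated error under the
1-SE rule. Because "root node error" and "agreement" are easily
conflated, the report states both explicitly: the trivial
majority-classifier error and the fraction of rows whose predicted class
matches the manual label. The published corpus's measurement table was
never deposited, so the printed classification figure is not
recomputable; the machinery is validated on synthetic measurement tables
with known class structure instead.

## The cultural-evolution simulator

`simulate_corpus()` generates ground-truthed corpora emulating the
qualitative dynamics the published tables show: one continuous song
lineage, progressive theme turnover, population-specific variants, and
tunable inter-population transmission.

The canonical song of population A mutates once per year:

1. **Death**: each theme is deleted with probability `p_death`.
2. **Evolution**: each surviving un-evolved theme becomes its
   `E`-suffixed form with probability `p_evolve` (mirroring observed
   relabellings such as 18 → 18E and 23 → 23E; an evolved theme does not
   evolve again).
3. **Birth**: `Binomial(initial_themes, p_birth)` fresh themes (globally
   fresh integer labels) are appended.

Births arrive at a constant innovation rate rather than scaling with the
current song, which makes song length an immigration–death process that
reverts to the equilibrium `initial_themes * p_birth / p_death` instead
of drifting: published songs hold a roughly stable 6–9 themes in every
year, and a scaling (branching-process) birth rule lets the song collapse
or balloon over a 5-year horizon. If a year's draws would kill every
theme with no birth, one uniformly chosen theme survives — the lineage
persists, as observed; corpora of this kind show no extinction and no
song "revolutions", and neither is modelled.

With probability `coupling` (m) the mutated sequence replaces population
B's canonical song within the same year — an all-or-nothing stand-in for
song learning on shared migration routes or feeding grounds — otherwise
B mutates independently from its own previous song. Each singer renders
the canonical sequence with each theme omitted with probability `dropout`
(drawn once per singer; a singer silenced entirely keeps one uniformly
chosen theme), identically across that singer's cycles.

Defaults are calibrated to the published tables: 5 years, 4 singers per
population-year (the field samples range 1–4), 6 initial themes (the 2001
song), 5 cycles per singer, and `p_birth = p_death = 0.5`,
`p_evolve = 0.1`. The turnover rate comes from the tables themselves:
consecutive-year canonical theme sets share Dice 0.14–0.53 (7–13 theme
changes per year on 6–9-theme songs), i.e. roughly half the song turns
over yearly, and two theme evolutions occur over four year-transitions of
about seven themes ($\approx 0.07$ per theme-year). `dropout = 0.1`
reflects the modest singer-level deviations the per-singer median
sequences show within a population-year. `coupling = 0.5` is a neutral
default; it is the parameter under study, swept explicitly by
`similarity_vs_coupling()`.

What the simulator deliberately does not reproduce: unit-level acoustic
variation (phrase strings can be attached from the fixture vocabulary,
but no acoustic drift is modelled), within-singer cycle-to-cycle
variability (cycles are identical up to the singer's dropout draw, so
simulated self-similarity is always 100), theme alternations and repeats
within a cycle, and any geography of contact. Passing recovery tests on
simulated corpora therefore demonstrates the pipeline's correctness on
corpora with known structure, not the field realism of any particular
similarity value.

Two recovery properties anchor the simulator to the pipeline: mean
final-year between-population Dice rises monotonically in the coupling
(Spearman $\rho = 1$ over the grid $\{0, 0.25, 0.5, 0.75, 1\}$ with 100
replicate seeds per point in the shipped tests), and UPGMA on a fully
coupled corpus groups singers by year rather than population (mean
adjusted Rand index $\ge 0.9$ against year labels over 20 seeds).

## Determinism and numerical conventions

* Every stochastic component (simulator, bootstrap, fold assignment)
  takes an explicit seed and restores the caller's RNG state; identical
  seed and parameters give bit-identical output.
* Set-median ties: shortest, then lexicographic token order. UPGMA
  ties: lowest-index pair. Cut thresholds are closed from the similar
  side (`cut = 70` keeps pairs at exactly 70% together).
* Degenerate inputs error early and by name: empty transcription files,
  position gaps, duplicate singer keys, tokens missing from a cost
  matrix, all-constant feature tables, sub-2-row bootstrap scales,
  distance matrices with asymmetries beyond $10^{-9}$.
* Newick export halves merge heights to node depths so leaf-to-leaf path
  length equals the cophenetic distance; internal nodes carry `AU/BP`
  labels; labels containing Newick metacharacters are single-quoted.
* Problem sizes in the shipped test suite are chosen to exercise each
  property at the scale of the packaged corpus (31 singers) or below;
  the edit-distance engine is verified exhaustively against independent
  oracles on all ~1.2 million ordered string pairs up to length 6 over a
  3-symbol alphabet and on random weighted instances.

## Known limitations

* Theme-level Dice from median sequences is a lower-information surface
  than the full phrase-type inventories the original analyses used; only
  the published values that survive that reduction are asserted.
* The LSI self-similarity diagonal is only meaningful for singers with
  multiple recorded cycles; the packaged fixture has one (median) cycle
  per singer, so its diagonal is the conventional 100.
* The multiscale-bootstrap resampling convention for similarity matrices
  is one of several defensible choices; it is configurable, and support
  values should be read as relative, not as calibrated p-values, at small
  replicate counts.
* Cost matrices assume every unit token was measured; unmeasured tokens
  must be added to the measurement table before weighted analyses.
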