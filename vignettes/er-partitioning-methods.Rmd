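---
title: "Methods: calling hypoxia-regulated mRNA partitioning between cytoplasm and ER"
author: "erpartition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling hypoxia-regulated mRNA partitioning between cytoplasm and ER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpartition)
```

# The scientific problem

Under hypoxia, cells suppress global protein synthesis, yet certain
transcripts — notably targets of the HIF transcription-factor network —
continue to be translated. One mechanism is selective partitioning of the
transcriptome: mRNAs that remain translated are enriched at
endoplasmic-reticulum (ER)-bound ribosomes, while bulk cytoplasmic
transcripts are not. Detecting this requires comparing two RNA fractions
(whole-cell "total" RNA and ER-associated RNA) between control and hypoxic
conditions, intersecting the resulting regulated gene sets, and then asking
what distinguishes the 5'/3' untranslated regions (UTRs) of transcripts
that are induced *and* ER-enriched: fewer upstream AUGs, higher basewise
evolutionary conservation, and specific cis-elements.

`erpartition` implements that computational chain as a reusable, tested
pipeline: regulation calling in each fraction, six-way group intersection,
UTR feature analysis, rank-based and linear group statistics, gene-set
enrichment, and discriminative IUPAC motif discovery — together with a
synthetic-data generator that plants every effect the pipeline is supposed
to detect, so each stage can be validated against known ground truth
without any external download.

# Regulation calling with one array per condition

## The expression filter

The design pools biological replicates onto a single array per fraction and
condition, so the expression matrix has exactly four columns. Genes whose
mean log2 intensity over all samples falls strictly below the 50% quantile
(linear-interpolation definition) are set aside as not expressed; ties at
the threshold are retained. The filter runs once on the combined
four-sample summary, so both fractions share one expressed-gene universe —
that makes the later set intersection well defined.

## The mean–SD loess model and the z-score

With no replicates, per-gene variance cannot be estimated directly.
Instead the pipeline exploits the mean–variance trend across genes. For a
fraction, each gene contributes `M` (log2 hypoxia − log2 control) and `A`
(their mean). Two robust local regressions are fitted:

* `trend(A)` — a loess fit of `M` on `A` (span 0.3, degree 2, Tukey
  biweight robustness iterations);
* `spread(A)` — a loess fit of `c · |M − trend(A)|` on `A` with the same
  settings.

The z-score is `z = (M − trend(A)) / spread(A)`, and a gene is called
regulated when both criteria hold: linear fold change above 1.4
(`|M| ≥ log2 1.4 ≈ 0.485`) and `|z| ≥ 3`, with the signs of `M` and `z`
agreeing. Both thresholds are two-sided because up- and downregulated sets
are both of interest; each direction applies its one-sided pair of
conditions.

Numerical choices worth recording:

* **Consistency constant.** `c = 1.379` by default. The usual 1.4826 is
  the consistency constant of the *median* of absolute deviations; the
  biweight local regression used here converges to the biweight location
  of the half-normal residual distribution, which is 0.725 σ, so its
  reciprocal makes `spread(A)` a Fisher-consistent estimate of the
  Gaussian SD. With 1.4826 the spread overestimates σ by about 7%,
  which visibly miscalibrates the z-scores in simulation. The constant is
  an exposed argument for users who prefer the MAD convention.
* **Robustness.** The biweight iterations keep genuinely regulated genes
  (outliers in `M`) from inflating the spread. This has a breakdown
  point: simulations with more than roughly a quarter of genes regulated
  contaminate the spread fit and cost sensitivity. The study-like regime
  (≈ 10–15% regulated) is comfortably inside it.
* **Boundary rule.** Outside the fitted `A` range, `trend` and `spread`
  are evaluated at the nearest boundary rather than extrapolated, to
  avoid spurious tail z-scores; the spread is floored at `1e-6`.
* **Degenerate input.** If all `M` are equal (or all residuals vanish)
  the spread is undefined and the fit aborts with an error rather than
  returning zero spread.

## Six-way intersection

Calls from the two fractions are intersected into six sets per the
direction (up/down) × localization (total-only, intersect, ER-only)
layout, plus the unchanged remainder. Genes filtered in either fraction
are excluded from all six sets. The construction guarantees the identities
`|up_total_only| + |up_intersect| = |up in total|` and
`|up_er_only| + |up_intersect| = |up in ER|` (same for down), which the
pipeline re-asserts at run time.

# UTR features

Transcript models are BED12-like (0-based, half-open; conversion from
1-based interchange formats is the reader's job). The 5'UTR is the spliced
sequence upstream of the CDS start in mRNA orientation, the 3'UTR the part
downstream of the CDS end; minus-strand transcripts are
reverse-complemented. Only UTRs of at least 30 nt enter the analysis — a
shorter UTR is excluded, not scored zero.

* **uAUG count** — every `ATG` trinucleotide in the 5'UTR, regardless of
  reading frame and counting overlaps (uAUGs need not be functional uORFs;
  the raw count is the feature). `N` never matches.
* **AUG score** — uAUG count divided by UTR length (per-nucleotide rate).
* **Mean conservation** — the arithmetic mean of a basewise (phyloP-style)
  conservation track over exactly the exonic UTR positions. Positions
  missing from the track are skipped and do not enter the denominator (an
  optional zero-fill mode exists but is off by default, since genome
  tracks legitimately have gaps). Intronic bases are never counted, and
  the value is strand-independent.

The default analysis unit is the transcript; a gene-centered mode averages
feature values over a gene's transcripts. The synthetic genome has exactly
one transcript per gene, so the distinction only matters on real
annotation.

# Group statistics

* **Scheirer–Ray–Hare rank ANOVA.** AUG scores are compared with respect
  to localization (total-only / intersect / ER-only) and direction
  (up / down): mid-ranks over all observations, a two-way sum-of-squares
  decomposition on the ranks (type II for unbalanced designs, which the
  six groups always are), and `H = SS_effect / (SS_total/(N−1))` against
  the chi-square upper tail with the effect's degrees of freedom. Because
  mid-ranks already absorb ties into `SS_total`, no separate
  tie-correction divisor is applied; the classical correction factor is
  reported for reference. Textbook presentations differ on these points,
  so the implementation is locked by an exhaustive small-design oracle
  suite (exact agreement with an independent type-II rank decomposition)
  and by a null simulation keeping the empirical type-I error at
  0.05 ± 0.02. Designs with empty cells warn and report the nominal
  interaction degrees of freedom.
* **Linear ANOVA + Tukey contrasts.** UTR conservation is compared across
  groups with a classic equal-variance one-way ANOVA and single-step
  studentized-range (Tukey HSD) adjusted pairwise p-values. A group
  significantly higher than every other group is flagged `#`, lower than
  every other `*` — the reporting convention used for group-wise
  conservation comparisons in this field.
* **Hypergeometric enrichment.** Gene-set enrichment of a candidate group
  against a user-supplied GMT-like annotation: upper-tail hypergeometric
  p per term, BH adjustment across tested terms, terms with candidate
  overlap below 2 not reported, top 10 returned. The universe defaults to
  the expressed genes after the 50% filter, not the whole annotation,
  since unexpressed genes were never eligible. (A web-service enrichment
  with database-version-dependent term content is deliberately out of
  scope; the internal test is the reproducible equivalent.)

# Discriminative motif discovery

Motifs are IUPAC words of widths 4–8 with 2- or 3-letter bracket classes
(`C[C,G,A]GCGC`), matched on the mRNA strand only — the inputs are UTRs,
so reverse-complement matching would be wrong. Discovery compares a
positive set (a subgroup's UTRs) with a reference set (the complete UTR
set for that side, positives removed) using the one-tailed Fisher exact
test on sequence-level presence:

1. enumerate every exact word of each width present in the positives and
   score it;
2. refine the top 100 words by greedy position-wise generalization to
   classes;
3. report the best motif while its E-value is below 0.05, erase all of
   its sites (mask with `N`) in both sets, and repeat.

Two design choices depart from a naive greedy-and-count scheme, both
driven by null calibration (on positives drawn at random from the
reference, the procedure must report nothing):

* **Penalized acceptance.** A generalization step is accepted only when it
  improves the Fisher p by more than the number of alternative moves
  examined in that pass. Plain "accept any improvement" lets the greedy
  search overfit small positive sets, because the best of ~70 candidate
  moves improves p by chance alone. Accepted steps still strictly
  decrease p.
* **Search-space E-value.** `E = p × N`, where `N` counts every
  enumerated word *times all of its reachable generalizations* (up to
  `max_general = 2` class positions; published UTR cis-elements carry at
  most two). Counting only the candidates the greedy path happened to
  evaluate understates the selection and reports junk motifs on null
  inputs. The cap at two class positions both matches the observed
  structure of UTR elements and bounds the search multiplicity.

Ties in p are broken lexicographically on the rendered motif string, so
discovery is fully deterministic. Per-transcript cis-element burden is the
site-level count (overlapping sites all counted) of the discovered 5'
motifs in a transcript's 5'UTR plus the 3' motifs in its 3'UTR.

# The synthetic-data generator

The generator emulates the study design, not merely a fixture: every
planted quantity is recorded as ground truth.

* **Expression.** One sample per fraction × condition. Control
  intensities are N(7, 2) on the log2 scale (the ER control adds a small
  correlated offset); hypoxia values add the planted effect —
  ±1.5 log2 units in the compartments dictated by the gene's group — and
  heteroscedastic noise `sd(A) = a + b·e^{−cA}` with defaults
  `(0.1, 1.4, 0.35)`: about 1.5 at the intensity floor, 0.4 at A ≈ 4.4,
  asymptote 0.1. The curve must stay bounded at the floor — a noise model
  that explodes at low intensity leaks low-baseline genes past the mean
  filter with enormous log-ratios. Group proportions default to
  study-like sizes (≈ 14.5% regulated overall, split across the six
  groups).
* **UTRs.** One transcript per gene, 1–3 exons, alternating strands, ~100
  transcripts per synthetic contig. 5'UTRs are GC 0.60 (60–300 nt),
  3'UTRs GC 0.45 (100–600 nt). Background ATGs are scrubbed
  (GC-neutrally) so the planted per-group uAUG rate is exact:
  0.010 /nt by default, 0.014 in the up-total-only group, 0.004 in the
  up-intersect group — the "more uAUGs in total-only, fewer in the
  ER-translated intersect" pattern the statistics are meant to detect. A
  CCGCGC 5' element and an AU-rich `TTTA[C,G,A]AAA` 3' element are
  planted preferentially in the up-intersect group (30% / 25% vs 2%
  background), with one concrete word instantiated per IUPAC class
  insertion.
* **Conservation.** Every exonic base receives N(0, 1); UTR bases of
  up-intersect transcripts are shifted by +1.0. True per-UTR means are
  recorded from the emitted track.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: probe-level artifacts and normalization
(inputs are assumed RMA-normalized), batch effects, correlated biological
pathway structure, multi-isoform genes, alternative UTR usage, and the
composition biases of real UTR sequence (beyond GC content). Results on
GEO-derived matrices additionally depend on the annotation and
normalization choices made upstream.

# Problem sizes and reproducibility

All randomness flows from a single integer seed per generator call
(stages derive fixed offsets), and fixed seeds give byte-identical
outputs. The bundled analysis scripts and the acceptance script use
10^4 genes for expression-level operating characteristics and a
2000-gene sequence-scale set for the UTR/conservation/motif stages, with
1200-gene runs (200 per regulated group) for the repeated rank-ANOVA
detection checks and 100 seeded null runs for motif calibration — sizes
chosen so each planted effect is detected with comfortable statistical
margin while a complete run stays desk-scale.

# Known limitations

* The spread model assumes a smooth mean–SD relationship across genes; it
  cannot express gene-specific variance, and heavy contamination
  (> ~25% regulated genes) degrades it.
* The published regulated-set counts from the original microarray study
  depend on that study's exact normalization and annotation and are not
  reproduced here; the pipeline's claims are calibration and recovery
  properties on data with known truth, plus exact agreement of every
  statistical primitive with brute-force oracles.
* Motif discovery reports short IUPAC elements only — no position-weight
  matrices, no strand search, no secondary-structure context — and its
  E-value is a Bonferroni-style bound, i.e. conservative for weak motifs.
* The conservation mapper trusts the track's coordinates; it does not
  recompute conservation from alignments.
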