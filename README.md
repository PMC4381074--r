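# erpartition

Calling hypoxia-induced transcriptome partitioning between the cytoplasm
and the endoplasmic reticulum (ER), and characterizing the UTRs of the
transcripts that escape translational shutdown.

Under hypoxia, bulk mRNA translation is suppressed, but transcripts that
localize to ER-bound ribosomes — prominently HIF-network targets — keep
being translated. The computational question: given expression profiles of
two RNA fractions (whole-cell *total* RNA and ER-associated RNA) under
control and hypoxia, which genes change in which compartment, and what
distinguishes the 5'/3' untranslated regions (UTRs) of genes induced in
*both* fractions? This package implements the full analysis chain for the
pooled single-array-per-condition design, plus a synthetic-data generator
with planted ground truth that makes every stage testable offline.

## The model

For each fraction, every gene contributes a log-ratio and mean intensity

```
M = log2(hypoxia) - log2(control),   A = (log2 hypoxia + log2 control) / 2.
```

Because the design has no replicates, the spread of `M` is modelled across
genes as a function of `A` with two robust loess fits (the mean–SD loess
model): `trend(A)` on `M`, and `spread(A)` on `c·|M − trend(A)|`
(`c = 1.379`, the consistency constant for a biweight location fit of
half-normal absolute residuals). Each gene is standardized,

```
z = (M - trend(A)) / spread(A),
```

and called regulated when both `|FC| > 1.4` (i.e. `|M| ≥ log2 1.4`) and
`|z| ≥ 3`, signs agreeing, after discarding genes below the 50% expression
quantile. Calls from the two fractions are intersected into six groups —
`{up,down} × {total_only, intersect, er_only}` — whose UTRs are then
compared: uAUG counts and AUG score (`uAUGs / UTR length`, UTRs ≥ 30 nt),
mean basewise conservation over exonic UTR positions, Scheirer–Ray–Hare
rank two-factor ANOVA (localization × direction), linear ANOVA with Tukey
contrasts, hypergeometric gene-set enrichment (BH-adjusted), and
DREME-style discriminative IUPAC motif discovery against the complete UTR
set with Fisher exact statistics and motif-erasure iterations.

See `vignettes/er-partitioning-methods.Rmd` for the full account of the
model, parameter defaults, and design decisions.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # expression + genome + UTRs + conservation
Rscript analysis/02_partition.R     # regulation calls, six-way groups
Rscript analysis/03_utr_features.R  # UTR lengths, uAUGs, conservation
Rscript analysis/04_group_stats.R   # SRH, Tukey, enrichment
Rscript analysis/05_motifs.R        # motif discovery + cis-element counts
```

A complete run takes about two minutes and prints, among other things:

```
[main] up_total_only=174  up_intersect=106  up_er_only=127  down_total_only=163
       down_intersect=88  down_er_only=124  unchanged=4219
caller sensitivity 0.995; false-call rate 0.0038 (n = 5001 expressed)
median AUG score: up_intersect 0.0000 vs unchanged 0.0084
mean 5' conservation: up_intersect 1.009 vs unchanged -0.000
SRH on AUG score:
           term df         H            p
       location  2 16.317149 0.0002862702
          level  1  2.903605 0.0883817000
 location:level  2  6.302450 0.0427996749
[5p] ANOVA F p = 2.19e-104; flags: up_intersect #
[5p] 33 positives vs 1967 reference: 1 motif(s)
   word pos_with ref_with            p            E
 CCGCGC       30      283 7.057658e-22 2.348166e-14
mean cis-element sites per transcript by group:
 ... up_intersect 1.18 ... unchanged 0.13 ...
```

Reading: the caller recovers 99.5% of the planted regulated genes with a
0.4% false-call rate and reproduces the planted six-way group structure;
the up-intersect group has the planted lower uAUG rate (AUG-score median
0 vs 0.0084; SRH localization effect p ≈ 3·10⁻⁴), carries the planted
+1.0 conservation shift (flagged `#`: higher than every other group in the
Tukey contrasts), yields its planted CCGCGC 5' element back from motif
discovery (E ≈ 2·10⁻¹⁴), and shows the highest cis-element burden per
transcript.

The same functions run on real inputs: a normalized expression TSV
(two-line header: sample ids, then `fraction:condition` labels), a genome
FASTA, transcript models as BED12, a fixedStep wig or bedGraph
conservation track, and a GMT-like annotation. `run_pipeline(run_config(...))`
chains all stages for either synthetic or file-based inputs.

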