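#!/usr/bin/env Rscript

# Stage 3 — UTR feature extraction on the sequence-scale set: per-transcript
# 5'/3' UTR length, uAUG count, AUG score (count/length, >= 30 nt only) and
# mean basewise conservation over exonic UTR positions.

suppressPackageStartupMessages(library(erpartition))

out <- "results/utr_features"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome("results/synthetic/genome.fa")
models <- read_transcripts("results/synthetic/transcripts.bed")
track <- read_track("results/synthetic/conservation.wig")
groups <- read.delim("results/partition/groups_seq.tsv")

feats <- summarize_features(models, genome, track, groups)
write.table(feats, file.path(out, "features.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (what in c("aug_score", "mean_conservation")) {
  summ <- feature_group_summary(feats[feats$side == "5p", ], what)
  write.table(summ, file.path(out, paste0("summary_5p_", what, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat(nrow(feats), "UTR records ( >= 30 nt ) over",
    length(unique(feats$gene_id)), "genes\n")
f5 <- feats[feats$side == "5p", ]
cat(sprintf("median AUG score: up_intersect %.4f vs unchanged %.4f\n",
            median(f5$aug_score[f5$group == "up_intersect"]),
            median(f5$aug_score[f5$group == "unchanged"])))
cat(sprintf("mean 5' conservation: up_intersect %.3f vs unchanged %.3f\n",
            mean(f5$mean_conservation[f5$group == "up_intersect"]),
            mean(f5$mean_conservation[f5$group == "unchanged"])))
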