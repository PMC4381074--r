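#!/usr/bin/env Rscript

# Stage 5 — discriminative motif discovery in the up-intersect UTRs against
# the complete UTR sets, followed by per-transcript cis-element site
# counting with the discovered motifs.

suppressPackageStartupMessages(library(erpartition))

out <- "results/motifs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome("results/synthetic/genome.fa")
models <- read_transcripts("results/synthetic/transcripts.bed")
groups <- read.delim("results/partition/groups_seq.tsv")
pos_genes <- groups$gene_id[groups$group == "up_intersect"]

utrs <- extract_utrs(models, genome)
utrs <- utrs[utrs$length >= 30, ]

all_motifs <- NULL
for (side in c("5p", "3p")) {
  us <- utrs[utrs$side == side, ]
  pos <- us$seq[us$gene_id %in% pos_genes]
  ref <- us$seq[!us$gene_id %in% pos_genes]  # positives excluded
  run <- discover_motifs(pos, ref, widths = 4:8, e_thresh = 0.05)
  cat(sprintf("[%s] %d positives vs %d reference: %d motif(s)\n",
              side, length(pos), length(ref), nrow(run$motifs)))
  if (nrow(run$motifs)) {
    print(run$motifs[, c("word", "pos_with", "ref_with", "p", "E")],
          row.names = FALSE)
    all_motifs <- rbind(all_motifs, cbind(side = side, run$motifs))
  }
}
write.table(all_motifs, file.path(out, "motifs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

if (!is.null(all_motifs)) {
  u5 <- utrs[utrs$side == "5p", ]
  u3 <- utrs[utrs$side == "3p", ]
  u3 <- u3[match(u5$transcript_id, u3$transcript_id), ]
  counts <- scan_counts(all_motifs$word[all_motifs$side == "5p"],
                        all_motifs$word[all_motifs$side == "3p"],
                        u5$seq, ifelse(is.na(u3$seq), "", u3$seq))
  scan_df <- data.frame(transcript_id = u5$transcript_id,
                        gene_id = u5$gene_id,
                        group = groups$group[match(u5$gene_id,
                                                   groups$gene_id)],
                        cis_element_sites = counts)
  write.table(scan_df, file.path(out, "scan_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  agg <- tapply(scan_df$cis_element_sites, scan_df$group, mean)
  cat("mean cis-element sites per transcript by group:\n")
  print(round(agg, 2))
}
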