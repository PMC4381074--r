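#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study: a pooled-design expression table
# (one array per fraction x condition), transcript models with 5'/3' UTR
# sequences on synthetic contigs, and a basewise conservation track, all
# with known ground truth.
#
# Conditions mirror the reference design: 10^4 genes for the expression
# contrasts; a 2000-gene sequence-scale subset (same generator, own seed)
# for the UTR/conservation/motif stages, where per-base work dominates.

suppressPackageStartupMessages(library(erpartition))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg_expr <- simulation_config(seed = 20240901)
ex <- simulate_expression(cfg_expr)
write_expression(ex$table, file.path(out, "expression.tsv"))
write_ground_truth(ex$truth, file.path(out, "ground_truth_expression.tsv"))
cat("expression: ", nrow(ex$table$mat), "genes;",
    sum(ex$truth$genes$group != "unchanged"), "planted regulated\n")

up <- simulation_config()$utr_params
up$planted_motifs[[1]]$prob <- c(up_intersect = 0.9)
cfg_seq <- simulation_config(
  n_genes = 2000,
  group_fractions = c(up_total_only = 0.03, up_intersect = 0.03,
                      up_er_only = 0.02, down_total_only = 0.03,
                      down_intersect = 0.02, down_er_only = 0.02,
                      unchanged = 0.85),
  utr_params = up, seed = 20240902)
ex2 <- simulate_expression(cfg_seq)
su <- simulate_utrs(cfg_seq, ex2$truth)
sc <- simulate_conservation(su$models, su$truth, cfg_seq)
write_expression(ex2$table, file.path(out, "expression_seq.tsv"))
write_genome(su$genome, file.path(out, "genome.fa"))
write_transcripts(su$models, file.path(out, "transcripts.bed"))
write_track(sc$track, file.path(out, "conservation.wig"))
write_ground_truth(sc$truth, file.path(out, "ground_truth_seq.tsv"))
write_manifest(list(seed_expression = 20240901, seed_sequence = 20240902,
                    n_genes_expression = cfg_expr$n_genes,
                    n_genes_sequence = cfg_seq$n_genes),
               file.path(out, "manifest.json"))
cat("sequence-scale set:", length(su$genome), "contigs,",
    nrow(su$models), "transcripts,", nrow(sc$track), "scored bases\n")
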