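# End-to-end driver chaining simulate -> partition -> utr-features -> stats
# -> discover -> scan into one reproducible run with a JSON-serializable
# configuration and a structured report.

.RUN_CONFIG_KEYS <- c("out_dir", "seed", "simulate", "stages", "sim",
                      "expression_path", "genome_path", "transcripts_path",
                      "track_path", "annotation_path",
                      "quantile", "span", "fc_thresh", "z_thresh",
                      "min_utr_len", "widths", "e_thresh", "max_motifs",
                      "positive_group", "verbose")

#' Build a pipeline run configuration
#'
#' All stage parameters in one JSON-serializable document. Unknown keys are
#' rejected. When `simulate` is `TRUE` the inputs are generated by the
#' synthetic-data module from `sim` (a [simulation_config()]); otherwise
#' the `*_path` entries must point to existing files.
#'
#' @param out_dir Output directory for all stage outputs.
#' @param seed Root seed; all stage randomness derives from it.
#' @param simulate Generate inputs with the synthetic-data module.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("partition", "utr_features", "stats", "discover", "scan")`.
#' @param sim A [simulation_config()] (its seed is overridden by `seed`).
#' @param expression_path,genome_path,transcripts_path,track_path,annotation_path
#'   Input files used when `simulate = FALSE` (annotation is optional
#'   either way).
#' @param quantile,span,fc_thresh,z_thresh Partitioning parameters.
#' @param min_utr_len Minimum UTR length admitted to the feature analysis.
#' @param widths,e_thresh,max_motifs Motif discovery parameters.
#' @param positive_group Partition group whose UTRs form the positive set
#'   for motif discovery.
#' @param verbose Print one structured line per stage.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(out_dir = tempfile("erpartition_run_"),
                       seed = 1L, simulate = TRUE,
                       stages = c("partition", "utr_features", "stats",
                                  "discover", "scan"),
                       sim = simulation_config(),
                       expression_path = NULL, genome_path = NULL,
                       transcripts_path = NULL, track_path = NULL,
                       annotation_path = NULL,
                       quantile = 0.5, span = 0.3, fc_thresh = 1.4,
                       z_thresh = 3, min_utr_len = 30L,
                       widths = 4:8, e_thresh = 0.05, max_motifs = 50L,
                       positive_group = "up_intersect", verbose = FALSE) {
  known <- c("partition", "utr_features", "stats", "discover", "scan")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
              stages = stages, sim = sim, expression_path = expression_path,
              genome_path = genome_path, transcripts_path = transcripts_path,
              track_path = track_path, annotation_path = annotation_path,
              quantile = quantile, span = span, fc_thresh = fc_thresh,
              z_thresh = z_thresh, min_utr_len = min_utr_len,
              widths = widths, e_thresh = e_thresh,
              max_motifs = as.integer(max_motifs),
              positive_group = positive_group, verbose = verbose)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected; nested `sim` entries are passed through
#' [simulation_config()] for validation.
#'
#' @param path JSON file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    if (!is.null(sim_args$utr_params$uaug_rate))
      sim_args$utr_params$uaug_rate <- unlist(sim_args$utr_params$uaug_rate)
    if (!is.null(sim_args$group_fractions))
      sim_args$group_fractions <- unlist(sim_args$group_fractions)
    if (!is.null(sim_args$noise)) sim_args$noise <- unlist(sim_args$noise)
    raw$sim <- do.call(simulation_config, sim_args)
  }
  do.call(run_config, raw)
}

.stage_log <- function(cfg, stage, ...) {
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] %s", stage, paste(sprintf(...), collapse = " ")))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate, partition, UTR features,
#' group statistics, motif discovery, motif scanning), writes every stage
#' output under `config$out_dir`, and returns a report with record counts,
#' group sizes, the motif table, the statistics tables, and a manifest of
#' parameters and output checksums. Identical configuration and seed give an
#' identical report.
#'
#' @param config A [run_config()].
#' @return List of class `"run_report"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  if (any(c("utr_features", "stats", "discover", "scan") %in% st) &&
      !"partition" %in% st)
    stop("stage dependency error: downstream stages require 'partition'")
  if (("stats" %in% st || "discover" %in% st) && !"utr_features" %in% st)
    stop("stage dependency error: 'stats'/'discover' require 'utr_features'")
  if ("scan" %in% st && !"discover" %in% st)
    stop("stage dependency error: 'scan' requires 'discover'")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = st)

  if (config$simulate) {
    sim <- config$sim
    sim$seed <- config$seed
    ex <- simulate_expression(sim)
    su <- simulate_utrs(sim, ex$truth)
    sc <- simulate_conservation(su$models, su$truth, sim)
    table <- ex$table
    genome <- su$genome
    models <- su$models
    track <- sc$track
    truth <- sc$truth
    write_expression(table, file.path(config$out_dir, "expression.tsv"))
    write_genome(genome, file.path(config$out_dir, "genome.fa"))
    write_transcripts(models, file.path(config$out_dir, "transcripts.bed"))
    write_track(track, file.path(config$out_dir, "conservation.wig"))
    write_ground_truth(truth, file.path(config$out_dir, "ground_truth.tsv"))
    report$simulate <- list(n_genes = nrow(truth$genes),
                            group_sizes = as.list(table(truth$genes$group)))
    .stage_log(config, "simulate", "%d genes", nrow(truth$genes))
  } else {
    table <- read_expression(config$expression_path)
    genome <- if (!is.null(config$genome_path)) read_genome(config$genome_path)
    models <- if (!is.null(config$transcripts_path))
      read_transcripts(config$transcripts_path)
    track <- if (!is.null(config$track_path)) read_track(config$track_path)
    truth <- NULL
  }

  part <- NULL
  if ("partition" %in% st) {
    part <- partition_expression(table, quantile = config$quantile,
                                 span = config$span,
                                 fc_thresh = config$fc_thresh,
                                 z_thresh = config$z_thresh)
    utils::write.table(part$calls,
                       file.path(config$out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(part$groups),
                       file.path(config$out_dir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sizes <- vapply(unclass(part$groups), length, integer(1))
    # conservation identities of the six-way intersection
    stopifnot(sizes[["up_total_only"]] + sizes[["up_intersect"]] ==
                sum(part$calls$status == "up" &
                      part$calls$fraction == "total"))
    report$partition <- list(group_sizes = as.list(sizes),
                             n_not_expressed =
                               sum(part$calls$status == "not_expressed") / 2)
    .stage_log(config, "partition", "groups: %s",
               paste(names(sizes), sizes, sep = "=", collapse = " "))
  }

  features <- NULL
  if ("utr_features" %in% st) {
    features <- summarize_features(models, genome, track, part$groups,
                                   min_len = config$min_utr_len)
    utils::write.table(features, file.path(config$out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$utr_features <- list(n_records = nrow(features))
    .stage_log(config, "utr_features", "%d UTR records", nrow(features))
  }

  if ("stats" %in% st) {
    f5 <- features[features$side == "5p" & features$group != "unchanged", ]
    loc <- sub("^(up|down)_", "", f5$group)
    lev <- sub("_.*$", "", f5$group)
    srh <- scheirer_ray_hare(f5$aug_score, loc, lev)
    utils::write.table(as.data.frame(srh),
                       file.path(config$out_dir, "srh_aug_score.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stats <- list(srh_aug_score = as.data.frame(srh))
    for (side in c("5p", "3p")) {
      fs <- features[features$side == side & features$group != "unchanged" &
                       !is.na(features$mean_conservation), ]
      if (nrow(fs) && length(unique(fs$group)) >= 2 &&
          all(table(fs$group) >= 2)) {
        tk <- anova_tukey(fs$mean_conservation, fs$group)
        utils::write.table(tk$contrasts,
                           file.path(config$out_dir,
                                     paste0("tukey_conservation_", side, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$stats[[paste0("conservation_", side)]] <-
          list(f_p = tk$f_p, flags = tk$flags)
      }
    }
    if (!is.null(config$annotation_path)) {
      terms <- read_gmt(config$annotation_path)
      universe <- part$calls$gene_id[part$calls$fraction == "total" &
                                       part$calls$status != "not_expressed"]
      cand <- part$groups$up_intersect
      enr <- hypergeom_enrich(cand, terms, universe)
      utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stats$enrichment <- enr
    }
    .stage_log(config, "stats", "SRH location p = %.3g", srh$p[1])
  }

  motifs <- NULL
  if ("discover" %in% st) {
    utrs <- extract_utrs(models, genome)
    utrs <- utrs[utrs$length >= config$min_utr_len, ]
    pos_genes <- part$groups[[config$positive_group]]
    disc <- lapply(c("5p", "3p"), function(side) {
      us <- utrs[utrs$side == side, ]
      pos <- us$seq[us$gene_id %in% pos_genes]
      ref <- us$seq[!us$gene_id %in% pos_genes]
      if (length(pos) == 0L || length(ref) == 0L) return(NULL)
      run <- discover_motifs(pos, ref, widths = config$widths,
                             e_thresh = config$e_thresh,
                             max_motifs = config$max_motifs)
      if (nrow(run$motifs)) cbind(side = side, run$motifs) else NULL
    })
    motifs <- do.call(rbind, disc)
    if (is.null(motifs))
      motifs <- data.frame(side = character(0), word = character(0),
                           width = integer(0), pos_with = integer(0),
                           pos_total = integer(0), ref_with = integer(0),
                           ref_total = integer(0), p = numeric(0),
                           E = numeric(0), iteration = integer(0))
    utils::write.table(motifs, file.path(config$out_dir, "motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$discover <- list(n_motifs = nrow(motifs), motifs = motifs)
    .stage_log(config, "discover", "%d motif(s)", nrow(motifs))
  }

  if ("scan" %in% st) {
    utrs <- extract_utrs(models, genome)
    u5 <- utrs[utrs$side == "5p", ]
    u3 <- utrs[utrs$side == "3p", ]
    u3 <- u3[match(u5$transcript_id, u3$transcript_id), ]
    counts <- scan_counts(motifs$word[motifs$side == "5p"],
                          motifs$word[motifs$side == "3p"],
                          u5$seq, u3$seq)
    scan_df <- data.frame(transcript_id = u5$transcript_id,
                          gene_id = u5$gene_id, cis_element_sites = counts,
                          stringsAsFactors = FALSE)
    utils::write.table(scan_df, file.path(config$out_dir, "scan_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$scan <- list(n_transcripts = nrow(scan_df),
                        total_sites = sum(counts))
    .stage_log(config, "scan", "%d total sites", sum(counts))
  }

  outputs <- list.files(config$out_dir, full.names = TRUE)
  report$manifest <- list(
    parameters = unclass(config)[setdiff(names(unclass(config)), "sim")],
    checksums = as.list(tools::md5sum(outputs)))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("erpartition run (seed", x$seed, ")\n")
  if (!is.null(x$partition)) {
    cat("group sizes:\n")
    print(unlist(x$partition$group_sizes))
  }
  if (!is.null(x$discover)) cat(x$discover$n_motifs, "motif(s) discovered\n")
  invisible(x)
}
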