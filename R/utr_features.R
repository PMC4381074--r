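# Transcript models on genomic coordinates (0-based half-open, BED12-like),
# exon-aware 5'/3' UTR extraction, upstream-AUG statistics, and mapping of a
# basewise conservation track onto UTR positions.

#' Construct a transcript-models table
#'
#' @param transcript_id,gene_id Character vectors.
#' @param contig Contig name per transcript.
#' @param strand `"+"` or `"-"`.
#' @param cds_start,cds_end CDS genomic interval (0-based half-open).
#' @param exon_starts,exon_ends Lists of integer vectors (genomic, 0-based
#'   half-open, sorted, non-overlapping).
#' @return `data.frame` of class `"transcript_models"` with list columns for
#'   the exon blocks.
#' @export
transcript_models <- function(transcript_id, gene_id, contig, strand,
                              cds_start, cds_end, exon_starts, exon_ends) {
  stopifnot(all(strand %in% c("+", "-")))
  for (i in seq_along(transcript_id)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (any(diff(es) <= 0) || any(ee <= es) ||
        (length(es) > 1L && any(es[-1] < ee[-length(ee)])))
      stop("exons must be sorted and non-overlapping: ", transcript_id[i])
    if (cds_start[i] < es[1] || cds_end[i] > ee[length(ee)])
      stop("CDS outside exon span: ", transcript_id[i])
  }
  out <- data.frame(
    transcript_id = transcript_id, gene_id = gene_id, contig = contig,
    strand = strand,
    tx_start = vapply(exon_starts, function(x) x[1], numeric(1)),
    tx_end = vapply(exon_ends, function(x) x[length(x)], numeric(1)),
    cds_start = cds_start, cds_end = cds_end,
    exon_starts = I(exon_starts), exon_ends = I(exon_ends),
    stringsAsFactors = FALSE)
  class(out) <- c("transcript_models", "data.frame")
  out
}

# Genomic intervals (0-based half-open, genomic order) of one transcript's
# 5' or 3' UTR: the exonic parts upstream/downstream of the CDS in mRNA
# orientation.
utr_blocks <- function(model, side) {
  stopifnot(side %in% c("5p", "3p"))
  es <- model$exon_starts[[1]]
  ee <- model$exon_ends[[1]]
  upstream <- (model$strand == "+") == (side == "5p")
  if (upstream) {  # genomic left of cds_start
    lim <- model$cds_start
    s <- pmin(es, lim); e <- pmin(ee, lim)
  } else {         # genomic right of cds_end
    lim <- model$cds_end
    s <- pmax(es, lim); e <- pmax(ee, lim)
  }
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

#' Extract 5' and 3' UTR records from a transcript model
#'
#' The 5'UTR is the spliced transcript sequence upstream of the CDS start in
#' mRNA orientation and the 3'UTR the part downstream of the CDS end;
#' minus-strand transcripts are reverse-complemented. Sequences are
#' uppercase over the DNA alphabet.
#'
#' @param models A `transcript_models` data.frame.
#' @param genome Named [Biostrings::DNAStringSet] (contig sequences).
#' @return `data.frame(transcript_id, gene_id, side, seq, length)` with two
#'   rows per transcript; zero-length UTRs yield empty sequences.
#' @export
extract_utrs <- function(models, genome) {
  stopifnot(inherits(models, "transcript_models"))
  rows <- vector("list", 2L * nrow(models))
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    if (!m$contig %in% names(genome)) stop("unknown contig: ", m$contig)
    ctg <- genome[[m$contig]]
    for (k in 1:2) {
      side <- c("5p", "3p")[k]
      ub <- utr_blocks(m, side)
      seq <- if (nrow(ub) == 0L) "" else {
        parts <- vapply(seq_len(nrow(ub)), function(j)
          as.character(Biostrings::subseq(ctg, ub$start[j] + 1L, ub$end[j])),
          character(1))
        s <- paste(parts, collapse = "")
        if (m$strand == "-") revcomp(s) else s
      }
      rows[[2L * (i - 1L) + k]] <- data.frame(
        transcript_id = m$transcript_id, gene_id = m$gene_id, side = side,
        seq = toupper(seq), length = nchar(seq), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Count upstream AUGs in a 5'UTR sequence
#'
#' Counts every `ATG` trinucleotide regardless of reading frame (tandem
#' occurrences such as `ATGATG` count twice; `N` never matches).
#'
#' @param seq Character vector of 5'UTR sequences.
#' @return Integer vector of uAUG counts.
#' @export
count_uaugs <- function(seq) {
  .cpp_site_counts(toupper(seq), motif_masks("ATG"))
}

#' AUG score of a 5'UTR
#'
#' Ratio of the uAUG count to the UTR length (per-nucleotide rate). UTRs
#' shorter than `min_len` (default 30 nt) are not scored: they signal
#' exclusion from analysis, not a score of zero.
#'
#' @param count Integer uAUG count(s).
#' @param length UTR length(s) in nt.
#' @param min_len Minimum admissible UTR length.
#' @return Numeric score(s), count/length.
#' @export
aug_score <- function(count, length, min_len = 30L) {
  if (any(length < min_len))
    stop("UTR shorter than ", min_len, " nt is excluded from analysis")
  count / length
}

#' Construct a conservation track
#'
#' Sparse per-contig basewise scores (0-based positions; scores may be
#' negative, phyloP-style).
#'
#' @param contig Character vector of contig names per scored base.
#' @param pos Integer vector of 0-based positions.
#' @param score Numeric finite scores.
#' @return `data.frame` of class `"conservation_track"`, sorted by contig
#'   and position.
#' @export
conservation_track <- function(contig, pos, score) {
  stopifnot(length(contig) == length(pos), length(pos) == length(score))
  if (!all(is.finite(score))) stop("non-finite conservation scores")
  if (anyDuplicated(paste0(contig, ":", pos)))
    stop("duplicate positions in conservation track")
  out <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                    score = as.numeric(score), stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("conservation_track", "data.frame")
  out
}

#' Map basewise conservation onto a transcript's UTR
#'
#' Arithmetic mean of the track scores over exactly the exonic UTR genomic
#' positions. Positions absent from the track are skipped and do not enter
#' the denominator; intronic bases are never counted; the value is
#' strand-independent.
#'
#' @param model One-row `transcript_models` data.frame.
#' @param side `"5p"` or `"3p"`.
#' @param track A [conservation_track()].
#' @param zero_fill If `TRUE`, missing positions count as score 0 instead of
#'   being skipped (off by default).
#' @param .index Optional precomputed [track_index()] (an optimization for
#'   repeated calls over the same track).
#' @return List with `mean` (NA if no covered bases) and `covered_bases`.
#' @export
map_conservation <- function(model, side, track, zero_fill = FALSE,
                             .index = NULL) {
  ub <- utr_blocks(model, side)
  upos <- if (nrow(ub)) unlist(lapply(seq_len(nrow(ub)), function(j)
    seq.int(ub$start[j], ub$end[j] - 1L))) else integer(0)
  if (is.null(.index)) .index <- track_index(track)
  vec <- .index[[model$contig]]
  sc <- if (is.null(vec)) rep(NA_real_, length(upos)) else {
    out_of_range <- upos + 1L > length(vec)
    v <- rep(NA_real_, length(upos))
    v[!out_of_range] <- vec[upos[!out_of_range] + 1L]
    v
  }
  covered <- sum(!is.na(sc))
  if (zero_fill) {
    m <- if (length(sc)) mean(ifelse(is.na(sc), 0, sc)) else NA_real_
  } else {
    m <- if (covered > 0L) mean(sc, na.rm = TRUE) else NA_real_
  }
  list(mean = m, covered_bases = covered)
}

#' Dense per-contig lookup index for a conservation track
#'
#' @param track A [conservation_track()].
#' @return Named list, one NA-filled numeric vector per contig with scores
#'   at position + 1.
#' @export
track_index <- function(track) {
  lapply(split(track[, c("pos", "score")], track$contig), function(d) {
    vec <- rep(NA_real_, max(d$pos) + 1L)
    vec[d$pos + 1L] <- d$score
    vec
  })
}

#' Per-gene UTR feature table across partition groups
#'
#' Joins UTR records (length, uAUG count, AUG score, mean conservation) with
#' the six-way partition groups, producing the long table consumed by the
#' group statistics. The default analysis unit is the transcript; with
#' `gene_centered = TRUE` feature values are averaged over a gene's
#' transcripts.
#'
#' @param models A `transcript_models` data.frame.
#' @param genome Named `DNAStringSet`.
#' @param track A [conservation_track()], or `NULL` to skip conservation.
#' @param groups A `partition_groups` object (or `data.frame(gene_id,
#'   group)`).
#' @param min_len Minimum UTR length admitted to analysis (default 30 nt).
#' @param gene_centered Average features over a gene's transcripts.
#' @return `data.frame(gene_id, transcript_id, group, side, length,
#'   uaug_count, aug_score, mean_conservation, covered_bases)`; UTRs shorter
#'   than `min_len` are dropped.
#' @export
summarize_features <- function(models, genome, track, groups,
                               min_len = 30L, gene_centered = FALSE) {
  gdf <- if (inherits(groups, "partition_groups")) as.data.frame(groups) else groups
  if (anyDuplicated(gdf$gene_id))
    stop("gene present in more than one group: ",
         gdf$gene_id[duplicated(gdf$gene_id)][1])
  utrs <- extract_utrs(models, genome)
  utrs$group <- gdf$group[match(utrs$gene_id, gdf$gene_id)]
  utrs <- utrs[!is.na(utrs$group) & utrs$length >= min_len, , drop = FALSE]
  utrs$uaug_count <- ifelse(utrs$side == "5p", count_uaugs(utrs$seq), NA_integer_)
  utrs$aug_score <- ifelse(utrs$side == "5p",
                           utrs$uaug_count / utrs$length, NA_real_)
  utrs$mean_conservation <- NA_real_
  utrs$covered_bases <- NA_integer_
  if (!is.null(track)) {
    tindex <- track_index(track)
    idx <- match(utrs$transcript_id, models$transcript_id)
    for (r in seq_len(nrow(utrs))) {
      mc <- map_conservation(models[idx[r], ], utrs$side[r], track,
                             .index = tindex)
      utrs$mean_conservation[r] <- mc$mean
      utrs$covered_bases[r] <- mc$covered_bases
    }
  }
  out <- utrs[, c("gene_id", "transcript_id", "group", "side", "length",
                  "uaug_count", "aug_score", "mean_conservation",
                  "covered_bases")]
  if (gene_centered) {
    out <- do.call(rbind, lapply(split(out, list(out$gene_id, out$side),
                                       drop = TRUE), function(d) {
      data.frame(gene_id = d$gene_id[1], transcript_id = NA_character_,
                 group = d$group[1], side = d$side[1],
                 length = mean(d$length), uaug_count = mean(d$uaug_count),
                 aug_score = mean(d$aug_score),
                 mean_conservation = mean(d$mean_conservation),
                 covered_bases = sum(d$covered_bases),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Per-group distribution summaries of a feature table
#'
#' Median and quartiles per group and side, for boxplot-style reporting.
#'
#' @param features Output of [summarize_features()].
#' @param feature Column to summarize (e.g. `"aug_score"`).
#' @return `data.frame(group, side, n, q1, median, q3)`.
#' @export
feature_group_summary <- function(features, feature = "aug_score") {
  parts <- split(features, list(features$group, features$side), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    v <- d[[feature]]
    v <- v[!is.na(v)]
    data.frame(group = d$group[1], side = d$side[1], n = length(v),
               q1 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
               median = if (length(v)) median(v) else NA_real_,
               q3 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
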