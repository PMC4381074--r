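# Readers/writers for the pipeline's interchange formats: expression TSV
# with a two-line header, genome FASTA, transcript BED12, conservation
# fixedStep wig / bedGraph, GMT-like gene-set annotation, ground-truth TSV
# and the JSON run manifest. FASTA goes through Biostrings and the genomic
# track/BED formats through rtracklayer; internal coordinates are 0-based
# half-open throughout.

#' Write an expression table
#'
#' Canonical TSV layout: line 1 `gene_id` + sample ids, line 2 `labels` +
#' `fraction:condition` per sample, then one row per gene. Numbers are
#' written with full precision (`%.10g`) so that write/read round-trips are
#' byte-stable.
#'
#' @param table An [expression_table()].
#' @param path Output path.
#' @export
write_expression <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", table$samples$sample_id), collapse = "\t"), con)
  writeLines(paste(c("labels", paste0(table$samples$fraction, ":",
                                      table$samples$condition)),
                   collapse = "\t"), con)
  body <- apply(table$mat, 1, function(x)
    paste(sprintf("%.10g", x), collapse = "\t"))
  writeLines(paste(rownames(table$mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read an expression table
#'
#' Expects the two-line header written by [write_expression()]; duplicate
#' gene ids and non-numeric cells are rejected.
#'
#' @param path Input path.
#' @return An [expression_table()].
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed expression file: too few lines")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  lab <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "gene_id" || lab[1] != "labels" || length(hdr) != length(lab))
    stop("malformed header: expected 'gene_id' and 'labels' lines")
  sample_id <- hdr[-1]
  parts <- strsplit(lab[-1], ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed fraction:condition labels")
  fraction <- vapply(parts, `[`, character(1), 1)
  condition <- vapply(parts, `[`, character(1), 2)
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  if (any(lengths(body) != length(hdr)))
    stop("malformed expression row (wrong number of fields)")
  gene_id <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(gene_id))
    stop("duplicate gene id: ", gene_id[duplicated(gene_id)][1])
  vals <- suppressWarnings(
    vapply(body, function(x) as.numeric(x[-1]), numeric(length(sample_id))))
  if (any(is.na(vals))) stop("non-numeric expression cell")
  mat <- t(matrix(vals, nrow = length(sample_id)))
  dimnames(mat) <- list(gene_id, sample_id)
  expression_table(mat, fraction, condition)
}

#' Write a genome FASTA
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path Input path.
#' @return Named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write transcript models as BED12
#'
#' The BED name field carries the transcript id; gene ids are recovered on
#' reading by stripping the trailing `.<n>` isoform suffix.
#'
#' @param models A `transcript_models` data.frame.
#' @param path Output path.
#' @export
write_transcripts <- function(models, path) {
  stopifnot(inherits(models, "transcript_models"))
  gr <- GenomicRanges::GRanges(
    seqnames = models$contig,
    ranges = IRanges::IRanges(start = models$tx_start + 1L, end = models$tx_end),
    strand = models$strand)
  gr$name <- models$transcript_id
  gr$score <- 0L
  gr$thick <- IRanges::IRanges(start = models$cds_start + 1L,
                               end = models$cds_end)
  gr$blocks <- IRanges::IRangesList(lapply(seq_len(nrow(models)), function(i) {
    IRanges::IRanges(
      start = models$exon_starts[[i]] - models$tx_start[i] + 1L,
      end = models$exon_ends[[i]] - models$tx_start[i])
  }))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read transcript models from BED12
#' @param path Input path.
#' @return A `transcript_models` data.frame.
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tx_start <- BiocGenerics::start(gr) - 1L
  blocks <- gr$blocks
  exon_starts <- lapply(seq_along(gr), function(i)
    tx_start[i] + BiocGenerics::start(blocks[[i]]) - 1L)
  exon_ends <- lapply(seq_along(gr), function(i)
    tx_start[i] + BiocGenerics::end(blocks[[i]]))
  transcript_models(
    transcript_id = gr$name,
    gene_id = sub("\\.\\d+$", "", gr$name),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    cds_start = BiocGenerics::start(gr$thick) - 1L,
    cds_end = BiocGenerics::end(gr$thick),
    exon_starts = exon_starts, exon_ends = exon_ends)
}

#' Write a conservation track
#'
#' `format = "wig"` writes fixedStep (1-based start per the wig convention);
#' `format = "bedGraph"` writes 0-based half-open intervals.
#'
#' @param track A [conservation_track()].
#' @param path Output path.
#' @param format `"wig"` or `"bedGraph"`.
#' @export
write_track <- function(track, path, format = c("wig", "bedGraph")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = track$contig,
    ranges = IRanges::IRanges(start = track$pos + 1L, width = 1L),
    score = track$score)
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

#' Read a conservation track (fixedStep wig or bedGraph)
#'
#' Positions are converted to the internal 0-based convention (wig
#' fixedStep starts are 1-based; bedGraph intervals are 0-based half-open
#' and are expanded to single bases). Overlapping intervals are an error.
#'
#' @param path Input path.
#' @param format `"wig"` or `"bedGraph"`; guessed from the extension by
#'   default.
#' @return A [conservation_track()].
#' @export
read_track <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(bedgraph|bg)$", tolower(path))) "bedGraph" else "wig"
  }
  gr <- rtracklayer::import(path, format = format)
  w <- BiocGenerics::width(gr)
  contig <- rep(as.character(GenomicRanges::seqnames(gr)), w)
  pos <- rep(BiocGenerics::start(gr) - 1L, w) + (sequence(w) - 1L)
  score <- rep(gr$score, w)
  if (anyDuplicated(paste0(contig, ":", pos)))
    stop("overlapping intervals in track: ", path)
  conservation_track(contig, pos, score)
}

#' Read a GMT-like gene-set annotation
#'
#' Tab-separated lines: term id, description, then member gene ids.
#'
#' @param path Input path.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("malformed GMT line (need >= 3 fields)")
  terms <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(terms) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(terms))) stop("duplicate term id in GMT")
  terms
}

#' Write a GMT-like gene-set annotation
#' @param terms Named list of gene-id vectors.
#' @param path Output path.
#' @param description Optional per-term description (defaults to the term
#'   id).
#' @export
write_gmt <- function(terms, path, description = names(terms)) {
  writeLines(vapply(seq_along(terms), function(i)
    paste(c(names(terms)[i], description[i], terms[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Write per-gene ground truth as TSV
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(truth$genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-gene ground truth TSV
#' @param path Input path.
#' @return `ground_truth` object with the `genes` table.
#' @export
read_ground_truth <- function(path) {
  structure(list(genes = read.delim(path, stringsAsFactors = FALSE)),
            class = "ground_truth")
}

#' Write a JSON run manifest
#'
#' Records parameters, seeds and input checksums of a pipeline run.
#'
#' @param manifest Named list.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
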