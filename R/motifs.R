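# Discriminative IUPAC motif machinery: parsing/rendering of bracket-class
# motifs, site matching on the mRNA strand only, Fisher exact enrichment of
# sequence-level presence, and the iterative discovery loop (enumerate exact
# words, generalize single positions to 2-/3-letter classes by hill-climbing,
# report while E < threshold, erase sites, repeat).

.BASES <- c("A", "C", "G", "T")
.BASE_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# 2- and 3-letter generalization classes (no N/4-letter class).
.CLASSES <- list(
  c("A", "C"), c("A", "G"), c("A", "T"), c("C", "G"), c("C", "T"), c("G", "T"),
  c("A", "C", "G"), c("A", "C", "T"), c("A", "G", "T"), c("C", "G", "T")
)

#' Parse an IUPAC bracket-class motif
#'
#' Motifs are written with plain bases and bracketed classes, e.g.
#' `"C[C,G,A]GCGC"` (commas optional: `"C[CGA]GCGC"` is equivalent). Each
#' class position matches any of its listed bases; `N` in a *sequence*
#' matches nothing.
#'
#' @param motif Motif string.
#' @return List of character vectors, one per motif position, each the set of
#'   allowed bases at that position.
#' @examples
#' parse_motif("C[C,G,A]GCGC")
#' @export
parse_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L, nzchar(motif))
  chars <- strsplit(motif, "")[[1]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      cls <- character()
      while (j <= length(chars) && chars[j] != "]") {
        if (chars[j] != ",") cls <- c(cls, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unterminated class in motif: ", motif)
      if (length(cls) < 1L || !all(cls %in% .BASES))
        stop("invalid IUPAC class in motif: ", motif)
      out[[length(out) + 1L]] <- .BASES[.BASES %in% cls]
      i <- j + 1L
    } else {
      if (!ch %in% .BASES) stop("invalid IUPAC letter '", ch, "' in motif: ", motif)
      out[[length(out) + 1L]] <- ch
      i <- i + 1L
    }
  }
  if (length(out) == 0L) stop("empty motif")
  out
}

#' Render a parsed motif back to bracket notation
#'
#' Classes are rendered comma-separated in A,C,G,T order, e.g. `[C,G]`.
#'
#' @param sets List of allowed-base sets as returned by [parse_motif()].
#' @return Motif string.
#' @export
render_motif <- function(sets) {
  paste(vapply(sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ","), "]")
  }, character(1)), collapse = "")
}

motif_masks <- function(motif) {
  sets <- if (is.list(motif)) motif else parse_motif(motif)
  vapply(sets, function(s) as.integer(sum(.BASE_MASK[s])), integer(1))
}

motif_width <- function(motif) {
  length(if (is.list(motif)) motif else parse_motif(motif))
}

#' Find all match sites of a motif in one sequence
#'
#' Matching is on the given strand only (sequences are mRNA-sense UTRs, so
#' no reverse-complement matching), overlapping sites are all reported, and
#' `N` satisfies no motif position.
#'
#' @param motif Motif string (see [parse_motif()]).
#' @param seq Single DNA sequence string over `A,C,G,T,N`.
#' @return Integer vector of 1-based match start positions.
#' @examples
#' match_sites("C[C,G,A]GCGC", "TTCAGCGCTT")  # site at position 3
#' @export
match_sites <- function(motif, seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .cpp_site_positions(toupper(seq), motif_masks(motif)) + 1L
}

#' Sequence-level presence counts of a motif
#'
#' @param motif Motif string.
#' @param seqs Character vector of sequences.
#' @return Named integer vector `c(with = , total = )`: number of sequences
#'   containing at least one site, and the set size.
#' @export
presence_counts <- function(motif, seqs) {
  if (length(seqs) == 0L) return(c(with = 0L, total = 0L))
  hits <- .cpp_has_motif(toupper(seqs), motif_masks(motif))
  c(with = sum(hits), total = length(seqs))
}

#' One-tailed Fisher exact enrichment p-value
#'
#' Exact upper-tail p-value for enrichment of sequence-level presence in the
#' positive set, from the hypergeometric distribution of the 2x2 table
#' (positives with/without vs reference with/without). Vectorized over
#' counts.
#'
#' @param pos_with,pos_total Presence count and size of the positive set.
#' @param ref_with,ref_total Presence count and size of the reference set.
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_p <- function(pos_with, pos_total, ref_with, ref_total) {
  if (any(c(pos_with, pos_total, ref_with, ref_total) < 0))
    stop("negative counts")
  if (any(pos_with > pos_total) || any(ref_with > ref_total))
    stop("inconsistent counts: with > total")
  # white balls = all 'with' sequences, draw pos_total sequences
  phyper(pos_with - 1, pos_with + ref_with,
         (pos_total - pos_with) + (ref_total - ref_with),
         pos_total, lower.tail = FALSE)
}

# Presence counts of every exact word of width `w` occurring in `seqs`.
# Returns data.table(word, n) of per-sequence presence (not site) counts;
# words containing non-ACGT letters (e.g. erasure N's) are dropped.
word_presence_table <- function(seqs, w) {
  pieces <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < w) return(character(0))
    unique(substring(s, 1:(n - w + 1L), w:n))
  })
  words <- unlist(pieces, use.names = FALSE)
  if (length(words) == 0L)
    return(data.table::data.table(word = character(0), n = integer(0)))
  dt <- data.table::data.table(word = words)
  dt <- dt[grepl("^[ACGT]+$", word)]
  dt[, list(n = .N), by = word]
}

# masks (bit order A,C,G,T) back to allowed-base sets
.masks_to_sets <- function(masks) {
  lapply(masks, function(m) .BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0])
}

.CLASS_MASKS <- vapply(.CLASSES, function(s) as.integer(sum(.BASE_MASK[s])),
                       integer(1))

# Hill-climb one seed word (C++): per pass, try replacing each position with
# each 2-/3-letter class; accept the best move whose p beats the current p
# by more than the number of moves tried in the pass (selection-penalized
# acceptance, so the reported E-value stays calibrated on null inputs);
# repeat until no admissible move remains.
.refine_motif <- function(word, pos, ref, max_general = 2L) {
  res <- .cpp_refine_word(pos, ref, motif_masks(word), .CLASS_MASKS,
                          as.integer(max_general))
  list(sets = .masks_to_sets(res$masks), p = res$p,
       pos_with = res$pos_with, ref_with = res$ref_with,
       n_eval = res$n_eval)
}

.erase_sites <- function(seqs, motif) {
  masks <- motif_masks(motif)
  w <- length(masks)
  n_sites <- 0L
  out <- vapply(seqs, function(s) {
    hits <- .cpp_site_positions(s, masks)
    if (length(hits) > 0L) {
      chars <- strsplit(s, "")[[1]]
      for (h in hits) chars[(h + 1L):(h + w)] <- "N"
      n_sites <<- n_sites + length(hits)
      paste(chars, collapse = "")
    } else s
  }, character(1), USE.NAMES = FALSE)
  list(seqs = out, n_sites = n_sites)
}

#' Discriminative motif discovery against a reference set
#'
#' Iterative elicitation of short IUPAC motifs enriched in a positive
#' sequence set relative to a reference set (typically a subgroup's UTRs
#' versus the complete UTR set). Each iteration (1) enumerates every exact
#' word of each width present in the positives and scores it by the
#' one-tailed Fisher exact test on sequence-level presence; (2) generalizes
#' the `top_q` best words position-by-position to 2-/3-letter classes by
#' hill-climbing on the Fisher p (a move is accepted only when it improves p
#' by more than the number of alternative moves evaluated in the pass, so
#' greedy selection does not de-calibrate the E-value); (3) converts the
#' best refined motif's p to
#' an E-value, `E = p * candidates_scored`, where `candidates_scored` is
#' the size of the iteration's reachable candidate space: every enumerated
#' word together with all of its generalizations carrying up to
#' `max_general` class positions (a Bonferroni over the search space, so E
#' stays calibrated on null inputs).
#' While `E < e_thresh` the motif is reported and all of its sites are
#' erased (masked with `N`) in both sets before the next iteration.
#'
#' Discovery is deterministic: ties in p are broken lexicographically on the
#' rendered motif string.
#'
#' @param pos,ref Character vectors of positive and reference sequences.
#' @param widths Integer vector of motif widths, within 3..8.
#' @param e_thresh E-value threshold for reporting.
#' @param max_motifs Maximum number of motifs to report.
#' @param top_q Number of top-scoring exact words carried into refinement.
#' @param max_general Maximum number of positions that may be widened to a
#'   class per motif (published UTR cis-elements carry at most two class
#'   positions; the cap also keeps the greedy search's selection depth, and
#'   hence the E-value calibration, under control).
#' @return Object of class `"discovery_run"`: list with `motifs` (data.frame
#'   of word, width, counts, p, E, iteration), `erasures` (sites erased per
#'   iteration) and `candidates_scored` per iteration.
#' @export
discover_motifs <- function(pos, ref, widths = 4:8, e_thresh = 0.05,
                            max_motifs = 50L, top_q = 100L,
                            max_general = 2L) {
  if (length(pos) == 0L || length(ref) == 0L)
    stop("both positive and reference sets must be non-empty")
  if (any(widths < 3L) || any(widths > 8L))
    stop("widths must lie within 3..8")
  pos <- toupper(pos)
  ref <- toupper(ref)
  motifs <- list()
  erasures <- list()
  cand_log <- integer(0)
  iter <- 0L
  while (length(motifs) < max_motifs) {
    iter <- iter + 1L
    # (1) exact-word pass
    word_stats <- data.table::rbindlist(lapply(widths, function(w) {
      ptab <- word_presence_table(pos, w)
      if (nrow(ptab) == 0L) return(NULL)
      rtab <- word_presence_table(ref, w)
      ptab[, ref_n := rtab$n[match(word, rtab$word)]]
      ptab[is.na(ref_n), ref_n := 0L]
      ptab[, p := fisher_p(n, length(pos), ref_n, length(ref))]
      ptab
    }))
    if (is.null(word_stats) || nrow(word_stats) == 0L) break
    data.table::setorder(word_stats, p, word)
    seeds <- head(word_stats$word, top_q)
    # (2) refinement
    refined <- lapply(seeds, .refine_motif, pos = pos, ref = ref,
                      max_general = max_general)
    words_rendered <- vapply(refined, function(r) render_motif(r$sets), character(1))
    ps <- vapply(refined, `[[`, numeric(1), "p")
    best_i <- order(ps, words_rendered)[1L]
    best <- refined[[best_i]]
    # (3) E-value: Bonferroni over the reachable candidate space — every
    # enumerated word together with all of its generalizations carrying up
    # to max_general class positions (10 classes per widened position).
    # Counting only the candidates the greedy search happened to evaluate
    # understates the selection and de-calibrates E on null inputs.
    wtab <- table(nchar(word_stats$word))
    space_per_word <- vapply(as.integer(names(wtab)), function(w) {
      sum(vapply(0:max_general, function(k) choose(w, k) * 10^k, numeric(1)))
    }, numeric(1))
    n_cand <- sum(space_per_word * as.integer(wtab))
    E <- best$p * n_cand
    cand_log <- c(cand_log, n_cand)
    if (!(E < e_thresh)) break
    word <- render_motif(best$sets)
    motifs[[length(motifs) + 1L]] <- data.frame(
      word = word, width = length(best$sets),
      pos_with = best$pos_with, pos_total = length(pos),
      ref_with = best$ref_with, ref_total = length(ref),
      p = best$p, E = E, iteration = iter,
      stringsAsFactors = FALSE)
    ep <- .erase_sites(pos, word)
    er <- .erase_sites(ref, word)
    pos <- ep$seqs
    ref <- er$seqs
    erasures[[length(erasures) + 1L]] <- data.frame(
      iteration = iter, word = word,
      pos_sites = ep$n_sites, ref_sites = er$n_sites,
      stringsAsFactors = FALSE)
  }
  structure(list(
    motifs = if (length(motifs)) do.call(rbind, motifs) else
      data.frame(word = character(0), width = integer(0),
                 pos_with = integer(0), pos_total = integer(0),
                 ref_with = integer(0), ref_total = integer(0),
                 p = numeric(0), E = numeric(0), iteration = integer(0)),
    erasures = if (length(erasures)) do.call(rbind, erasures) else NULL,
    candidates_scored = cand_log,
    widths = widths, e_thresh = e_thresh
  ), class = "discovery_run")
}

#' @export
print.discovery_run <- function(x, ...) {
  cat("Discriminative motif discovery:", nrow(x$motifs), "motif(s), widths",
      paste(range(x$widths), collapse = "-"), ", E <", x$e_thresh, "\n")
  if (nrow(x$motifs)) print(x$motifs, row.names = FALSE)
  invisible(x)
}

#' Per-transcript cis-element site counts
#'
#' Total number of match sites of the 5'-applicable motifs in a transcript's
#' 5'UTR plus the 3'-applicable motifs in its 3'UTR (site-level: overlapping
#' sites all counted).
#'
#' @param motifs5,motifs3 Character vectors of motif strings for each side.
#' @param utr5,utr3 Character vectors (parallel over transcripts) of UTR
#'   sequences; empty strings allowed.
#' @return Integer vector of per-transcript total counts.
#' @export
scan_counts <- function(motifs5, motifs3, utr5, utr3) {
  stopifnot(length(utr5) == length(utr3))
  total <- integer(length(utr5))
  for (m in motifs5) total <- total + .cpp_site_counts(toupper(utr5), motif_masks(m))
  for (m in motifs3) total <- total + .cpp_site_counts(toupper(utr3), motif_masks(m))
  total
}
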