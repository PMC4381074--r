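# Synthetic-data generator. Emulates the study design downstream stages
# consume: one pooled array per fraction x condition with intensity-dependent
# noise, planted up/down genes split between total-only / intersect / ER-only
# regimes, UTR sequences with controllable GC, planted IUPAC motifs and
# per-group uAUG rates, and a basewise conservation track with a
# group-dependent mean shift. Every run is reproducible from a single seed.

.GROUPS <- c("up_total_only", "up_intersect", "up_er_only",
             "down_total_only", "down_intersect", "down_er_only", "unchanged")

#' Simulation configuration
#'
#' Bundles all generator parameters with validation. Defaults define the
#' reference study conditions used throughout the test-suite: 10^4 genes,
#' log2 baseline N(7, 2), heteroscedastic noise `sd(A) = a + b*exp(-c*A)`
#' decaying from about 1.5 at the noise floor through 0.4 at A = 4.4 to an
#' asymptote of 0.1 at bright intensities, planted log2 effect 1.5,
#' GC-rich 5'UTRs, a CCGCGC-like 5' element and an AU-rich 3' element
#' planted preferentially in the up-intersect group, a lowered uAUG rate in
#' that group, and a +1 conservation shift over its UTRs.
#'
#' @param n_genes Number of genes (one transcript each).
#' @param baseline_mean,baseline_sd Log2-intensity baseline distribution.
#' @param noise Named numeric `c(a=, b=, c=)` of the noise model
#'   `sd(A) = a + b * exp(-c * A)`.
#' @param effect_size Planted |log2 fold change| for regulated genes.
#' @param group_fractions Named proportions over the seven groups
#'   (six regulated + `unchanged`); must sum to 1.
#' @param utr_params List: `gc_5p`, `gc_3p` (GC contents), `len_5p`,
#'   `len_3p` (length ranges, min >= 30), `uaug_rate` (named per-group
#'   planted uAUG rate per nt; unnamed groups use `default`),
#'   `planted_motifs` (list of lists with `motif`, `side` ("5p"/"3p"),
#'   `prob` named per group, `background` probability elsewhere).
#' @param conservation_params List: `mean`, `sd` of the background score and
#'   `group_shift` (named per-group additive shift over UTR bases).
#' @param seed Integer root seed; all stage randomness derives from it.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(
    n_genes = 10000L,
    baseline_mean = 7, baseline_sd = 2,
    noise = c(a = 0.1, b = 1.4, c = 0.35),
    effect_size = 1.5,
    group_fractions = c(up_total_only = 0.030, up_intersect = 0.015,
                        up_er_only = 0.020, down_total_only = 0.035,
                        down_intersect = 0.020, down_er_only = 0.025,
                        unchanged = 0.855),
    utr_params = list(
      gc_5p = 0.6, gc_3p = 0.45,
      len_5p = c(60L, 300L), len_3p = c(100L, 600L),
      uaug_rate = c(default = 0.010, up_total_only = 0.014,
                    up_intersect = 0.004),
      planted_motifs = list(
        list(motif = "CCGCGC", side = "5p",
             prob = c(up_intersect = 0.30), background = 0.02),
        list(motif = "TTTA[C,G,A]AAA", side = "3p",
             prob = c(up_intersect = 0.25), background = 0.02))),
    conservation_params = list(mean = 0, sd = 1,
                               group_shift = c(up_intersect = 1.0)),
    seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be positive")
  n_genes <- as.integer(n_genes)
  stopifnot(all(c("a", "b", "c") %in% names(noise)))
  if (!setequal(names(group_fractions), .GROUPS))
    stop("group_fractions must name exactly the seven groups")
  if (abs(sum(group_fractions) - 1) > 1e-9)
    stop("group_fractions must sum to 1")
  if (any(group_fractions < 0) || any(group_fractions > 1))
    stop("group_fractions must lie in [0, 1]")
  up <- utr_params
  stopifnot(is.list(up), up$gc_5p >= 0, up$gc_5p <= 1,
            up$gc_3p >= 0, up$gc_3p <= 1)
  if (min(up$len_5p) < 30L || min(up$len_3p) < 30L)
    stop("UTR length ranges must start at >= 30 nt")
  for (pm in up$planted_motifs) {
    w <- motif_width(pm$motif)  # validates IUPAC letters too
    if (w > min(if (pm$side == "5p") up$len_5p else up$len_3p))
      stop("planted motif '", pm$motif, "' longer than the shortest ",
           pm$side, " UTR")
    if (any(c(pm$prob, pm$background) < 0) || any(c(pm$prob, pm$background) > 1))
      stop("motif insertion probabilities must lie in [0, 1]")
  }
  ur <- up$uaug_rate
  if (is.null(names(ur)) || !"default" %in% names(ur))
    stop("uaug_rate must be a named vector including 'default'")
  if (any(ur < 0)) stop("uaug_rate must be non-negative")
  structure(list(n_genes = n_genes, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, noise = noise,
                 effect_size = effect_size,
                 group_fractions = group_fractions[.GROUPS],
                 utr_params = up,
                 conservation_params = conservation_params,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

noise_sd <- function(config, A) {
  n <- config$noise
  n[["a"]] + n[["b"]] * exp(-n[["c"]] * A)
}

#' Simulate an expression table with planted regulation
#'
#' One sample per fraction x condition (4 columns). Control intensities are
#' drawn from the log2 baseline (the ER control adds a small correlated
#' offset); hypoxia intensities equal control plus the planted effect (sign
#' and compartment per group) plus heteroscedastic noise with
#' `sd(A) = a + b*exp(-c*A)` evaluated at the control intensity.
#'
#' @param config A [simulation_config()].
#' @return List with `table` (an [expression_table()]) and `truth` (class
#'   `"ground_truth"`: data.frame `genes` with per-gene true group label).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  group <- sample(.GROUPS, n, replace = TRUE, prob = config$group_fractions)
  ctrl_total <- rnorm(n, config$baseline_mean, config$baseline_sd)
  ctrl_er <- ctrl_total + rnorm(n, 0, 0.3)
  eff <- config$effect_size
  d_total <- eff * ((group %in% c("up_total_only", "up_intersect")) -
                    (group %in% c("down_total_only", "down_intersect")))
  d_er <- eff * ((group %in% c("up_er_only", "up_intersect")) -
                 (group %in% c("down_er_only", "down_intersect")))
  hyp_total <- ctrl_total + d_total + rnorm(n, 0, noise_sd(config, ctrl_total))
  hyp_er <- ctrl_er + d_er + rnorm(n, 0, noise_sd(config, ctrl_er))
  mat <- cbind(total_control = ctrl_total, total_hypoxia = hyp_total,
               ER_control = ctrl_er, ER_hypoxia = hyp_er)
  rownames(mat) <- gene_id
  tab <- expression_table(mat,
                          fraction = c("total", "total", "ER", "ER"),
                          condition = c("control", "hypoxia",
                                        "control", "hypoxia"))
  truth <- structure(list(genes = data.frame(
    gene_id = gene_id, group = group, stringsAsFactors = FALSE)),
    class = "ground_truth")
  list(table = tab, truth = truth)
}

# --- sequence helpers ---------------------------------------------------

# iid bases at the requested GC content
random_seq <- function(len, gc) {
  paste(sample(.BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Destroy every ATG whose triple does not overlap a protected interval by
# replacing its middle T with A (GC-neutral; cannot create a new ATG, and
# ATG matches never overlap each other so one pass suffices).
scrub_atg <- function(seq, protect_start = integer(0), protect_end = integer(0)) {
  hits <- match_sites("ATG", seq)
  if (length(hits) == 0L) return(seq)
  keep <- rep(FALSE, length(hits))
  if (length(protect_start)) {
    for (i in seq_along(hits)) {
      keep[i] <- any(hits[i] <= protect_end & hits[i] + 2L >= protect_start)
    }
  }
  bad <- hits[!keep]
  if (length(bad) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  chars[bad + 1L] <- "A"
  paste(chars, collapse = "")
}

# Instantiate a concrete word from an IUPAC motif (one base sampled per class).
instantiate_motif <- function(motif) {
  sets <- parse_motif(motif)
  paste(vapply(sets, function(s) s[sample.int(length(s), 1L)], character(1)),
        collapse = "")
}

overwrite_at <- function(seq, at, word) {
  paste0(substring(seq, 1, at - 1L), word,
         substring(seq, at + nchar(word), nchar(seq)))
}

# Build one UTR sequence: GC background, all background ATGs scrubbed,
# planted uAUGs (5p only), then planted motifs; returns sequence plus truth.
build_utr <- function(len, gc, side, uaug_rate, motif_specs, group) {
  seq <- scrub_atg(random_seq(len, gc))
  planted_aug <- integer(0)
  if (side == "5p" && uaug_rate > 0) {
    n_aug <- rbinom(1L, len, uaug_rate)
    if (n_aug > 0L) {
      # non-overlapping triple slots
      slots <- seq(1L, len - 2L, by = 3L)
      n_aug <- min(n_aug, length(slots))
      at <- sort(sample(slots, n_aug))
      for (a in at) seq <- overwrite_at(seq, a, "ATG")
      planted_aug <- at
    }
  }
  motif_rows <- NULL
  protect_s <- planted_aug
  protect_e <- planted_aug + 2L
  for (spec in motif_specs) {
    if (spec$side != side) next
    pr <- if (group %in% names(spec$prob)) spec$prob[[group]] else spec$background
    if (runif(1) >= pr) next
    w <- motif_width(spec$motif)
    # avoid overwriting planted uAUGs
    cand <- setdiff(seq_len(len - w + 1L), unlist(lapply(planted_aug, function(a)
      (a - w + 1L):(a + 2L))))
    if (length(cand) == 0L) next
    at <- cand[sample.int(length(cand), 1L)]
    word <- instantiate_motif(spec$motif)
    seq <- overwrite_at(seq, at, word)
    motif_rows <- rbind(motif_rows, data.frame(
      motif = spec$motif, word = word, start = at, stringsAsFactors = FALSE))
    protect_s <- c(protect_s, at)
    protect_e <- c(protect_e, at + w - 1L)
  }
  # motif insertion may have created incidental ATGs at junctions
  if (side == "5p") seq <- scrub_atg(seq, protect_s, protect_e)
  list(seq = seq, planted_aug = planted_aug, motifs = motif_rows,
       uaug_count = length(match_sites("ATG", seq)))
}

#' Simulate transcript models, genome and UTR sequences
#'
#' One transcript per gene, laid out on synthetic contigs (one per ~100
#' transcripts, alternating strands, 1-3 exons). 5'/3' UTRs are generated at
#' the configured GC content with group-specific planted uAUG rates and
#' IUPAC motifs (one concrete word instantiated per insertion); outside
#' planted positions 5'UTRs contain no ATG, so the planted count is the true
#' uAUG count up to motif-internal ATGs, which are re-counted from the final
#' sequence.
#'
#' @param config A [simulation_config()].
#' @param truth Ground truth from [simulate_expression()] (carries group
#'   labels).
#' @return List with `genome` (named [Biostrings::DNAStringSet]), `models`
#'   (a `transcript_models` data.frame, see [transcript_models()]) and
#'   `truth` augmented with `utrs` (per-transcript side, sequence, length,
#'   true uAUG count) and `motifs` (planted motif positions).
#' @export
simulate_utrs <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "ground_truth"))
  set.seed(config$seed + 1L)
  up <- config$utr_params
  genes <- truth$genes
  n <- nrow(genes)
  per_contig <- 100L
  contig_of <- ceiling(seq_len(n) / per_contig)
  contig_names <- sprintf("ctg%03d", sort(unique(contig_of)))
  rate_of <- function(grp) {
    if (grp %in% names(up$uaug_rate)) up$uaug_rate[[grp]] else up$uaug_rate[["default"]]
  }
  utr_rows <- vector("list", 2L * n)
  motif_rows <- list()
  model_rows <- vector("list", n)
  contig_seq <- setNames(vector("list", length(contig_names)), contig_names)
  offset <- setNames(integer(length(contig_names)), contig_names)
  gap <- 50L
  for (i in seq_len(n)) {
    grp <- genes$group[i]
    gid <- genes$gene_id[i]
    tid <- paste0(gid, ".1")
    len5 <- sample(up$len_5p[1]:up$len_5p[2], 1L)
    len3 <- sample(up$len_3p[1]:up$len_3p[2], 1L)
    u5 <- build_utr(len5, up$gc_5p, "5p", rate_of(grp), up$planted_motifs, grp)
    u3 <- build_utr(len3, up$gc_3p, "3p", rate_of(grp), up$planted_motifs, grp)
    cds_len <- 3L * sample(100L:200L, 1L)
    cds <- paste0("ATG", random_seq(cds_len - 6L, 0.5), "TAA")
    mrna <- paste0(u5$seq, cds, u3$seq)
    tx_len <- nchar(mrna)
    strand <- if (i %% 2L == 0L) "-" else "+"
    n_exons <- sample(1:3, 1L)
    # cut the mRNA into exon chunks of >= 30 nt
    if (n_exons > 1L) {
      cuts <- sort(sample(seq(30L, tx_len - 30L), n_exons - 1L))
      while (any(diff(c(0L, cuts, tx_len)) < 30L)) {
        cuts <- sort(sample(seq(30L, tx_len - 30L), n_exons - 1L))
      }
    } else cuts <- integer(0)
    bounds <- c(0L, cuts, tx_len)
    chunks <- substring(mrna, head(bounds, -1L) + 1L, bounds[-1L])
    introns <- if (n_exons > 1L)
      vapply(seq_len(n_exons - 1L), function(j) random_seq(sample(30:80, 1L), 0.45),
             character(1)) else character(0)
    # genomic orientation: for '-' the genome holds the reverse complement,
    # exon order reversed
    if (strand == "+") {
      g_chunks <- chunks
    } else {
      g_chunks <- rev(vapply(chunks, revcomp, character(1), USE.NAMES = FALSE))
    }
    ctg <- contig_names[contig_of[i]]
    pos <- offset[ctg] + gap  # 0-based start of exon 1
    exon_starts <- integer(n_exons)
    exon_ends <- integer(n_exons)
    pieces <- character(0)
    pieces <- c(pieces, random_seq(gap, 0.4))
    p <- pos
    for (e in seq_len(n_exons)) {
      exon_starts[e] <- p
      exon_ends[e] <- p + nchar(g_chunks[e])
      pieces <- c(pieces, g_chunks[e])
      p <- exon_ends[e]
      if (e < n_exons) {
        pieces <- c(pieces, introns[e])
        p <- p + nchar(introns[e])
      }
    }
    contig_seq[[ctg]] <- c(contig_seq[[ctg]], pieces)
    offset[ctg] <- p
    # CDS boundaries in transcript coordinates -> genomic thick interval
    cds_tx <- c(nchar(u5$seq), nchar(u5$seq) + cds_len)  # 0-based half-open
    gcoords <- tx_to_genome(exon_starts, exon_ends, strand, c(cds_tx[1], cds_tx[2] - 1L))
    model_rows[[i]] <- data.frame(
      transcript_id = tid, gene_id = gid, contig = ctg, strand = strand,
      tx_start = exon_starts[1], tx_end = exon_ends[n_exons],
      cds_start = min(gcoords), cds_end = max(gcoords) + 1L,
      exon_starts = I(list(exon_starts)), exon_ends = I(list(exon_ends)),
      stringsAsFactors = FALSE)
    utr_rows[[2L * i - 1L]] <- data.frame(
      transcript_id = tid, gene_id = gid, group = grp, side = "5p",
      seq = u5$seq, length = nchar(u5$seq), uaug_count = u5$uaug_count,
      stringsAsFactors = FALSE)
    utr_rows[[2L * i]] <- data.frame(
      transcript_id = tid, gene_id = gid, group = grp, side = "3p",
      seq = u3$seq, length = nchar(u3$seq), uaug_count = NA_integer_,
      stringsAsFactors = FALSE)
    for (side in c("5p", "3p")) {
      mr <- if (side == "5p") u5$motifs else u3$motifs
      if (!is.null(mr)) {
        mr$transcript_id <- tid
        mr$side <- side
        motif_rows[[length(motif_rows) + 1L]] <- mr
      }
    }
  }
  genome <- Biostrings::DNAStringSet(
    vapply(contig_seq, paste, character(1), collapse = ""))
  names(genome) <- contig_names
  models <- do.call(rbind, model_rows)
  class(models) <- c("transcript_models", "data.frame")
  truth$utrs <- do.call(rbind, utr_rows)
  truth$motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else NULL
  list(genome = genome, models = models, truth = truth)
}

# map transcript-coordinate positions (0-based) to genomic positions given
# genomic exon blocks; for '-' transcripts transcript coordinates run along
# the reverse complement.
tx_to_genome <- function(exon_starts, exon_ends, strand, tx_pos) {
  widths <- exon_ends - exon_starts
  if (strand == "+") {
    cum <- cumsum(c(0L, widths))
    vapply(tx_pos, function(tp) {
      e <- findInterval(tp, cum, rightmost.closed = FALSE)
      exon_starts[e] + (tp - cum[e])
    }, numeric(1))
  } else {
    rw <- rev(widths)
    cum <- cumsum(c(0L, rw))
    ne <- length(widths)
    vapply(tx_pos, function(tp) {
      e <- findInterval(tp, cum, rightmost.closed = FALSE)
      ge <- ne - e + 1L  # genomic exon index (last genomic exon is first in tx)
      exon_ends[ge] - 1L - (tp - cum[e])
    }, numeric(1))
  }
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Simulate a basewise conservation track
#'
#' Emits a score for every exonic base of every transcript: background
#' `N(mean, sd)` plus the configured additive shift over 5'/3' UTR bases of
#' transcripts in shifted groups. True per-UTR mean conservation (average of
#' the emitted scores over the UTR's exonic positions) is recorded in the
#' ground truth.
#'
#' @param models A `transcript_models` data.frame.
#' @param truth Ground truth carrying group labels.
#' @param config A [simulation_config()].
#' @return List with `track` (a [conservation_track()]) and `truth`
#'   augmented with `conservation` (per transcript/side true mean).
#' @export
simulate_conservation <- function(models, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  cp <- config$conservation_params
  shift_groups <- names(cp$group_shift)
  grp_of <- setNames(truth$genes$group, truth$genes$gene_id)
  ctg_l <- vector("list", nrow(models))
  pos_l <- vector("list", nrow(models))
  score_l <- vector("list", nrow(models))
  cons_rows <- vector("list", 2L * nrow(models))
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    ex_pos <- unlist(lapply(seq_along(m$exon_starts[[1]]), function(e)
      seq.int(m$exon_starts[[1]][e], m$exon_ends[[1]][e] - 1L)))
    sc <- rnorm(length(ex_pos), cp$mean, cp$sd)
    grp <- grp_of[[m$gene_id]]
    for (k in c(1L, 2L)) {
      side <- c("5p", "3p")[k]
      ub <- utr_blocks(m, side)
      upos <- if (nrow(ub)) unlist(lapply(seq_len(nrow(ub)), function(j)
        seq.int(ub$start[j], ub$end[j] - 1L))) else integer(0)
      idx <- match(upos, ex_pos)
      if (grp %in% shift_groups && length(idx))
        sc[idx] <- sc[idx] + cp$group_shift[[grp]]
      cons_rows[[2L * (i - 1L) + k]] <- data.frame(
        transcript_id = m$transcript_id, side = side,
        true_mean_conservation = if (length(idx)) mean(sc[idx]) else NA_real_,
        stringsAsFactors = FALSE)
    }
    ctg_l[[i]] <- rep(m$contig, length(ex_pos))
    pos_l[[i]] <- ex_pos
    score_l[[i]] <- sc
  }
  track <- conservation_track(unlist(ctg_l), unlist(pos_l), unlist(score_l))
  truth$conservation <- do.call(rbind, cons_rows)
  list(track = track, truth = truth)
}
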