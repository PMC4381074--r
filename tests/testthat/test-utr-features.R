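toy_genome <- function(seq, name = "chr1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

test_that("UTR extraction handles both strands and edge CDS placement", {
  set.seed(5)
  seq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  genome <- toy_genome(seq)
  plus <- transcript_models("t1", "g1", "chr1", "+", 130, 190,
                            list(100L), list(200L))
  u <- extract_utrs(plus, genome)
  expect_equal(u$seq[u$side == "5p"], substr(seq, 101, 130))
  expect_equal(u$seq[u$side == "3p"], substr(seq, 191, 200))
  # same coordinates on the minus strand: roles swap and revcomp applies
  minus <- transcript_models("t1", "g1", "chr1", "-", 130, 190,
                             list(100L), list(200L))
  um <- extract_utrs(minus, genome)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(um$seq[um$side == "5p"], rc(substr(seq, 191, 200)))
  expect_equal(um$seq[um$side == "3p"], rc(substr(seq, 101, 130)))
  # worked 10-nt example with a hand-written reverse complement
  g2 <- toy_genome("AACCGGTTAG")
  m2 <- transcript_models("t2", "g2", "chr1", "-", 0, 6, list(0L), list(10L))
  u2 <- extract_utrs(m2, g2)
  expect_equal(u2$seq[u2$side == "5p"], "CTAA")  # revcomp of TTAG
  # CDS at the transcript start leaves an empty 5'UTR
  m3 <- transcript_models("t3", "g3", "chr1", "+", 100, 150,
                          list(100L), list(200L))
  u3 <- extract_utrs(m3, genome)
  expect_equal(u3$length[u3$side == "5p"], 0)
  expect_error(extract_utrs(plus, toy_genome(seq, "other")), "unknown contig")
  expect_error(transcript_models("t", "g", "chr1", "+", 50, 90,
                                 list(100L), list(200L)), "CDS outside")
})

test_that("generated transcripts round-trip through extraction", {
  s <- small_sim()
  utrs <- extract_utrs(s$models, s$genome)
  m <- merge(utrs, s$truth$utrs[, c("transcript_id", "side", "seq")],
             by = c("transcript_id", "side"))
  expect_equal(nrow(m), nrow(utrs))
  expect_true(all(m$seq.x == m$seq.y))
  # conservation of bases: 5' + CDS + 3' = spliced length
  tx_len <- vapply(seq_len(nrow(s$models)), function(i)
    sum(s$models$exon_ends[[i]] - s$models$exon_starts[[i]]), numeric(1))
  per_tx <- tapply(utrs$length, utrs$transcript_id, sum)
  cds_len <- tx_len - per_tx[s$models$transcript_id]
  expect_true(all(cds_len > 0))
  expect_true(all(cds_len %% 3 == 0))
})

test_that("uAUG counting matches an overlap-aware regex oracle", {
  expect_equal(count_uaugs("ATGGATGC"), 2L)
  expect_equal(count_uaugs("CCCCCC"), 0L)
  expect_equal(count_uaugs("ATGATG"), 2L)
  expect_equal(count_uaugs("ANGATG"), 1L)
  set.seed(8)
  seqs <- random_dna(1000, 60, gc = 0.4)
  expect_equal(count_uaugs(seqs), vapply(seqs, oracle_uaug, integer(1),
                                         USE.NAMES = FALSE))
})

test_that("AUG score is count per nucleotide with a 30-nt admission rule", {
  expect_equal(aug_score(2, 100), 0.02)
  expect_equal(aug_score(0, 50), 0)
  expect_error(aug_score(3, 29), "excluded")
  # scales as 1/length for fixed count
  lens <- c(30, 60, 120, 240)
  expect_equal(aug_score(3, lens), 3 / lens)
  expect_true(all(diff(aug_score(3, lens)) < 0))
})

test_that("conservation mapping equals the per-base loop oracle", {
  trk <- conservation_track(
    contig = rep("chr1", 30),
    pos = c(100:109, 150:159, 200:209),
    score = c(rep(0, 10), rep(2, 10), seq(-1, 1, length.out = 10)))
  # two-exon 5'UTR [100,110)+[150,160); intron ignored
  m <- transcript_models("t1", "g1", "chr1", "+", 205, 209,
                         list(c(100L, 150L, 200L)),
                         list(c(110L, 160L, 210L)))
  got <- map_conservation(m, "5p", trk)
  blocks <- data.frame(start = c(100L, 150L, 200L), end = c(110L, 160L, 205L))
  exp <- oracle_map_conservation(blocks, "chr1", trk)
  expect_equal(got$mean, exp$mean)
  expect_equal(got$covered_bases, exp$covered_bases)
  # strand does not change the value
  mm <- transcript_models("t1", "g1", "chr1", "-", 205, 209,
                          list(c(100L, 150L, 200L)),
                          list(c(110L, 160L, 210L)))
  expect_equal(map_conservation(mm, "3p", trk)$mean, got$mean)
  # gaps: missing positions skipped, denominator = covered bases
  trk2 <- conservation_track(rep("chr1", 5), 100:104, rep(0.5, 5))
  m2 <- transcript_models("t2", "g2", "chr1", "+", 110, 115,
                          list(100L), list(115L))
  got2 <- map_conservation(m2, "5p", trk2)
  expect_equal(got2$mean, 0.5)
  expect_equal(got2$covered_bases, 5)
  expect_equal(map_conservation(m2, "5p", trk2, zero_fill = TRUE)$mean,
               0.5 * 5 / 10)
  # zero coverage signals an undefined mean
  m3 <- transcript_models("t3", "g3", "chr1", "+", 500, 505,
                          list(490L), list(510L))
  expect_true(is.na(map_conservation(m3, "5p", trk2)$mean))
})

test_that("randomized multi-exon mapping agrees with the oracle", {
  set.seed(12)
  for (rep_i in 1:5) {
    pos <- sort(sample(0:399, 150))
    trk <- conservation_track(rep("c1", 150), pos, rnorm(150))
    e1 <- sort(sample(0:100, 2)); e2 <- sort(sample(150:250, 2))
    if (diff(e1) == 0) e1[2] <- e1[2] + 5L
    if (diff(e2) == 0) e2[2] <- e2[2] + 5L
    cds <- c(e2[1], e2[1] + 1L)
    m <- transcript_models("t", "g", "c1",
                           sample(c("+", "-"), 1), cds[1], cds[2],
                           list(c(e1[1], e2[1])), list(c(e1[2], e2[2])))
    for (side in c("5p", "3p")) {
      got <- map_conservation(m, side, trk)
      ub <- erpartition:::utr_blocks(m, side)
      if (nrow(ub) == 0) next
      exp <- oracle_map_conservation(ub, "c1", trk)
      expect_equal(got$mean, exp$mean)
      expect_equal(got$covered_bases, exp$covered_bases)
    }
  }
})

test_that("feature summary joins groups and reflects planted differences", {
  s <- small_sim()
  groups <- data.frame(gene_id = s$truth$genes$gene_id,
                       group = s$truth$genes$group,
                       stringsAsFactors = FALSE)
  feats <- summarize_features(s$models, s$genome, s$track, groups)
  expect_true(all(c("gene_id", "group", "side", "length", "uaug_count",
                    "aug_score", "mean_conservation") %in% names(feats)))
  expect_true(all(feats$length >= 30))
  # 5' records carry scores, 3' records do not
  expect_true(all(is.na(feats$aug_score[feats$side == "3p"])))
  expect_true(all(!is.na(feats$aug_score[feats$side == "5p"])))
  # uAUG rates: up_total_only planted higher than up_intersect
  f5 <- feats[feats$side == "5p", ]
  expect_gt(mean(f5$aug_score[f5$group == "up_total_only"]),
            mean(f5$aug_score[f5$group == "up_intersect"]))
  # conservation shift on up_intersect UTRs is visible
  expect_gt(mean(feats$mean_conservation[feats$group == "up_intersect"]),
            mean(feats$mean_conservation[feats$group == "unchanged"]) + 0.5)
  # a gene in two groups is rejected
  bad <- rbind(groups, groups[1, ])
  bad$group[nrow(bad)] <- "up_er_only"
  expect_error(summarize_features(s$models, s$genome, NULL, bad),
               "more than one group")
  # gene-centered mode collapses to one record per gene and side
  gc <- summarize_features(s$models, s$genome, NULL, groups,
                           gene_centered = TRUE)
  expect_lte(nrow(gc), 2 * length(unique(groups$gene_id)))
  summ <- feature_group_summary(f5, "aug_score")
  expect_true(all(c("group", "n", "median") %in% names(summ)))
})
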