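test_that("IUPAC parsing and rendering round-trip bracket motifs", {
  expect_equal(length(parse_motif("C[C,G,A]GCGC")), 6)
  expect_equal(parse_motif("C[C,G,A]GCGC")[[2]], c("A", "C", "G"))
  expect_equal(render_motif(parse_motif("C[CGA]GCGC")), "C[A,C,G]GCGC")
  expect_equal(render_motif(parse_motif("ATG")), "ATG")
  expect_error(parse_motif("A[XY]G"), "invalid IUPAC")
  expect_error(parse_motif("AB"), "invalid IUPAC letter")
  expect_error(parse_motif("A[CG"), "unterminated")
})

test_that("site matching honours classes, overlap and N", {
  # the top reported 5'UTR element in the study's notation
  expect_equal(match_sites("C[C,G,A]GCGC", "TTCAGCGCTT"), 3L)
  expect_equal(match_sites("ATG", "ATGATG"), c(1L, 4L))
  expect_equal(length(match_sites("[A,C,T]", "G")), 0L)
  expect_equal(length(match_sites("ATG", "ANG")), 0L)
  # agreement with a lookahead-regex oracle on random cases
  set.seed(61)
  for (i in 1:20) {
    motif <- render_motif(lapply(1:5, function(j)
      sample(c("A", "C", "G", "T"), sample(1:3, 1))))
    s <- random_dna(1, 300, gc = 0.5)
    expect_equal(match_sites(motif, s), oracle_sites(motif, s))
  }
})

test_that("presence counts are sequence-level, not site-level", {
  seqs <- c("ATGATGATG", "CCCCC", "GGATGGG")
  expect_equal(presence_counts("ATG", seqs), c(with = 2L, total = 3L))
  expect_equal(presence_counts("ATG", character(0)),
               c(with = 0L, total = 0L))
})

test_that("Fisher enrichment p equals brute-force tail summation", {
  expect_equal(fisher_p(0, 100, 50, 100), 1.0)
  expect_equal(fisher_p(40, 100, 10, 100),
               oracle_fisher_p(40, 100, 10, 100), tolerance = 1e-12)
  # one-sidedness: depletion is not enrichment
  expect_gt(fisher_p(10, 100, 40, 100), 0.999)
  expect_error(fisher_p(-1, 10, 0, 10), "negative")
  expect_error(fisher_p(11, 10, 0, 10), "inconsistent")
  # exhaustive agreement over all tables with grand total <= 60
  for (pt in 1:30) for (rt in 1:30) {
    pw <- 0:pt
    for (rw in 0:rt) {
      got <- fisher_p(pw, pt, rw, rt)
      exp <- vapply(pw, oracle_fisher_p, numeric(1), pos_total = pt,
                    ref_with = rw, ref_total = rt)
      if (max(abs(got - exp)) > 1e-12)
        stop(sprintf("mismatch at table (%d,%d)", pt, rt))
    }
  }
  succeed()
})

test_that("discovery recovers a planted motif and respects erasure", {
  set.seed(62)
  ref <- random_dna(800, 120, gc = 0.6)
  pos <- random_dna(250, 120, gc = 0.6)
  planted <- sample(250, 80)
  for (i in planted) {
    at <- sample(115, 1)
    substr(pos[i], at, at + 5) <- "CCGCGC"
  }
  run <- discover_motifs(pos, ref, widths = 4:8, e_thresh = 0.05)
  expect_gte(nrow(run$motifs), 1)
  top <- run$motifs$word[1]
  expect_lt(run$motifs$E[1], 1e-3)
  hit <- vapply(pos[planted], function(s)
    length(match_sites(top, s)) > 0, logical(1))
  expect_gte(mean(hit), 0.9)
  # determinism
  run_b <- discover_motifs(pos, ref, widths = 4:8, e_thresh = 0.05)
  expect_identical(run$motifs, run_b$motifs)
  # E is never below p
  expect_true(all(run$motifs$E >= run$motifs$p))
  # erasure: after the run the reported motifs have no remaining positive
  # sites (re-erase manually and recount)
  er <- pos
  for (w in run$motifs$word) er <- erpartition:::.erase_sites(er, w)$seqs
  for (w in run$motifs$word)
    expect_equal(unname(presence_counts(w, er)["with"]), 0L)
})

test_that("two planted motifs are found in successive iterations", {
  set.seed(63)
  pos <- random_dna(300, 100, gc = 0.5)
  ref <- random_dna(1000, 100, gc = 0.5)
  for (i in sample(300, 130)) {
    at <- sample(94, 1); substr(pos[i], at, at + 5) <- "CCGCGC"
  }
  for (i in sample(300, 80)) {
    at <- sample(92, 1); substr(pos[i], at, at + 7) <- "TTTACAAA"
  }
  run <- discover_motifs(pos, ref, widths = 4:8)
  expect_gte(nrow(run$motifs), 2)
  expect_equal(run$motifs$word[1:2], c("CCGCGC", "TTTACAAA"))
  expect_equal(run$motifs$iteration[1:2], c(1L, 2L))
})

test_that("null inputs yield no motifs in most seeded runs", {
  clean <- 0
  for (s in 1:12) {
    set.seed(100 + s)
    allseq <- random_dna(250, 100, gc = 0.5)
    idx <- sample(250, 60)
    run <- discover_motifs(allseq[idx], allseq[-idx], widths = 4:8)
    clean <- clean + (nrow(run$motifs) == 0)
  }
  expect_gte(clean, 11)
})

test_that("discovery rejects invalid widths and empty sets", {
  expect_error(discover_motifs(character(0), "ACGT"), "non-empty")
  expect_error(discover_motifs("ACGT", "ACGT", widths = 2:5), "3..8")
  expect_error(discover_motifs("ACGT", "ACGT", widths = 9), "3..8")
})

test_that("per-transcript scan counts match a regex site oracle", {
  expect_equal(scan_counts("ATG", character(0), "ATGATG", ""), 2L)
  expect_equal(scan_counts(character(0), character(0), "ATGATG", "AAA"), 0L)
  set.seed(64)
  u5 <- random_dna(50, 80, 0.6)
  u3 <- random_dna(50, 150, 0.4)
  m5 <- c("CCGCGC", "GC[G,T]G")
  m3 <- c("TTTA[C,G,A]AAA", "AT[A,T]A")
  got <- scan_counts(m5, m3, u5, u3)
  exp <- vapply(seq_along(u5), function(i) {
    sum(vapply(m5, function(m) length(oracle_sites(m, u5[i])), integer(1))) +
      sum(vapply(m3, function(m) length(oracle_sites(m, u3[i])), integer(1)))
  }, integer(1))
  expect_equal(got, exp)
})
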