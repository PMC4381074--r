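# Independent brute-force oracles used to pin down the package's statistics
# and sequence operations. These deliberately avoid the code paths they
# check.

# upper-tail hypergeometric P(X >= k) by direct combinatorial summation
oracle_hyper_tail <- function(k, white, black, draws) {
  hi <- min(white, draws)
  if (k > hi) return(0)
  ks <- max(k, max(0, draws - black)):hi
  sum(exp(lchoose(white, ks) + lchoose(black, draws - ks) -
            lchoose(white + black, draws)))
}

# one-tailed Fisher enrichment p for a 2x2 presence table, via the oracle
oracle_fisher_p <- function(pos_with, pos_total, ref_with, ref_total) {
  oracle_hyper_tail(pos_with, pos_with + ref_with,
                    (pos_total - pos_with) + (ref_total - ref_with),
                    pos_total)
}

# overlap-counting uAUG oracle via lookahead regex
oracle_uaug <- function(seq) {
  m <- gregexpr("(?=ATG)", seq, perl = TRUE)[[1]]
  sum(m > 0)
}

# IUPAC motif to regex (classes -> character classes); N excluded explicitly
oracle_motif_regex <- function(motif) {
  sets <- parse_motif(motif)
  paste(vapply(sets, function(s)
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]"),
    character(1)), collapse = "")
}

# all overlapping match start positions (1-based) via lookahead regex
oracle_sites <- function(motif, seq) {
  pat <- paste0("(?=", oracle_motif_regex(motif), ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  as.integer(m[m > 0])
}

# per-base loop oracle for conservation mapping over explicit UTR intervals
oracle_map_conservation <- function(blocks, contig, track) {
  vals <- c()
  for (j in seq_len(nrow(blocks))) {
    for (p in seq.int(blocks$start[j], blocks$end[j] - 1L)) {
      hit <- track$score[track$contig == contig & track$pos == p]
      vals <- c(vals, if (length(hit)) hit else NA_real_)
    }
  }
  list(mean = if (any(!is.na(vals))) mean(vals, na.rm = TRUE) else NA_real_,
       covered_bases = sum(!is.na(vals)))
}

# Scheirer-Ray-Hare oracle: type-II rank ANOVA through car::Anova on an
# independently built linear model over the mid-ranks
oracle_srh <- function(values, a, b) {
  r <- rank(values)
  d <- data.frame(r = r, a = factor(a), b = factor(b))
  fit <- stats::lm(r ~ a * b, data = d)
  ss <- car::Anova(fit, type = 2)
  ms_total <- sum((r - mean(r))^2) / (length(r) - 1)
  H <- ss[c("a", "b", "a:b"), "Sum Sq"] / ms_total
  df <- ss[c("a", "b", "a:b"), "Df"]
  data.frame(term = c("location", "level", "location:level"),
             df = df, H = H, p = pchisq(H, df, lower.tail = FALSE))
}

# random sequence generator for fixtures
random_dna <- function(n, len, gc = 0.5) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE,
                 c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""), character(1))
}

# small cached synthetic dataset reused across test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_genes = 300, seed = 71)
      ex <- simulate_expression(cfg)
      su <- simulate_utrs(cfg, ex$truth)
      sc <- simulate_conservation(su$models, su$truth, cfg)
      cache <<- list(cfg = cfg, table = ex$table, genome = su$genome,
                     models = su$models, track = sc$track, truth = sc$truth)
    }
    cache
  }
})
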