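test_that("simulation is reproducible under a fixed seed", {
  cfg <- simulation_config(n_genes = 200, seed = 7)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$table$mat, b$table$mat)
  expect_identical(a$truth$genes, b$truth$genes)
  ua <- simulate_utrs(cfg, a$truth)
  ub <- simulate_utrs(cfg, b$truth)
  expect_identical(as.character(ua$genome), as.character(ub$genome))
  expect_identical(ua$truth$utrs, ub$truth$utrs)
  ca <- simulate_conservation(ua$models, ua$truth, cfg)
  cb <- simulate_conservation(ub$models, ub$truth, cfg)
  expect_identical(ca$track, cb$track)
})

test_that("zero noise and zero effect leave hypoxia equal to control", {
  cfg <- simulation_config(n_genes = 50, effect_size = 0,
                           noise = c(a = 0, b = 0, c = 1), seed = 3)
  ex <- simulate_expression(cfg)
  m <- ex$table$mat
  expect_equal(m[, "total_hypoxia"], m[, "total_control"])
  expect_equal(m[, "ER_hypoxia"], m[, "ER_control"])
})

test_that("config validation rejects inconsistent settings", {
  expect_error(simulation_config(n_genes = 0), "positive")
  gf <- c(up_total_only = 0.5, up_intersect = 0.1, up_er_only = 0.1,
          down_total_only = 0.1, down_intersect = 0.1, down_er_only = 0.1,
          unchanged = 0.5)
  expect_error(simulation_config(group_fractions = gf), "sum to 1")
  up <- simulation_config()$utr_params
  up$len_5p <- c(10L, 50L)
  expect_error(simulation_config(utr_params = up), "30")
  up <- simulation_config()$utr_params
  up$planted_motifs[[1]]$motif <- "CCGXGC"
  expect_error(simulation_config(utr_params = up), "invalid IUPAC")
  up <- simulation_config()$utr_params
  up$planted_motifs[[1]]$motif <- strrep("A", 40)
  up$len_5p <- c(30L, 35L)
  expect_error(simulation_config(utr_params = up), "longer than")
})

test_that("planted group sizes follow the configured multinomial", {
  gf <- c(up_total_only = 0.05, up_intersect = 0.05, up_er_only = 0.05,
          down_total_only = 0.05, down_intersect = 0.05, down_er_only = 0.05,
          unchanged = 0.70)
  cfg <- simulation_config(n_genes = 10000, group_fractions = gf, seed = 19)
  ex <- simulate_expression(cfg)
  counts <- table(factor(ex$truth$genes$group, levels = names(gf)))
  # binomial SE check on one group
  phat <- counts[["up_intersect"]] / 10000
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(phat - 0.05), 4 * se)
  # chi-square goodness of fit across all seven groups
  gof <- suppressWarnings(chisq.test(counts, p = gf))
  expect_gt(gof$p.value, 0.001)
})

test_that("UTR generator plants motifs, uAUG rates and GC as configured", {
  up <- simulation_config()$utr_params
  up$planted_motifs <- list(list(motif = "CCGCGC", side = "5p",
                                 prob = c(up_intersect = 1.0),
                                 background = 0))
  up$uaug_rate <- c(default = 0, up_total_only = 0.02)
  cfg <- simulation_config(n_genes = 250, utr_params = up, seed = 23)
  ex <- simulate_expression(cfg)
  su <- simulate_utrs(cfg, ex$truth)
  u5 <- su$truth$utrs[su$truth$utrs$side == "5p", ]
  # probability-1 insertion: every up_intersect 5'UTR carries a site
  tgt <- u5[u5$group == "up_intersect", ]
  expect_gt(nrow(tgt), 0)
  expect_true(all(vapply(tgt$seq, function(s)
    length(match_sites("CCGCGC", s)) >= 1, logical(1))))
  # zero background probability: no planted-motif record outside the group
  if (!is.null(su$truth$motifs)) {
    ids_in <- u5$transcript_id[u5$group == "up_intersect"]
    expect_true(all(su$truth$motifs$transcript_id[
      su$truth$motifs$side == "5p"] %in% ids_in))
  }
  # uaug_rate 0 groups have zero uAUGs
  zero <- u5[u5$group != "up_total_only", ]
  expect_true(all(zero$uaug_count == 0))
  # GC content of the 5' set near the configured 0.6
  allseq <- paste(u5$seq, collapse = "")
  gc <- sum(strsplit(allseq, "")[[1]] %in% c("G", "C")) / nchar(allseq)
  expect_lt(abs(gc - 0.6), 0.02)
  # both strands represented
  expect_setequal(unique(su$models$strand), c("+", "-"))
})

test_that("planted-motif presence off-target matches the background rate", {
  up <- simulation_config()$utr_params
  up$planted_motifs <- list(list(motif = "CCGCGC", side = "5p",
                                 prob = c(up_intersect = 1.0),
                                 background = 0.10))
  cfg <- simulation_config(n_genes = 800, utr_params = up, seed = 29)
  ex <- simulate_expression(cfg)
  su <- simulate_utrs(cfg, ex$truth)
  mt <- su$truth$motifs
  u5 <- su$truth$utrs[su$truth$utrs$side == "5p", ]
  off <- u5[u5$group != "up_intersect", ]
  planted_off <- sum(off$transcript_id %in%
                       mt$transcript_id[mt$side == "5p"])
  phat <- planted_off / nrow(off)
  se <- sqrt(0.10 * 0.90 / nrow(off))
  expect_lt(abs(phat - 0.10), 4 * se)
})

test_that("conservation track carries the configured group shift", {
  s <- small_sim()  # default config: +1.0 shift on up_intersect UTRs
  cons <- s$truth$conservation
  grp <- s$truth$genes$group[match(sub("\\.1$", "", cons$transcript_id),
                                   s$truth$genes$gene_id)]
  tgt <- cons$true_mean_conservation[grp == "up_intersect"]
  oth <- cons$true_mean_conservation[grp != "up_intersect"]
  expect_gt(length(tgt), 3)
  d <- mean(tgt, na.rm = TRUE) - mean(oth, na.rm = TRUE)
  expect_lt(abs(d - 1.0), 0.15)
  # no shift at all: UTR means scatter around the background mean
  cfg0 <- simulation_config(
    n_genes = 120, seed = 31,
    conservation_params = list(mean = 0.25, sd = 0.5, group_shift = NULL))
  ex <- simulate_expression(cfg0)
  su <- simulate_utrs(cfg0, ex$truth)
  sc <- simulate_conservation(su$models, su$truth, cfg0)
  expect_lt(abs(mean(sc$truth$conservation$true_mean_conservation,
                     na.rm = TRUE) - 0.25), 0.02)
})
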