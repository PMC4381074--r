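make_table <- function(mat) {
  expression_table(mat, fraction = c("total", "total", "ER", "ER"),
                   condition = c("control", "hypoxia", "control", "hypoxia"))
}

test_that("expression filter removes genes strictly below the quantile", {
  mat <- matrix(rep(c(2, 4, 6, 8), 4), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  tab <- make_table(mat)
  filt <- filter_expressed(tab, 0.5)  # linear-interpolation median = 5
  expect_setequal(rownames(filt$mat), c("g3", "g4"))
  expect_setequal(attr(filt, "not_expressed"), c("g1", "g2"))
  # quantile 0 retains everything
  expect_equal(nrow(filter_expressed(tab, 0)$mat), 4)
  # ties at the threshold are retained
  tied <- make_table(matrix(5, 4, 4, dimnames = dimnames(mat)))
  expect_equal(nrow(filter_expressed(tied, 0.5)$mat), 4)
  expect_error(filter_expressed(tab, 1), "quantile")
  expect_error(filter_expressed(tab, -0.1), "quantile")
})

test_that("contrast computes (A, M) per gene within a fraction", {
  mat <- matrix(c(8, 9, 7, 7,
                  10, 10.485, 5, 5), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  con <- compute_contrast(make_table(mat), "total")
  expect_equal(con$A, c(8.5, 10.2425))
  expect_equal(con$M, c(1.0, 0.485))
  # M = 0.485 sits at the linear FC 1.4 boundary
  expect_equal(2^con$M[2], 1.4, tolerance = 5e-4)
  con_er <- compute_contrast(make_table(mat), "ER")
  expect_equal(con_er$M, c(0, 0))
  expect_error(compute_contrast(make_table(mat), "nucleus"), "not present")
})

test_that("mean-SD loess recovers a flat trend and constant spread", {
  set.seed(101)
  A <- runif(5000, 4, 12)
  M <- rnorm(5000, 0, 0.2)
  fit <- fit_mean_sd_loess(A, M)
  grid <- seq(4.5, 11.5, length.out = 30)
  expect_true(all(abs(ma_trend(fit, grid)) < 0.03))
  expect_true(all(abs(ma_spread(fit, grid) / 0.2 - 1) < 0.10))
})

test_that("mean-SD loess tracks rising heteroscedastic spread", {
  set.seed(102)
  A <- runif(6000, 0, 10)
  sdA <- 0.1 + 0.03 * A  # 0.1 -> 0.4
  M <- rnorm(6000, 0, sdA)
  fit <- fit_mean_sd_loess(A, M)
  grid <- seq(0.5, 9.5, by = 1)
  sp <- ma_spread(fit, grid)
  expect_true(all(abs(sp / (0.1 + 0.03 * grid) - 1) < 0.15))
  # monotone within fit tolerance
  expect_true(all(diff(sp) > -0.01))
})

test_that("degenerate inputs to the loess model raise errors", {
  A <- runif(100, 4, 12)
  expect_error(fit_mean_sd_loess(A, rep(0, 100)), "degenerate spread")
  expect_error(fit_mean_sd_loess(A[1:30], rnorm(30)), "at least 50")
})

test_that("z-score matches its closed form and the boundary rule", {
  set.seed(103)
  A <- runif(2000, 4, 12)
  M <- rnorm(2000, 0, 0.3)
  fit <- fit_mean_sd_loess(A, M)
  tr <- ma_trend(fit, A)
  sp <- ma_spread(fit, A)
  # z = (M - trend)/spread exactly
  expect_equal(z_score(A, M, fit), (M - tr) / sp, tolerance = 1e-12)
  # M constructed on the trend gives z = 0; +3 spread gives z = 3
  expect_equal(z_score(A, tr, fit), rep(0, 2000), tolerance = 1e-12)
  expect_equal(z_score(A, tr + 3 * sp, fit), rep(3, 2000), tolerance = 1e-12)
  # outside the fitted range the nearest boundary value is used
  expect_equal(ma_trend(fit, 100), ma_trend(fit, max(A)))
  expect_equal(ma_spread(fit, -100), ma_spread(fit, min(A)))
  expect_true(all(is.finite(z_score(c(-5, 50), c(1, -1), fit))))
})

test_that("regulation calls require both fold-change and z thresholds", {
  calls <- call_regulation(c("a", "b", "c", "d"),
                           A = c(8, 8, 8, 8),
                           M = c(1.0, 0.3, -1.0, 0.6),
                           z = c(4, 5, -4, 2))
  expect_equal(calls$status, c("up", "unchanged", "down", "unchanged"))
  expect_error(call_regulation("a", 8, 1, 4, fc_thresh = 1), "exceed 1")
})

test_that("six-way intersection obeys the set algebra", {
  mk <- function(ids, status) data.frame(gene_id = ids, status = status,
                                         stringsAsFactors = FALSE)
  uni <- letters[1:10]
  tot <- mk(uni, c("up", "up", "up", "down", "unchanged", "unchanged",
                   "unchanged", "unchanged", "not_expressed", "unchanged"))
  er <- mk(uni, c("unchanged", "up", "up", "unchanged", "up", "down",
                  "unchanged", "unchanged", "unchanged", "not_expressed"))
  g <- intersect_groups(tot, er)
  expect_setequal(g$up_total_only, "a")
  expect_setequal(g$up_intersect, c("b", "c"))
  expect_setequal(g$up_er_only, "e")
  expect_setequal(g$down_total_only, "d")
  expect_setequal(g$down_er_only, "f")
  expect_setequal(g$unchanged, c("g", "h"))
  # not_expressed in either fraction excluded everywhere
  expect_false(any(c("i", "j") %in% unlist(unclass(g))))
  # conservation identity |up_total| = |up_total_only| + |up_intersect|
  n_up_total <- sum(tot$status == "up" & er$status != "not_expressed")
  expect_equal(length(g$up_total_only) + length(g$up_intersect), n_up_total)
  # empty call sets give empty groups
  g0 <- intersect_groups(mk(uni, rep("unchanged", 10)),
                         mk(uni, rep("unchanged", 10)))
  expect_true(all(lengths(unclass(g0))[1:6] == 0))
  expect_error(intersect_groups(tot, mk(letters[2:11], rep("up", 10))),
               "different gene universes")
  # invariance under gene reordering
  perm <- sample(10)
  g2 <- intersect_groups(tot[perm, ], er[rev(perm), ])
  for (nm in names(g)) expect_setequal(g[[nm]], g2[[nm]])
})

test_that("caller reaches high sensitivity at constant noise sd 0.25", {
  cfg <- simulation_config(n_genes = 10000,
                           noise = c(a = 0.25, b = 0, c = 1), seed = 41)
  ex <- simulate_expression(cfg)
  part <- partition_expression(ex$table)
  gdf <- as.data.frame(part$groups)
  called <- setNames(gdf$group, gdf$gene_id)
  truth <- ex$truth$genes
  expressed <- gdf$gene_id
  reg <- truth[truth$gene_id %in% expressed & truth$group != "unchanged", ]
  unch <- truth[truth$gene_id %in% expressed & truth$group == "unchanged", ]
  sens <- mean(called[reg$gene_id] == reg$group)
  fcr <- mean(called[unch$gene_id] != "unchanged")
  expect_gte(sens, 0.95)
  expect_lte(fcr, 0.01)
})
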