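# Regulation calling in two RNA fractions and six-way group intersection.
#
# The design has one pooled array per fraction x condition, so no replicate
# variance exists; instead the spread of the log-ratio M is modelled as a
# function of mean intensity A across genes (mean-SD loess model) and each
# gene's M is standardized to a z-score against that intensity-dependent
# spread. A gene is called regulated when both |FC| > 1.4 and |z| >= 3 with
# agreeing signs.

#' Construct an expression table
#'
#' @param mat Numeric matrix of log2 intensities, genes x samples, with
#'   rownames = gene ids and colnames = sample ids.
#' @param fraction Character vector per sample, each `"total"` or `"ER"`.
#' @param condition Character vector per sample, each `"control"` or
#'   `"hypoxia"`.
#' @return Object of class `"expression_table"`.
#' @export
expression_table <- function(mat, fraction, condition) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat))) stop("matrix must carry gene ids as rownames")
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))][1]
    stop("duplicate gene id: ", dup)
  }
  if (!all(is.finite(mat))) stop("non-finite intensities")
  if (length(fraction) != ncol(mat) || length(condition) != ncol(mat))
    stop("fraction/condition labels must match the number of samples")
  if (!all(fraction %in% c("total", "ER"))) stop("fraction must be 'total' or 'ER'")
  if (!all(condition %in% c("control", "hypoxia")))
    stop("condition must be 'control' or 'hypoxia'")
  for (fr in unique(fraction)) {
    if (!all(c("control", "hypoxia") %in% condition[fraction == fr]))
      stop("fraction '", fr, "' lacks one of the two conditions")
  }
  structure(list(
    mat = mat,
    samples = data.frame(sample_id = colnames(mat), fraction = fraction,
                         condition = condition, stringsAsFactors = FALSE)
  ), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$mat), "genes x", ncol(x$mat), "samples\n")
  print(x$samples, row.names = FALSE)
  invisible(x)
}

#' Expression-quantile filter
#'
#' Removes genes whose summary intensity (mean over all samples) lies
#' strictly below the given quantile of the summary distribution
#' (linear-interpolation quantile). Genes exactly at the threshold are
#' retained. Removed gene ids are recorded in the `"not_expressed"`
#' attribute of the result.
#'
#' @param table An [expression_table()].
#' @param quantile Quantile in `[0, 1)`; default 0.5 (genes below the 50%
#'   expression quantile are disregarded).
#' @return Filtered `expression_table` with attribute `not_expressed`.
#' @export
filter_expressed <- function(table, quantile = 0.5) {
  stopifnot(inherits(table, "expression_table"))
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile < 0 || quantile >= 1)
    stop("quantile must lie in [0, 1)")
  if (nrow(table$mat) == 0L) stop("empty expression table")
  summ <- rowMeans(table$mat)
  thr <- stats::quantile(summ, quantile, type = 7, names = FALSE)
  keep <- summ >= thr
  out <- table
  out$mat <- table$mat[keep, , drop = FALSE]
  attr(out, "not_expressed") <- rownames(table$mat)[!keep]
  out
}

#' Per-gene (A, M) contrast within a fraction
#'
#' `M` is the log2 fold change hypoxia vs control (multiple samples per
#' condition are averaged in log2 space first) and `A` the mean log2
#' intensity of the two condition means.
#'
#' @param table An [expression_table()].
#' @param fraction `"total"` or `"ER"`.
#' @return `data.frame(gene_id, A, M)`.
#' @export
compute_contrast <- function(table, fraction) {
  stopifnot(inherits(table, "expression_table"))
  sel <- table$samples$fraction == fraction
  if (!any(sel)) stop("fraction '", fraction, "' not present")
  cond <- table$samples$condition[sel]
  if (!all(c("control", "hypoxia") %in% cond))
    stop("fraction '", fraction, "' lacks one of the two conditions")
  sub <- table$mat[, sel, drop = FALSE]
  ctrl <- rowMeans(sub[, cond == "control", drop = FALSE])
  hyp <- rowMeans(sub[, cond == "hypoxia", drop = FALSE])
  data.frame(gene_id = rownames(table$mat), A = (ctrl + hyp) / 2,
             M = hyp - ctrl, row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the mean-standard-deviation loess model
#'
#' Fits `trend(A)`, a robust local regression of M on A, and `spread(A)`, a
#' robust local regression of `consistency * |M - trend(A)|` on A. Both
#' fits use Tukey biweight robustness iterations so that genuinely
#' regulated genes do not inflate the spread. The default consistency
#' constant 1.379 makes the spread a Fisher-consistent estimate of the
#' Gaussian SD: the biweight location of half-normal absolute residuals is
#' 0.725 sigma (the familiar 1.4826 would apply if the local fit tracked
#' the conditional median, and overestimates the SD here by about 7%).
#' The spread is floored at `floor_eps`. Outside the fitted A range both
#' curves are evaluated at the nearest boundary (no extrapolation of
#' slope).
#'
#' @param A,M Numeric vectors (mean intensity, log ratio) over genes.
#' @param span Loess span; default 0.3.
#' @param floor_eps Lower floor for the spread.
#' @param consistency Multiplier applied to absolute residuals before the
#'   spread fit so that `spread(A)` estimates the Gaussian SD.
#' @return Object of class `"loess_ma_fit"` with elements `trend`, `spread`
#'   (loess fits), `range` (fitted A range) and `span`.
#' @export
fit_mean_sd_loess <- function(A, M, span = 0.3, floor_eps = 1e-6,
                              consistency = 1.379) {
  stopifnot(length(A) == length(M))
  if (length(A) < 50L) stop("need at least 50 genes to fit the mean-SD model")
  if (!all(is.finite(A)) || !all(is.finite(M))) stop("non-finite input")
  if (stats::sd(M) == 0)
    stop("degenerate spread: log-ratios have no variability")
  lt <- stats::loess(M ~ A, span = span, degree = 2, family = "symmetric")
  r <- M - stats::fitted(lt)
  if (all(abs(r) < floor_eps) || stats::sd(r) == 0)
    stop("degenerate spread: residuals have no variability")
  ls <- stats::loess(y ~ A, data = data.frame(A = A, y = consistency * abs(r)),
                     span = span, degree = 2, family = "symmetric")
  structure(list(trend = lt, spread = ls, range = range(A), span = span,
                 floor_eps = floor_eps, iterations = 4L),
            class = "loess_ma_fit")
}

#' Evaluate the fitted trend at intensities A
#' @param fit A [fit_mean_sd_loess()] result.
#' @param A Numeric intensities; values outside the fitted range are clamped
#'   to the nearest boundary.
#' @return Numeric trend values.
#' @export
ma_trend <- function(fit, A) {
  stopifnot(inherits(fit, "loess_ma_fit"))
  A <- pmin(pmax(A, fit$range[1]), fit$range[2])
  as.numeric(predict(fit$trend, newdata = data.frame(A = A)))
}

#' Evaluate the fitted spread at intensities A
#' @inheritParams ma_trend
#' @return Numeric spread values, floored at `fit$floor_eps` (always > 0).
#' @export
ma_spread <- function(fit, A) {
  stopifnot(inherits(fit, "loess_ma_fit"))
  A <- pmin(pmax(A, fit$range[1]), fit$range[2])
  pmax(as.numeric(predict(fit$spread, newdata = data.frame(A = A))),
       fit$floor_eps)
}

#' Intensity-standardized z-score
#'
#' `z = (M - trend(A)) / spread(A)` under the mean-SD loess model.
#'
#' @param A,M Numeric vectors.
#' @param fit A [fit_mean_sd_loess()] result.
#' @return Numeric z-scores.
#' @export
z_score <- function(A, M, fit) {
  (M - ma_trend(fit, A)) / ma_spread(fit, A)
}

#' Call per-gene regulation status
#'
#' A gene is `up` iff `M >= log2(fc_thresh)` and `z >= z_thresh`, `down` iff
#' `M <= -log2(fc_thresh)` and `z <= -z_thresh`, otherwise `unchanged`.
#'
#' @param gene_id Character vector of gene ids.
#' @param A,M,z Numeric vectors from [compute_contrast()] / [z_score()].
#' @param fc_thresh Linear fold-change threshold (> 1); default 1.4.
#' @param z_thresh z-score threshold; default 3.
#' @param fraction Optional fraction label stored in the result.
#' @return `data.frame(gene_id, fraction, A, M, z, status)`.
#' @export
call_regulation <- function(gene_id, A, M, z, fc_thresh = 1.4, z_thresh = 3,
                            fraction = NA_character_) {
  if (fc_thresh <= 1) stop("fc_thresh must exceed 1")
  lfc <- log2(fc_thresh)
  status <- ifelse(M >= lfc & z >= z_thresh, "up",
            ifelse(M <= -lfc & z <= -z_thresh, "down", "unchanged"))
  data.frame(gene_id = gene_id, fraction = fraction, A = A, M = M, z = z,
             status = status, row.names = NULL, stringsAsFactors = FALSE)
}

#' Full regulation calling for one fraction
#'
#' Convenience wrapper: contrast, mean-SD loess fit, z-scores, and calls.
#'
#' @inheritParams compute_contrast
#' @inheritParams call_regulation
#' @param span Loess span passed to [fit_mean_sd_loess()].
#' @return `data.frame` of calls (see [call_regulation()]) with the loess
#'   fit attached as attribute `"fit"`.
#' @export
call_fraction <- function(table, fraction, span = 0.3, fc_thresh = 1.4,
                          z_thresh = 3) {
  con <- compute_contrast(table, fraction)
  fit <- fit_mean_sd_loess(con$A, con$M, span = span)
  z <- z_score(con$A, con$M, fit)
  calls <- call_regulation(con$gene_id, con$A, con$M, z,
                           fc_thresh = fc_thresh, z_thresh = z_thresh,
                           fraction = fraction)
  attr(calls, "fit") <- fit
  calls
}

#' Intersect total-RNA and ER-RNA regulation calls into six groups
#'
#' Genes regulated in only one fraction fall into the `*_total_only` /
#' `*_er_only` sets; genes regulated in both (same direction) into
#' `*_intersect`. Within a direction the three sets are pairwise disjoint
#' and satisfy `up_total_only + up_intersect = ` all genes up in total (and
#' analogously for ER and for down). Genes marked not expressed in either
#' fraction are excluded from all six sets.
#'
#' @param calls_total,calls_er Call data.frames over the same gene universe
#'   (columns `gene_id`, `status`; status may include `"not_expressed"`).
#' @return Object of class `"partition_groups"`: named list of gene-id
#'   vectors for the six regulated sets plus `unchanged`, with the universe
#'   as attribute.
#' @export
intersect_groups <- function(calls_total, calls_er) {
  if (!setequal(calls_total$gene_id, calls_er$gene_id))
    stop("call sets cover different gene universes")
  er_status <- calls_er$status[match(calls_total$gene_id, calls_er$gene_id)]
  tot_status <- calls_total$status
  g <- calls_total$gene_id
  expressed <- tot_status != "not_expressed" & er_status != "not_expressed"
  up_t <- g[expressed & tot_status == "up"]
  up_e <- g[expressed & er_status == "up"]
  dn_t <- g[expressed & tot_status == "down"]
  dn_e <- g[expressed & er_status == "down"]
  groups <- list(
    up_total_only   = setdiff(up_t, up_e),
    up_intersect    = intersect(up_t, up_e),
    up_er_only      = setdiff(up_e, up_t),
    down_total_only = setdiff(dn_t, dn_e),
    down_intersect  = intersect(dn_t, dn_e),
    down_er_only    = setdiff(dn_e, dn_t)
  )
  groups$unchanged <- setdiff(g[expressed], unlist(groups))
  structure(groups, universe = g, class = "partition_groups")
}

#' @export
print.partition_groups <- function(x, ...) {
  sizes <- vapply(unclass(x), length, integer(1))
  cat("partition_groups over", length(attr(x, "universe")), "genes\n")
  print(sizes)
  invisible(x)
}

#' Coerce partition groups to a long data.frame
#' @param x A `partition_groups` object.
#' @param ... Unused.
#' @return `data.frame(gene_id, group)` over assigned genes.
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.partition_groups <- function(x, ...) {
  data.frame(gene_id = unlist(unclass(x), use.names = FALSE),
             group = rep(names(x), vapply(unclass(x), length, integer(1))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition an expression table end to end
#'
#' Applies the expression filter, calls regulation separately in the total
#' and ER fractions, and intersects the calls into the six groups. Filtered
#' genes appear in the calls with status `"not_expressed"`.
#'
#' @inheritParams filter_expressed
#' @inheritParams call_fraction
#' @return List with `calls` (both fractions, all genes), `groups`
#'   (a [intersect_groups()] result) and `fits` (per-fraction loess fits).
#' @export
partition_expression <- function(table, quantile = 0.5, span = 0.3,
                                 fc_thresh = 1.4, z_thresh = 3) {
  filt <- filter_expressed(table, quantile)
  dropped <- attr(filt, "not_expressed")
  per_fraction <- lapply(c(total = "total", ER = "ER"), function(fr) {
    calls <- call_fraction(filt, fr, span = span, fc_thresh = fc_thresh,
                           z_thresh = z_thresh)
    if (length(dropped)) {
      calls <- rbind(calls, data.frame(
        gene_id = dropped, fraction = fr, A = NA_real_, M = NA_real_,
        z = NA_real_, status = "not_expressed", stringsAsFactors = FALSE))
    }
    calls
  })
  groups <- intersect_groups(per_fraction$total, per_fraction$ER)
  list(calls = do.call(rbind, c(per_fraction, make.row.names = FALSE)),
       groups = groups,
       fits = lapply(per_fraction, attr, "fit"))
}
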