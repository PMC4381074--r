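# Statistical comparisons across the partition groups: rank-based two-factor
# ANOVA (Scheirer-Ray-Hare), linear one-way ANOVA with Tukey post-hoc
# contrasts, and hypergeometric gene-set enrichment with BH correction.

# residual sum of squares of y on a design matrix (least squares via QR)
.rss <- function(y, X) {
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Scheirer-Ray-Hare rank-based two-factor ANOVA
#'
#' Mid-ranks are assigned over all N observations (ties averaged) and a
#' two-way ANOVA sum-of-squares decomposition is computed on the ranks;
#' unbalanced designs use type-II sums of squares. Each effect's statistic
#' is `H = SS_effect / MS_total` with `MS_total = SS_total / (N - 1)`
#' (computed from the mid-ranks, which already absorbs ties; no separate
#' tie-correction divisor is applied, though the classical correction
#' factor is reported), and p-values come from the chi-square upper tail at
#' the effect's degrees of freedom.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factor labels (>= 2 levels each), e.g.
#'   localization and expression-level direction.
#' @return `data.frame` of class `"srh_result"` with rows for factor A,
#'   factor B and the interaction: `term`, `df`, `H`, `p`; attributes `N`
#'   and `tie_factor`.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b))
  if (any(is.na(values)) || any(is.na(factor_a)) || any(is.na(factor_b)))
    stop("every observation must be labeled and non-missing")
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  a <- nlevels(fa)
  b <- nlevels(fb)
  if (a < 2L || b < 2L) stop("each factor needs at least 2 levels")
  if (any(table(fa, fb) == 0L))
    warning("empty cells; statistics computed from available cells")
  n <- length(values)
  r <- rank(values)  # mid-ranks, ties averaged
  ss_total <- sum((r - mean(r))^2)
  df <- c(a - 1L, b - 1L, (a - 1L) * (b - 1L))
  terms <- c("location", "level", "location:level")
  if (ss_total == 0) {
    H <- c(0, 0, 0); p <- c(1, 1, 1)
  } else {
    Xa <- model.matrix(~fa)
    Xb <- model.matrix(~fb)
    Xab <- model.matrix(~fa + fb)
    Xfull <- model.matrix(~fa * fb)
    ss_a <- .rss(r, Xb) - .rss(r, Xab)    # type II
    ss_b <- .rss(r, Xa) - .rss(r, Xab)
    ss_int <- .rss(r, Xab) - .rss(r, Xfull)
    ms_total <- ss_total / (n - 1)
    H <- pmax(c(ss_a, ss_b, ss_int), 0) / ms_total
    p <- pchisq(H, df, lower.tail = FALSE)
  }
  tt <- table(r)
  tie_factor <- 1 - sum(tt^3 - tt) / (n^3 - n)
  out <- data.frame(term = terms, df = df, H = H, p = p,
                    stringsAsFactors = FALSE)
  attr(out, "N") <- n
  attr(out, "tie_factor") <- tie_factor
  class(out) <- c("srh_result", "data.frame")
  out
}

#' One-way ANOVA with Tukey post-hoc contrasts
#'
#' Fits a linear one-way ANOVA (classic equal-variance model) and computes
#' all pairwise group contrasts with single-step studentized-range adjusted
#' p-values. Each group is additionally flagged `"#"` when significantly
#' higher than all other groups and `"*"` when significantly lower than all
#' others at `alpha`.
#'
#' @param values Numeric response.
#' @param group Group labels (>= 2 groups, >= 2 observations each).
#' @param alpha Significance level for the all-pairs flags.
#' @return List of class `"posthoc_table"`: `f_statistic`, `f_p`,
#'   `contrasts` (`data.frame(contrast, estimate, lwr, upr, p_adj)`) and
#'   `flags` (`data.frame(group, flag)`).
#' @export
anova_tukey <- function(values, group, alpha = 0.05) {
  g <- factor(group)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("need at least 2 observations per group")
  dat <- data.frame(y = values, g = g)
  fit <- aov(y ~ g, data = dat)
  if (sum(fit$residuals^2) < .Machine$double.eps * sum(values^2) + 1e-300)
    stop("zero within-group variance")
  av <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  contrasts <- data.frame(contrast = rownames(tk), estimate = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE)
  lev <- levels(g)
  flags <- vapply(lev, function(gl) {
    pair <- strsplit(contrasts$contrast, "-", fixed = TRUE)
    inv <- vapply(pair, function(p) gl %in% p, logical(1))
    if (!any(inv)) return("")
    est <- contrasts$estimate[inv]
    # orient estimates as (this group) - (other group)
    first <- vapply(pair[inv], function(p) p[1] == gl, logical(1))
    est <- ifelse(first, est, -est)
    sig <- contrasts$p_adj[inv] < alpha
    if (all(sig) && all(est > 0)) "#"
    else if (all(sig) && all(est < 0)) "*"
    else ""
  }, character(1))
  structure(list(f_statistic = av[["F value"]][1], f_p = av[["Pr(>F)"]][1],
                 contrasts = contrasts,
                 flags = data.frame(group = lev, flag = unname(flags),
                                    stringsAsFactors = FALSE)),
            class = "posthoc_table")
}

#' @export
print.posthoc_table <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.3g\n", x$f_statistic, x$f_p))
  print(x$contrasts, row.names = FALSE)
  marked <- x$flags[x$flags$flag != "", , drop = FALSE]
  if (nrow(marked)) print(marked, row.names = FALSE)
  invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each term's overlap with a candidate
#' gene set against a universe, BH-adjusted over the tested terms. Term gene
#' lists are intersected with the universe before testing; terms overlapping
#' the candidates in fewer than `min_overlap` genes are not reported.
#'
#' @param candidates Character vector of candidate gene ids (subset of the
#'   universe).
#' @param terms Named list of term gene-id vectors.
#' @param universe Character vector of all eligible gene ids (typically all
#'   expressed genes after the 50% filter).
#' @param min_overlap Minimum candidate overlap for a term to be reported.
#' @param top Number of top-ranked terms to return.
#' @return `data.frame(term, term_size, set_size, overlap, p, p_adj, rank)`
#'   sorted by p.
#' @export
hypergeom_enrich <- function(candidates, terms, universe, min_overlap = 2L,
                             top = 10L) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  candidates <- unique(candidates)
  if (!all(candidates %in% universe))
    stop("candidates must be a subset of the universe")
  N <- length(universe)
  n <- length(candidates)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(terms[[tm]]), universe)
    k <- length(intersect(tg, candidates))
    if (k < min_overlap) return(NULL)
    K <- length(tg)
    data.frame(term = tm, term_size = K, set_size = n, overlap = k,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(term = character(0), term_size = integer(0),
                      set_size = integer(0), overlap = integer(0),
                      p = numeric(0), p_adj = numeric(0), rank = integer(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  head(out, top)
}
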