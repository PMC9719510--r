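#' Pearson correlation with t-distribution p-value
#'
#' Product-moment correlation coefficient with a two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors, length >= 3, neither constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs, got ", n)
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: constant input")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Quadrant proportions of paired fold changes
#'
#' Classifies points by the sign pair `(x, y)`:
#' Q1 `(+,+)`, Q2 `(-,+)`, Q3 `(-,-)`, Q4 `(+,-)`. Points lying on either
#' axis (`x == 0` or `y == 0`) are excluded from the fractions and counted.
#'
#' @param x,y paired numeric vectors.
#' @return list with `fractions` (named Q1..Q4, summing to 1; `NA` if every
#'   point is on an axis), `n_used`, `n_excluded`.
#' @export
quadrant_proportions <- function(x, y) {
  stopifnot(length(x) == length(y))
  on_axis <- x == 0 | y == 0
  xs <- x[!on_axis]; ys <- y[!on_axis]
  n <- length(xs)
  if (n == 0) {
    fr <- setNames(rep(NA_real_, 4), c("Q1", "Q2", "Q3", "Q4"))
  } else {
    fr <- c(Q1 = sum(xs > 0 & ys > 0), Q2 = sum(xs < 0 & ys > 0),
            Q3 = sum(xs < 0 & ys < 0), Q4 = sum(xs > 0 & ys < 0)) / n
  }
  list(fractions = fr, n_used = n, n_excluded = sum(on_axis))
}

#' Over-enrichment of the overlap between two gene sets
#'
#' One-sided hypergeometric upper-tail test of the overlap of two sets drawn
#' from a common universe, plus the 2x2 odds ratio (Haldane 0.5 correction
#' when any cell is zero).
#'
#' @param set_a,set_b character vectors of gene ids (or `gene_set` objects),
#'   both subsets of `universe`.
#' @param universe character vector (or `gene_set`) of all eligible genes.
#' @return an `overlap_enrichment` list: `n_universe`, `n_set_a`, `n_set_b`,
#'   `n_overlap`, `odds_ratio`, `pvalue`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  ids <- function(s) unique(if (inherits(s, "gene_set")) s$gene_ids else s)
  a <- ids(set_a); b <- ids(set_b); u <- ids(universe)
  if (!length(u)) stop("empty universe")
  if (!all(a %in% u) || !all(b %in% u))
    stop("both sets must be subsets of the universe")
  N <- length(u); nA <- length(a); nB <- length(b)
  k <- length(intersect(a, b))
  p <- phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
  cells <- c(k, nA - k, nB - k, N - nA - nB + k)
  if (any(cells == 0)) cells <- cells + 0.5
  structure(list(n_universe = N, n_set_a = nA, n_set_b = nB, n_overlap = k,
                 odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 pvalue = p),
            class = "overlap_enrichment")
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat(sprintf(
    "overlap_enrichment: %d / %d x %d in universe %d; OR = %.3g, p = %.3g\n",
    x$n_overlap, x$n_set_a, x$n_set_b, x$n_universe, x$odds_ratio, x$pvalue))
  invisible(x)
}

#' Correlate mRNA fold changes with region-stratified signal fold changes
#'
#' Inner-joins a gene-level differential-expression table (restricted to a
#' caller-supplied gene set when given) with per-gene signal fold changes
#' for one region class, then computes the Pearson correlation and quadrant
#' proportions of the paired `(mRNA log2FC, signal log2FC)` values. Genes
#' with no peaks in the requested class are dropped and counted.
#'
#' @param de_tab DE data.frame with `gene_id`, `log2fc`.
#' @param region_fc a `gene_region_fc` (from [gene_region_avg_log2fc()]), or
#'   a `gene_summed_fc` result when `region_class = "summed"`.
#' @param region_class one of `"promoter_5utr"`, `"genebody"`,
#'   `"distal_intergenic"`, or `"summed"`.
#' @param gene_set optional `gene_set` (or character vector) restricting the
#'   genes considered.
#' @param min_n minimum join size (default 3); smaller joins are an error.
#' @return an `integration_result`: `region_class`, `n_genes`, `pearson_r`,
#'   `pearson_p`, `significance_label` (`"NS"` when p >= 0.05),
#'   `quadrant_fractions`, `n_excluded_on_axis`, `n_dropped_no_peaks`, and
#'   the joined `pairs` data.frame.
#' @export
correlate_expression_signal <- function(de_tab, region_fc,
                                        region_class = "promoter_5utr",
                                        gene_set = NULL, min_n = 3) {
  if (!is.null(gene_set)) {
    ids <- if (inherits(gene_set, "gene_set")) gene_set$gene_ids else gene_set
    de_tab <- de_tab[de_tab$gene_id %in% ids, , drop = FALSE]
  }
  if (region_class == "summed") {
    if (!"summed_log2fc" %in% names(region_fc))
      stop("region_class 'summed' needs a gene_summed_fc table")
    sig <- data.frame(gene_id = region_fc$gene_id,
                      signal_log2fc = region_fc$summed_log2fc)
  } else {
    stopifnot(region_class %in% REGION_CLASSES)
    sub <- region_fc[region_fc$region_class == region_class, , drop = FALSE]
    sig <- data.frame(gene_id = sub$gene_id, signal_log2fc = sub$avg_log2fc)
  }
  joined <- merge(de_tab[, c("gene_id", "log2fc")], sig, by = "gene_id")
  n_dropped <- nrow(de_tab) - nrow(joined)
  if (nrow(joined) < min_n)
    stop("only ", nrow(joined), " genes with both mRNA and '", region_class,
         "' signal fold changes (need >= ", min_n, ")")
  pc <- pearson_correlation(joined$log2fc, joined$signal_log2fc)
  qp <- quadrant_proportions(joined$log2fc, joined$signal_log2fc)
  structure(list(region_class = region_class, n_genes = pc$n,
                 pearson_r = pc$r, pearson_p = pc$p,
                 significance_label = if (pc$p < 0.05)
                   format(pc$p, digits = 3) else "NS",
                 quadrant_fractions = qp$fractions,
                 n_excluded_on_axis = qp$n_excluded,
                 n_dropped_no_peaks = n_dropped,
                 pairs = joined),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("integration_result [%s]: n = %d, R = %.3f (p = %.3g%s)\n",
              x$region_class, x$n_genes, x$pearson_r, x$pearson_p,
              if (x$significance_label == "NS") ", NS" else ""))
  fr <- x$quadrant_fractions * 100
  cat(sprintf("  quadrants: Q1 %.1f%%  Q2 %.1f%%  Q3 %.1f%%  Q4 %.1f%%",
              fr[1], fr[2], fr[3], fr[4]))
  cat(sprintf("  (%d on-axis excluded, %d without peaks)\n",
              x$n_excluded_on_axis, x$n_dropped_no_peaks))
  invisible(x)
}

#' @export
plot.integration_result <- function(x, ...) {
  graphics::plot(x$pairs$log2fc, x$pairs$signal_log2fc,
                 xlab = "mRNA log2FC", ylab = "signal log2FC",
                 main = sprintf("%s: R = %.2f (%s)", x$region_class,
                                x$pearson_r, x$significance_label),
                 pch = 16, cex = 0.6,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Tabulate integration results as one row per region class
#' @param results list of `integration_result` objects.
#' @return data.frame with n, r, p, quadrant percentages and exclusions.
#' @export
integration_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    fr <- x$quadrant_fractions * 100
    data.frame(region_class = x$region_class, n_genes = x$n_genes,
               pearson_r = x$pearson_r, pearson_p = x$pearson_p,
               significance = x$significance_label,
               q1_pct = fr[1], q2_pct = fr[2], q3_pct = fr[3], q4_pct = fr[4],
               n_excluded_on_axis = x$n_excluded_on_axis,
               n_dropped_no_peaks = x$n_dropped_no_peaks,
               row.names = NULL)
  }))
}
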