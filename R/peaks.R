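#' Build consensus peaks across conditions
#'
#' Concatenates the per-condition peak calls and merges them into a disjoint
#' union (the common quantification frame), recording which conditions
#' contributed to each consensus peak.
#'
#' @param peak_sets named list of peak data frames (`chrom`, `start`, `end`),
#'   one per condition.
#' @return data.frame of disjoint sorted consensus peaks with a `sources`
#'   column (comma-separated contributing condition names).
#' @export
build_consensus_peaks <- function(peak_sets) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  if (is.null(names(peak_sets)) || any(!nzchar(names(peak_sets))))
    names(peak_sets) <- paste0("set", seq_along(peak_sets))
  all_pk <- do.call(rbind, lapply(names(peak_sets), function(nm) {
    p <- as.data.frame(validate_intervals(peak_sets[[nm]], nm))
    if (!nrow(p)) return(NULL)
    p[, c("chrom", "start", "end")]
  }))
  if (is.null(all_pk))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), sources = character()))
  consensus <- merge_intervals(all_pk)
  sources <- rep("", nrow(consensus))
  for (nm in sort(names(peak_sets))) {
    p <- peak_sets[[nm]]
    if (!nrow(p)) next
    hit <- rep(FALSE, nrow(consensus))
    hits <- .point_overlaps(.midpoint(p$start, p$end), as.character(p$chrom),
                            consensus)
    hit[unique(hits$subject)] <- TRUE
    sources <- ifelse(hit, ifelse(nzchar(sources),
                                  paste(sources, nm, sep = ","), nm), sources)
  }
  consensus$sources <- sources
  consensus
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the reference of each peak is the
#' geometric mean of its counts over samples (peaks with any zero excluded);
#' a sample's factor is the median over peaks of `count / reference`. When no
#' peak has all-positive counts, library-size factors
#' (column sum / geometric mean of column sums) are used instead, with a
#' message.
#'
#' @param counts non-negative numeric matrix, peaks x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero count matrix")
  pos <- rowSums(counts == 0) == 0
  if (any(pos)) {
    logc <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(logc)  # log geometric mean
    fac <- apply(exp(logc - ref), 2, median)
  } else {
    message("no peak with all-positive counts; ",
            "falling back to library-size factors")
    cs <- colSums(counts)
    fac <- cs / exp(mean(log(cs)))
  }
  if (is.null(names(fac))) names(fac) <- colnames(counts)
  fac
}

#' Per-peak log2 fold changes with a Welch test stand-in
#'
#' Counts are divided by size factors; the per-peak statistic is
#' `log2((mean2 + pc) / (mean1 + pc))` on condition means of normalized
#' counts. With >= 2 replicates per condition a two-sided Welch t-test on
#' `log2(normalized + 1)` is applied per peak and BH-adjusted across all
#' peaks jointly; significance flags are set at `alpha` on the adjusted
#' p-value. With fewer replicates p-values are `NA` and significance is
#' proxied by `|log2fc| >= 1` (marked by the `proxy_significance` attribute).
#'
#' @param counts peaks x samples count matrix.
#' @param factors per-sample size factors (default: [size_factors()]).
#' @param condition character/factor of length `ncol(counts)` with exactly
#'   two levels; fold changes are condition2 over condition1.
#' @param ref reference (condition1) level; default the first factor level.
#' @param pseudocount added to both condition means (default 1).
#' @param alpha significance level on BH-adjusted p-values (default 0.05).
#' @return a `peak_differential` data.frame: `log2fc`, `pvalue`,
#'   `adjusted_pvalue`, `significant_up`, `significant_down`.
#' @export
peak_log2fc <- function(counts, factors = size_factors(counts), condition,
                        ref = NULL, pseudocount = 1, alpha = 0.05) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(counts), length(factors) == ncol(counts))
  lev <- unique(condition)
  if (length(lev) != 2) stop("exactly two conditions required, got: ",
                             paste(lev, collapse = ", "))
  if (!is.null(ref)) {
    if (!ref %in% lev) stop("ref condition '", ref, "' not present")
    lev <- c(ref, setdiff(lev, ref))
  }
  i1 <- condition == lev[1]; i2 <- condition == lev[2]
  norm <- sweep(counts, 2, factors, "/")
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  log2fc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 >= 2 && n2 >= 2) {
    l <- log2(norm + 1)
    a <- l[, i1, drop = FALSE]; b <- l[, i2, drop = FALSE]
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
    se2 <- va / n1 + vb / n2
    tt <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / n1)^2 / (n1 - 1) + (vb / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tt), df)
    # degenerate-variance guard: identical replicates within both groups
    zero <- se2 == 0
    p[zero & ma == mb] <- 1
    p[zero & ma != mb] <- .Machine$double.xmin
    p[is.na(p)] <- 1
    padj <- p.adjust(p, method = "BH")
    sig_up <- padj < alpha & log2fc > 0
    sig_dn <- padj < alpha & log2fc < 0
    proxy <- FALSE
  } else {
    p <- rep(NA_real_, nrow(counts)); padj <- p
    sig_up <- log2fc >= 1
    sig_dn <- log2fc <= -1
    proxy <- TRUE
  }
  out <- data.frame(log2fc = log2fc, pvalue = p, adjusted_pvalue = padj,
                    significant_up = sig_up, significant_down = sig_dn)
  attr(out, "conditions") <- lev
  attr(out, "alpha") <- alpha
  attr(out, "pseudocount") <- pseudocount
  attr(out, "proxy_significance") <- proxy
  class(out) <- c("peak_differential", "data.frame")
  out
}

#' Per-gene summed-peak log2 fold change
#'
#' The gene-locus statistic: normalized counts of all peaks assigned to a
#' gene (promoter/5'UTR and gene-body classes by default) are summed within
#' each condition before taking the log2 ratio:
#' `log2((sum cond2 + pc) / (sum cond1 + pc))`. Genes with no assigned peak
#' are absent from the output.
#'
#' @param annotation output of [assign_region()] for the counted peaks
#'   (rows aligned with `counts`).
#' @param counts,factors,condition,ref,pseudocount as in [peak_log2fc()].
#' @param classes region classes counted as part of the gene locus.
#' @return data.frame `gene_id`, `summed_log2fc`, `n_peaks`.
#' @export
gene_summed_fc <- function(annotation, counts, factors = size_factors(counts),
                           condition, ref = NULL, pseudocount = 1,
                           classes = c("promoter_5utr", "genebody")) {
  counts <- as.matrix(counts)
  stopifnot(nrow(annotation) == nrow(counts))
  condition <- as.character(condition)
  lev <- unique(condition)
  if (length(lev) != 2) stop("exactly two conditions required")
  if (!is.null(ref)) lev <- c(ref, setdiff(lev, ref))
  norm <- sweep(counts, 2, factors, "/")
  m1 <- rowMeans(norm[, condition == lev[1], drop = FALSE])
  m2 <- rowMeans(norm[, condition == lev[2], drop = FALSE])
  keep <- annotation$region_class %in% classes & !is.na(annotation$gene_id)
  if (!any(keep))
    return(data.frame(gene_id = character(), summed_log2fc = numeric(),
                      n_peaks = integer()))
  gid <- annotation$gene_id[keep]
  s1 <- tapply(m1[keep], gid, sum)
  s2 <- tapply(m2[keep], gid, sum)
  np <- tapply(gid, gid, length)
  out <- data.frame(gene_id = names(s1),
                    summed_log2fc = log2((as.numeric(s2) + pseudocount) /
                                           (as.numeric(s1) + pseudocount)),
                    n_peaks = as.integer(np))
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Per-gene, per-region-class average log2 fold change
#'
#' For each gene and region class, the arithmetic mean of the per-peak log2
#' fold changes of all peaks assigned there, regardless of significance.
#' Promoter/5'UTR and gene-body peaks group by their assigned `gene_id`;
#' distal intergenic peaks group by `nearest_gene`. Gene-class combinations
#' with no peaks are absent (not zero).
#'
#' @param peak_diff a `peak_differential` (rows aligned with `annotation`).
#' @param annotation output of [assign_region()] for the same peaks.
#' @return a `gene_region_fc` data.frame: `gene_id`, `region_class`,
#'   `avg_log2fc`, `n_peaks`.
#' @export
gene_region_avg_log2fc <- function(peak_diff, annotation) {
  stopifnot(nrow(peak_diff) == nrow(annotation))
  gene_key <- ifelse(annotation$region_class == "distal_intergenic",
                     annotation$nearest_gene, annotation$gene_id)
  keep <- !is.na(gene_key)
  key <- paste(gene_key[keep], annotation$region_class[keep], sep = "\r")
  avg <- tapply(peak_diff$log2fc[keep], key, mean)
  np <- tapply(key, key, length)
  parts <- strsplit(names(avg), "\r", fixed = TRUE)
  out <- data.frame(gene_id = vapply(parts, `[`, "", 1),
                    region_class = vapply(parts, `[`, "", 2),
                    avg_log2fc = as.numeric(avg),
                    n_peaks = as.integer(np))
  out <- out[order(out$gene_id, out$region_class), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_region_fc", "data.frame")
  out
}

#' Read peak calls from BED3+ or narrowPeak
#'
#' Only the first three columns are used; extra columns are ignored.
#'
#' @param path BED / narrowPeak path.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
read_peaks <- function(path) {
  first <- readLines(path, n = 1)
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (ncol >= 10) {
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
    gr <- rtracklayer::import(path, format = "bed", extraCols = extra)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
  }
  df <- as.data.frame(gr)
  out <- data.frame(chrom = as.character(df$seqnames), start = df$start - 1,
                    end = df$end)
  validate_intervals(out, "peaks")
  out
}

#' Write intervals as BED3(+name)
#' @param x interval data.frame; optional `name` column becomes column 4.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start),
                   as.integer(x$end))
  if (!is.null(x$name)) lines <- paste(lines, x$name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-peak count table
#'
#' TSV with header: `chrom`, `start`, `end`, then one column per sample.
#'
#' @param path counts TSV path.
#' @return list with `peaks` (data.frame) and `counts` (matrix).
#' @export
read_peak_counts <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(tab)))
    stop("counts TSV must have chrom/start/end columns")
  peaks <- tab[, need]
  validate_intervals(peaks, "count peaks")
  counts <- as.matrix(tab[, setdiff(names(tab), need), drop = FALSE])
  storage.mode(counts) <- "numeric"
  list(peaks = peaks, counts = counts)
}
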