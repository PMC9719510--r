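#' Partition gene loci into promoter/5'UTR and gene-body regions
#'
#' For each gene, the promoter/5'UTR class is the strand-aware promoter
#' window around the TSS (default +/- 3000 bp) unioned with any annotated
#' 5'UTR; the gene-body class is the TSS-TES span (exons, introns and 3'UTR)
#' minus the promoter/5'UTR intervals. Positions covered by neither class of
#' any gene are implicitly distal intergenic.
#'
#' @param gm a `gene_models` object.
#' @param promoter_window numeric length-2, bp upstream and downstream of the
#'   TSS (transcription-oriented).
#' @return A `region_partition` object: list with `intervals`
#'   (data.frame `gene_id`, `chrom`, `start`, `end`, `region_class`),
#'   `genes` and `promoter_window`.
#' @export
partition_regions <- function(gm, promoter_window = c(3000, 3000)) {
  stopifnot(inherits(gm, "gene_models"), length(promoter_window) == 2,
            all(promoter_window >= 0))
  g <- gm$genes
  if (nrow(g)) {
    up <- promoter_window[1]; down <- promoter_window[2]
    plus <- g$strand == "+"
    win_lo <- pmax(0, ifelse(plus, g$tss - up, g$tss - down))
    win_hi <- ifelse(plus, g$tss + down, g$tss + up)
    # per-gene set algebra in one pass: group ranges by gene via seqnames
    grp_ranges <- function(ids, start, end) {
      GenomicRanges::GRanges(factor(ids, levels = g$gene_id),
                             .iranges(start, end))
    }
    prom <- GenomicRanges::reduce(c(
      grp_ranges(g$gene_id, win_lo, win_hi),
      grp_ranges(gm$utr5$gene_id, gm$utr5$start, gm$utr5$end)))
    span <- GenomicRanges::reduce(c(
      grp_ranges(g$gene_id, pmin(g$tss, g$tes), pmax(g$tss, g$tes)),
      grp_ranges(gm$utr3$gene_id, gm$utr3$start, gm$utr3$end)))
    body <- GenomicRanges::setdiff(span, prom)
    as_df <- function(gr, cls) {
      ids <- as.character(GenomicRanges::seqnames(gr))
      data.frame(gene_id = ids, chrom = g$chrom[match(ids, g$gene_id)],
                 start = GenomicRanges::start(gr) - 1,
                 end = GenomicRanges::end(gr), region_class = cls,
                 stringsAsFactors = FALSE)
    }
    intervals <- rbind(as_df(prom, "promoter_5utr"), as_df(body, "genebody"))
    intervals <- intervals[order(intervals$gene_id, intervals$start), ,
                           drop = FALSE]
  } else {
    intervals <- data.frame(gene_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            region_class = character())
  }
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, genes = g,
                 promoter_window = promoter_window),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("region_partition:", nrow(x$genes), "genes; promoter window -",
      x$promoter_window[1], "/ +", x$promoter_window[2], "bp\n")
  tab <- table(x$intervals$region_class)
  for (cls in names(tab)) cat("  ", cls, ":", tab[[cls]], "intervals\n")
  invisible(x)
}

#' Region classes of the package
#' @export
REGION_CLASSES <- c("promoter_5utr", "genebody", "distal_intergenic")

#' Assign peaks to region classes and genes
#'
#' Each peak is classified by its midpoint with precedence
#' promoter/5'UTR > gene body > distal intergenic. When the midpoint falls in
#' the same class of several genes, the gene whose TSS is closest to the
#' midpoint wins; remaining ties break by lexicographic `gene_id`. Distal
#' intergenic peaks carry `gene_id = NA` but always report the nearest gene
#' (by TSS distance), which downstream region-stratified statistics use to
#' associate intergenic peaks with loci.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param partition a `region_partition`.
#' @return data.frame: the peak coordinates plus `midpoint`, `region_class`,
#'   `gene_id` (NA for distal intergenic) and `nearest_gene`.
#' @export
assign_region <- function(peaks, partition) {
  stopifnot(inherits(partition, "region_partition"))
  peaks <- as.data.frame(validate_intervals(peaks, "peaks"))
  n <- nrow(peaks)
  mid <- .midpoint(peaks$start, peaks$end)
  cls <- rep("distal_intergenic", n)
  gene <- rep(NA_character_, n)
  g <- partition$genes
  known <- as.character(peaks$chrom) %in% unique(g$chrom)
  if (any(!known))
    warning(sum(!known), " peak(s) on chromosomes absent from the ",
            "annotation assigned to distal_intergenic")
  iv <- partition$intervals
  unassigned <- which(known)
  for (class_now in c("promoter_5utr", "genebody")) {
    if (!length(unassigned)) break
    sub <- iv[iv$region_class == class_now, , drop = FALSE]
    hits <- .point_overlaps(mid[unassigned], as.character(peaks$chrom)[unassigned], sub)
    if (!nrow(hits)) next
    hits$peak <- unassigned[hits$query]
    hits$gene_id <- sub$gene_id[hits$subject]
    hits$tssdist <- abs(mid[hits$peak] - g$tss[match(hits$gene_id, g$gene_id)])
    hits <- hits[order(hits$peak, hits$tssdist, hits$gene_id), , drop = FALSE]
    best <- hits[!duplicated(hits$peak), , drop = FALSE]
    cls[best$peak] <- class_now
    gene[best$peak] <- best$gene_id
    unassigned <- setdiff(unassigned, best$peak)
  }
  # nearest gene by |midpoint - TSS| on the same chromosome, for every peak;
  # ties break by lexicographic gene_id (secondary sort + first occurrence)
  nearest <- rep(NA_character_, n)
  for (ch in unique(as.character(peaks$chrom))) {
    gi <- which(g$chrom == ch)
    if (!length(gi)) next
    pi <- which(peaks$chrom == ch)
    ord <- gi[order(g$tss[gi], g$gene_id[gi])]
    ts <- g$tss[ord]; ids <- g$gene_id[ord]; ng <- length(ord)
    k <- findInterval(mid[pi], ts)
    li <- pmax(k, 1); ri <- pmin(k + 1, ng)
    first_of <- function(idx) findInterval(ts[idx], ts, left.open = TRUE) + 1
    li <- first_of(li); ri <- first_of(ri)
    dl <- abs(mid[pi] - ts[li]); dr <- abs(mid[pi] - ts[ri])
    use_r <- (k == 0) | (dr < dl) | (dr == dl & ids[ri] < ids[li])
    nearest[pi] <- ids[ifelse(use_r, ri, li)]
  }
  cbind(peaks[, c("chrom", "start", "end"), drop = FALSE],
        data.frame(midpoint = mid, region_class = cls, gene_id = gene,
                   nearest_gene = nearest, stringsAsFactors = FALSE))
}

#' Write a region partition as BED6
#'
#' One line per partition interval, `name = class:gene_id`, score 0.
#'
#' @param partition a `region_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_bed <- function(partition, path) {
  iv <- partition$intervals
  strand <- partition$genes$strand[match(iv$gene_id, partition$genes$gene_id)]
  lines <- sprintf("%s\t%d\t%d\t%s:%s\t0\t%s", iv$chrom,
                   as.integer(iv$start), as.integer(iv$end),
                   iv$region_class, iv$gene_id, strand)
  writeLines(lines, path)
  invisible(path)
}
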