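# Independent brute-force oracles and toy-data builders used by the tests.
# The oracles deliberately avoid the code paths they check: set arithmetic
# is done per base over small coordinate spaces, statistics by their
# defining formulas.

# per-base set-union merge of intervals with coordinates < limit
oracle_merge <- function(intervals, limit = 1200) {
  out <- list()
  for (ch in sort(unique(as.character(intervals$chrom)))) {
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    covered <- rep(FALSE, limit)
    for (i in seq_len(nrow(sub))) {
      covered[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep])
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  df <- do.call(rbind, unname(out))
  rownames(df) <- NULL
  df
}

# a random toy genome as a gene_models object; genes may overlap
make_toy_genome <- function(n_genes = 8, chrom = c("c1", "c2"),
                            span_max = 900) {
  starts <- sample(0:(span_max - 120), n_genes, replace = TRUE)
  lens <- sample(60:120, n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  ids <- sprintf("t%02d", seq_len(n_genes))
  chs <- sample(chrom, n_genes, replace = TRUE)
  genes <- data.frame(gene_id = ids, chrom = chs, strand = strand,
                      start = starts, end = starts + lens,
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  genes$tss <- ifelse(strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(strand == "+", genes$end, genes$start)
  exons <- data.frame(gene_id = ids, chrom = chs, start = starts,
                      end = starts + lens, stringsAsFactors = FALSE)
  # random terminal UTRs on about half the genes
  has_u <- runif(n_genes) < 0.5
  u5 <- genes[has_u, , drop = FALSE]
  utr5 <- data.frame(
    gene_id = u5$gene_id, chrom = u5$chrom,
    start = ifelse(u5$strand == "+", u5$start, u5$end - 10),
    end = ifelse(u5$strand == "+", u5$start + 10, u5$end))
  utr3 <- data.frame(
    gene_id = u5$gene_id, chrom = u5$chrom,
    start = ifelse(u5$strand == "+", u5$end - 10, u5$start),
    end = ifelse(u5$strand == "+", u5$end, u5$start + 10))
  chromexpr:::.gene_models(genes, exons, utr5, utr3)
}

# per-base region sets for one gene under the midpoint/precedence rules
.oracle_gene_sets <- function(gm, i, window) {
  g <- gm$genes[i, ]
  up <- window[1]; down <- window[2]
  if (g$strand == "+") {
    prom <- seq.int(max(0, g$tss - up), g$tss + down - 1)
  } else {
    prom <- seq.int(max(0, g$tss - down), g$tss + up - 1)
  }
  u5 <- gm$utr5[gm$utr5$gene_id == g$gene_id, , drop = FALSE]
  for (j in seq_len(nrow(u5)))
    prom <- union(prom, seq.int(u5$start[j], u5$end[j] - 1))
  span <- seq.int(min(g$tss, g$tes), max(g$tss, g$tes) - 1)
  u3 <- gm$utr3[gm$utr3$gene_id == g$gene_id, , drop = FALSE]
  for (j in seq_len(nrow(u3)))
    span <- union(span, seq.int(u3$start[j], u3$end[j] - 1))
  list(promoter = prom, body = setdiff(span, prom))
}

# explicit scan over all genes applying precedence, TSS distance and
# lexicographic tie-breaks for a single peak midpoint
oracle_assign <- function(mid, chrom, gm, window) {
  g <- gm$genes
  cand <- which(g$chrom == chrom)
  sets <- lapply(cand, function(i) .oracle_gene_sets(gm, i, window))
  pick <- function(indices) {
    d <- abs(mid - g$tss[indices])
    indices[order(d, g$gene_id[indices])][1]
  }
  in_prom <- cand[vapply(seq_along(cand),
                         function(j) mid %in% sets[[j]]$promoter, TRUE)]
  if (length(in_prom))
    return(list(class = "promoter_5utr", gene = g$gene_id[pick(in_prom)]))
  in_body <- cand[vapply(seq_along(cand),
                         function(j) mid %in% sets[[j]]$body, TRUE)]
  if (length(in_body))
    return(list(class = "genebody", gene = g$gene_id[pick(in_body)]))
  nearest <- if (length(cand)) g$gene_id[pick(cand)] else NA_character_
  list(class = "distal_intergenic", gene = NA_character_, nearest = nearest)
}

# mean per-peak log2fc per (gene, class) by explicit looping
oracle_region_avg <- function(log2fc, gene_key, region_class) {
  keep <- !is.na(gene_key)
  log2fc <- log2fc[keep]; gene_key <- gene_key[keep]
  region_class <- region_class[keep]
  out <- list()
  for (gene in unique(gene_key)) {
    for (cls in unique(region_class[gene_key == gene])) {
      sel <- gene_key == gene & region_class == cls
      out[[paste(gene, cls)]] <- data.frame(
        gene_id = gene, region_class = cls,
        avg_log2fc = sum(log2fc[sel]) / sum(sel), n_peaks = sum(sel))
    }
  }
  df <- do.call(rbind, unname(out))
  df <- df[order(df$gene_id, df$region_class), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# product-moment r from the covariance formula, no cor()
oracle_pearson_r <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# upper-tail hypergeometric p by direct combinatorial enumeration
oracle_hyper_p <- function(k, nA, nB, N) {
  js <- k:min(nA, nB)
  sum(choose(nA, js) * choose(N - nA, nB - js)) / choose(N, nB)
}

# small random interval set on 1-2 chromosomes, coords < 1000
random_intervals <- function(max_n = 10, n = sample.int(max_n, 1)) {
  s <- sample(0:980, n, replace = TRUE)
  data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
             start = s, end = s + sample(1:20, n, replace = TRUE))
}
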