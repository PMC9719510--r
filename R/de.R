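#' Read a gene-level differential-expression table
#'
#' TSV with header: `gene_id`, `biotype`, `log2fc`, `pvalue`, then FPKM
#' columns named `fpkm_<sample>`.
#'
#' @param path TSV path.
#' @return data.frame, one row per gene.
#' @export
read_de_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "biotype", "log2fc", "pvalue")
  if (!all(need %in% names(tab)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene_id)) stop("duplicated gene_id in DE table")
  tab
}

#' Write a differential-expression table as TSV
#' @param tab DE data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# FPKM matrix (genes x samples) from fpkm_<sample> columns
.fpkm_matrix <- function(tab) {
  cols <- grep("^fpkm_", names(tab), value = TRUE)
  if (!length(cols)) stop("DE table has no fpkm_<sample> columns")
  m <- as.matrix(tab[, cols, drop = FALSE])
  colnames(m) <- sub("^fpkm_", "", cols)
  rownames(m) <- tab$gene_id
  m
}

#' Filter a DE table to significantly changed genes
#'
#' Keeps genes meeting all three criteria: (1) `pvalue < p_cutoff`;
#' (2) protein-coding biotype; (3) mean FPKM above `fpkm_cutoff` in at least
#' one of the two conditions. Genes with missing biotype are excluded with a
#' warning.
#'
#' @param tab DE data.frame (see [read_de_table()]).
#' @param conditions named character vector mapping sample name (as in the
#'   `fpkm_<sample>` columns) to condition; exactly two conditions.
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param fpkm_cutoff per-condition mean-FPKM cutoff (default 5).
#' @param biotype biotype retained (default `"protein_coding"`).
#' @return the filtered DE data.frame (subset of the input rows).
#' @export
filter_significant_genes <- function(tab, conditions, p_cutoff = 0.05,
                                     fpkm_cutoff = 5,
                                     biotype = "protein_coding") {
  fpkm <- .fpkm_matrix(tab)
  if (!all(colnames(fpkm) %in% names(conditions)))
    stop("conditions must name every fpkm_<sample> column")
  cond <- conditions[colnames(fpkm)]
  lev <- unique(cond)
  if (length(lev) != 2) stop("exactly two conditions required")
  m1 <- rowMeans(fpkm[, cond == lev[1], drop = FALSE])
  m2 <- rowMeans(fpkm[, cond == lev[2], drop = FALSE])
  bt <- tab$biotype
  if (any(is.na(bt))) {
    warning(sum(is.na(bt)), " gene(s) with missing biotype excluded")
  }
  keep <- !is.na(bt) & bt == biotype & tab$pvalue < p_cutoff &
    (m1 > fpkm_cutoff | m2 > fpkm_cutoff)
  tab[keep, , drop = FALSE]
}

.new_gene_set <- function(label, gene_ids, metadata) {
  structure(list(label = label, gene_ids = gene_ids, metadata = metadata),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$label, "': ", length(x$gene_ids), " genes\n", sep = "")
  md <- x$metadata
  cat("  ", paste(names(md), unlist(lapply(md, format)), sep = "=",
                  collapse = "; "), "\n")
  invisible(x)
}

#' Derive a signature gene set from a two-group comparison
#'
#' Filters to `pvalue < p_cutoff` and linear fold change at least
#' `fc_cutoff` in the requested direction, then (optionally) ranks and
#' truncates to the top `n`. Ranking by p-value is ascending with
#' `|fold change|` descending as tie-break; ranking by fold change is
#' `|log2fc|` descending with p-value ascending as tie-break; final ties
#' break by `gene_id`.
#'
#' @param tab DE data.frame with `gene_id`, `log2fc`, `pvalue`.
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param fc_cutoff linear-scale fold-change cutoff (default 2).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param top_n optional truncation size.
#' @param rank_by `"pvalue"` or `"fold_change"`.
#' @param label gene-set label.
#' @return a `gene_set` (ids plus derivation metadata).
#' @export
derive_signature <- function(tab, p_cutoff = 0.05, fc_cutoff = 2,
                             direction = c("up", "down", "both"),
                             top_n = NULL,
                             rank_by = c("pvalue", "fold_change"),
                             label = "signature") {
  direction <- match.arg(direction)
  rank_by <- match.arg(rank_by)
  stopifnot(fc_cutoff >= 1)
  lfc_cut <- log2(fc_cutoff)
  pass_fc <- switch(direction,
                    up = tab$log2fc >= lfc_cut,
                    down = tab$log2fc <= -lfc_cut,
                    both = abs(tab$log2fc) >= lfc_cut)
  sub <- tab[tab$pvalue < p_cutoff & pass_fc, , drop = FALSE]
  ord <- if (rank_by == "pvalue") {
    order(sub$pvalue, -abs(sub$log2fc), sub$gene_id)
  } else {
    order(-abs(sub$log2fc), sub$pvalue, sub$gene_id)
  }
  sub <- sub[ord, , drop = FALSE]
  if (!is.null(top_n)) {
    if (top_n > nrow(sub)) {
      warning("top_n = ", top_n, " exceeds the ", nrow(sub),
              " qualifying genes; returning all")
    }
    sub <- head(sub, top_n)
  }
  .new_gene_set(label, sub$gene_id,
                list(p_cutoff = p_cutoff, fc_cutoff = fc_cutoff,
                     direction = direction, top_n = top_n, rank_by = rank_by,
                     n = nrow(sub)))
}

#' Top N most significantly changed genes
#'
#' The `n` smallest p-values regardless of direction, ties broken by
#' `|log2fc|` descending then `gene_id`. Intended to run on an already
#' filtered table (see [filter_significant_genes()]).
#'
#' @param tab DE data.frame.
#' @param n number of genes (default 200).
#' @param label gene-set label.
#' @return a `gene_set`.
#' @export
top_changed_genes <- function(tab, n = 200, label = "top_changed") {
  if (n > nrow(tab)) {
    warning("n = ", n, " exceeds table size ", nrow(tab), "; returning all")
    n <- nrow(tab)
  }
  ord <- order(tab$pvalue, -abs(tab$log2fc), tab$gene_id)
  ids <- tab$gene_id[ord][seq_len(n)]
  .new_gene_set(label, ids, list(n = n, rank_by = "pvalue"))
}

#' Write / read a gene set (one id per line, metadata header)
#' @param gs a `gene_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gs, path) {
  md <- gs$metadata
  hdr <- c(paste0("# label: ", gs$label),
           vapply(names(md), function(k) {
             paste0("# ", k, ": ",
                    if (is.null(md[[k]])) "NULL" else format(md[[k]]))
           }, ""))
  writeLines(c(hdr, gs$gene_ids), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @param path path to a gene-set file.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  label <- sub("^# label: ", "", lines[hdr][1])
  .new_gene_set(label, lines[!hdr & nzchar(lines)], list(source = path))
}

#' Per-sample Z-score standardization of an FPKM matrix
#'
#' Standardizes each sample (column) over genes:
#' `Z = (x - mu) / sigma` with the column mean and sample (n-1) standard
#' deviation of that sample's FPKM values.
#'
#' @param fpkm numeric matrix, genes x samples.
#' @return matrix of Z values, same dimensions.
#' @export
zscore_by_sample <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (nrow(fpkm) < 2) stop("need >= 2 genes per sample")
  mu <- colMeans(fpkm)
  sigma <- apply(fpkm, 2, sd)
  if (any(sigma == 0)) {
    bad <- colnames(fpkm)[sigma == 0]
    if (is.null(bad)) bad <- which(sigma == 0)
    stop("constant FPKM column (sample ", paste(bad, collapse = ", "),
         "): Z-score undefined")
  }
  sweep(sweep(fpkm, 2, mu, "-"), 2, sigma, "/")
}

#' Colitis histology score
#'
#' Sums the four H&E scoring parameters: inflammatory infiltration of the
#' lamina propria (1-3), goblet-cell loss (0-2), mucosal erosion to
#' ulceration (0-2) and submucosal spread to transmural involvement (0-2);
#' the total severity score ranges 1-9.
#'
#' @param infiltration integer in 1..3.
#' @param goblet_loss,erosion,submucosal_spread integers in 0..2.
#' @return a `histology_score` data.frame with the four parameters and
#'   `total` (vectorized over inputs).
#' @export
histology_colitis_score <- function(infiltration, goblet_loss, erosion,
                                    submucosal_spread) {
  chk <- function(x, nm, lo, hi) {
    if (any(is.na(x)) || any(x != as.integer(x)) || any(x < lo | x > hi))
      stop(nm, " must be an integer in ", lo, "..", hi)
    as.integer(x)
  }
  infiltration <- chk(infiltration, "infiltration", 1, 3)
  goblet_loss <- chk(goblet_loss, "goblet_loss", 0, 2)
  erosion <- chk(erosion, "erosion", 0, 2)
  submucosal_spread <- chk(submucosal_spread, "submucosal_spread", 0, 2)
  out <- data.frame(infiltration = infiltration, goblet_loss = goblet_loss,
                    erosion = erosion, submucosal_spread = submucosal_spread,
                    total = infiltration + goblet_loss + erosion +
                      submucosal_spread)
  class(out) <- c("histology_score", "data.frame")
  out
}
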