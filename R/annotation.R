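#' Read a gene annotation (GTF or BED12)
#'
#' Parses gene models from a GTF file (1-based closed coordinates, converted
#' to 0-based half-open on read) or a BED12 file (already 0-based). One model
#' is kept per gene; when a gene has several transcripts the one with the
#' longest genomic span is used. The transcription start site (TSS) of a
#' minus-strand gene is the rightmost coordinate of its span.
#'
#' @param path path to a GTF (`.gtf`) or BED12 (`.bed`) file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return A `gene_models` object: a list with data frames `genes`
#'   (`gene_id`, `chrom`, `strand`, `start`, `end`, `tss`, `tes`, `biotype`),
#'   `exons`, `utr5`, `utr3` (each `gene_id`, `chrom`, `start`, `end`).
#' @export
read_gene_annotation <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  if (format == "gtf") .read_gtf(path) else .read_bed12(path)
}

.read_gtf <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  # light structural validation so malformed lines are reported by number
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    bad <- which(body)[which(nf < 9)[1]]
    stop("malformed GTF line ", bad, ": expected >= 9 tab-separated fields")
  }
  st <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
  en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
  if (any(is.na(st) | is.na(en))) {
    bad <- which(body)[which(is.na(st) | is.na(en))[1]]
    stop("malformed GTF line ", bad, ": non-numeric coordinates")
  }
  drop <- en < st  # zero/negative-length record in 1-based closed coords
  if (any(drop)) {
    warning(sum(drop), " GTF record(s) with end < start rejected")
    tmp <- tempfile(fileext = ".gtf")
    writeLines(c(lines[!body], lines[body][!drop]), tmp)
    path <- tmp
    on.exit(unlink(tmp))
  }
  gr <- suppressWarnings(rtracklayer::import(path, format = "gtf"))
  df <- as.data.frame(gr)
  df$chrom <- as.character(df$seqnames)
  df$start0 <- df$start - 1  # to 0-based half-open
  df$end0 <- df$end
  df$type <- as.character(df$type)
  if (is.null(df$gene_id)) stop("GTF lacks gene_id attributes")
  biotype <- df$gene_biotype
  if (is.null(biotype)) biotype <- df$gene_type
  if (is.null(biotype)) biotype <- rep(NA_character_, nrow(df))
  df$biotype <- as.character(biotype)

  ex <- df[df$type == "exon", , drop = FALSE]
  if (!nrow(ex)) stop("GTF contains no exon records")
  # one model per gene: longest-span transcript when annotated
  if (!is.null(ex$transcript_id) && !all(is.na(ex$transcript_id))) {
    span <- tapply(seq_len(nrow(ex)), ex$transcript_id, function(i) {
      max(ex$end0[i]) - min(ex$start0[i])
    })
    tx_gene <- tapply(ex$gene_id, ex$transcript_id, `[`, 1)
    keep_tx <- vapply(split(names(span), unlist(tx_gene)), function(txs) {
      txs[order(-span[txs], txs)][1]
    }, "")
    ex <- ex[ex$transcript_id %in% keep_tx, , drop = FALSE]
    df <- df[is.na(df$transcript_id) | df$transcript_id %in% keep_tx, ,
             drop = FALSE]
  }

  gene_ids <- sort(unique(as.character(ex$gene_id)))
  pick <- function(types) {
    sel <- df[df$type %in% types, c("gene_id", "chrom", "start0", "end0")]
    names(sel) <- c("gene_id", "chrom", "start", "end")
    sel <- sel[order(sel$gene_id, sel$start), , drop = FALSE]
    rownames(sel) <- NULL
    sel
  }
  exons <- pick("exon")
  utr5 <- pick(c("five_prime_utr", "5UTR"))
  utr3 <- pick(c("three_prime_utr", "3UTR"))

  first <- match(gene_ids, ex$gene_id)
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(ex$chrom[first]),
    strand = as.character(ex$strand[first]),
    start = as.numeric(tapply(ex$start0, ex$gene_id, min)[gene_ids]),
    end = as.numeric(tapply(ex$end0, ex$gene_id, max)[gene_ids]),
    stringsAsFactors = FALSE
  )
  bt <- df$biotype[match(gene_ids, df$gene_id)]
  genes$biotype <- ifelse(is.na(bt), "unknown", bt)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  .gene_models(genes, exons, utr5, utr3)
}

.read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  if (is.null(df$blocks)) stop("BED input lacks block (BED12) structure")
  genes <- data.frame(
    gene_id = as.character(df$name),
    chrom = as.character(df$seqnames),
    strand = ifelse(as.character(df$strand) %in% c("+", "-"),
                    as.character(df$strand), "+"),
    start = df$start - 1,
    end = df$end,
    biotype = "unknown",
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  blocks <- gr$blocks  # block coords are relative to chromStart, 1-based
  exons <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(
      gene_id = genes$gene_id[i], chrom = genes$chrom[i],
      start = genes$start[i] + IRanges::start(b) - 1,
      end = genes$start[i] + IRanges::end(b)
    )
  }))
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric())
  .gene_models(genes, exons, empty, empty)
}

.gene_models <- function(genes, exons, utr5, utr3) {
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in annotation")
  structure(
    list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s);",
      nrow(x$exons), "exons,", nrow(x$utr5), "5'UTRs,",
      nrow(x$utr3), "3'UTRs\n")
  invisible(x)
}

#' Write gene models as GTF
#'
#' Emits gene, exon and UTR records (1-based closed coordinates) with
#' `gene_id`, `transcript_id` and `gene_biotype` attributes. Output bytes are
#' deterministic for a given object.
#'
#' @param gm a `gene_models` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gm, path) {
  g <- gm$genes
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tchromexpr\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, as.integer(start + 1), as.integer(end), strand, attrs)
  }
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_biotype "%s";',
                     id, id, g$biotype[i])
    lines <- c(lines,
               fmt(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i], attrs))
    for (tab in c("exons", "utr5", "utr3")) {
      type <- c(exons = "exon", utr5 = "five_prime_utr",
                utr3 = "three_prime_utr")[[tab]]
      sub <- gm[[tab]][gm[[tab]]$gene_id == id, , drop = FALSE]
      if (nrow(sub))
        lines <- c(lines, fmt(sub$chrom, type, sub$start, sub$end,
                              g$strand[i], attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
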