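#' Construct a step-wise coverage track
#'
#' A signal track is a sorted set of non-overlapping steps
#' `(chrom, start, end, value)` with per-base signal density; uncovered
#' positions have value 0.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`, `value`.
#' @return a `signal_track` (data.frame subclass), sorted by `(chrom, start)`.
#' @export
signal_track <- function(x) {
  x <- as.data.frame(x)
  if (!nrow(x)) {
    x <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    value = numeric())
    class(x) <- c("signal_track", "data.frame")
    return(x)
  }
  validate_intervals(x, "signal_track")
  if (!"value" %in% names(x)) stop("signal_track needs a value column")
  if (any(x$value < 0)) stop("signal_track values must be >= 0")
  x <- x[order(x$chrom, x$start), c("chrom", "start", "end", "value")]
  by_ch <- split(seq_len(nrow(x)), as.character(x$chrom))
  for (i in by_ch) {
    if (length(i) > 1 && any(x$start[i][-1] < x$end[i][-length(i)]))
      stop("signal_track steps overlap on ", x$chrom[i[1]])
  }
  rownames(x) <- NULL
  class(x) <- c("signal_track", "data.frame")
  x
}

#' Read a 4-column bedGraph file as a signal track
#' @param path bedGraph path (0-based, half-open).
#' @return a `signal_track`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- as.data.frame(gr)
  signal_track(data.frame(chrom = as.character(df$seqnames),
                          start = df$start - 1, end = df$end,
                          value = df$score))
}

#' Write a signal track as bedGraph
#' @param track a `signal_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                   as.integer(track$end), format(track$value, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' RPKM-normalize a raw coverage track
#'
#' Rescales per-base read-count density to reads per kilobase per million
#' mapped fragments: `value * 1e9 / library_size`. The step structure is
#' unchanged.
#'
#' @param track a `signal_track` of per-base read-count density.
#' @param library_size total mapped fragments (> 0).
#' @return a `signal_track` in RPKM units.
#' @export
rpkm_normalize <- function(track, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1 ||
      library_size <= 0)
    stop("library_size must be a positive number")
  track$value <- track$value * 1e9 / library_size
  track
}

# cumulative integral lookup for one chromosome of a track:
# returns function I(x) = integral of the step function over [0, x)
.track_integral <- function(track, chrom) {
  i <- which(as.character(track$chrom) == chrom)
  s <- track$start[i]; e <- track$end[i]; v <- track$value[i]
  cumbefore <- c(0, cumsum(v * (e - s)))
  function(x) {
    k <- findInterval(x, s)
    ifelse(k == 0, 0,
           cumbefore[pmax(k, 1)] +
             v[pmax(k, 1)] * pmax(0, pmin(x, e[pmax(k, 1)]) - s[pmax(k, 1)]))
  }
}

#' Quantify track signal over an interval
#'
#' `sum` is the integral of the step function over the interval
#' (value x overlap length); `mean` divides by the interval length.
#' Uncovered bases contribute 0.
#'
#' @param track a `signal_track`.
#' @param chrom chromosome name.
#' @param start,end interval bounds (0-based half-open; fractional bounds
#'   allowed for scaled-bin computations).
#' @param mode `"sum"` or `"mean"`.
#' @return numeric scalar (vectorized over `start`/`end`).
#' @export
interval_signal <- function(track, chrom, start, end, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  stopifnot(all(end > start))
  if (!chrom %in% track$chrom) {
    warning("chromosome ", chrom, " absent from track; returning 0")
    return(rep(0, length(start)))
  }
  I <- .track_integral(track, chrom)
  s <- I(end) - I(start)
  if (mode == "mean") s / (end - start) else s
}

#' Scaled metagene profile over a gene set
#'
#' Each gene's TSS-to-TES span is split into `body_bins` equal-fraction bins;
#' flanks of `flank_bp` are binned at fixed `flank_bin_bp` resolution. Bins
#' are ordered 5' to 3' in transcript orientation (minus-strand genes are
#' traversed right to left), the per-bin mean signal is averaged over genes.
#'
#' @param track a `signal_track`.
#' @param gm a `gene_models` object (all genes used).
#' @param body_bins number of scaled gene-body bins.
#' @param flank_bp flank length in bp on each side.
#' @param flank_bin_bp fixed flank bin width (must divide `flank_bp`).
#' @param gene_set_label label stored with the profile.
#' @return a `metagene_profile`: list with `values` (per-bin mean over
#'   genes), `cumulative` (running sum of `values`), bin layout and
#'   `n_genes`.
#' @export
metagene_profile <- function(track, gm, body_bins = 100, flank_bp = 2000,
                             flank_bin_bp = 50, gene_set_label = "genes") {
  stopifnot(body_bins >= 1, flank_bp >= 0, flank_bin_bp > 0)
  g <- gm$genes
  if (!nrow(g)) stop("empty gene set")
  fbins <- if (flank_bp > 0) as.integer(round(flank_bp / flank_bin_bp)) else 0L
  total <- fbins + body_bins + fbins
  acc <- matrix(0, nrow(g), total)
  for (i in seq_len(nrow(g))) {
    tss <- g$tss[i]; tes <- g$tes[i]
    dirn <- if (g$strand[i] == "+") 1 else -1
    L <- abs(tes - tss)
    # bin boundaries in transcript order, as genomic coordinates
    up <- if (fbins) tss - dirn * seq(flank_bp, 0, by = -flank_bin_bp) else tss
    body <- tss + dirn * seq(0, L, length.out = body_bins + 1)
    down <- if (fbins) tes + dirn * seq(0, flank_bp, by = flank_bin_bp) else tes
    bounds <- c(up, body[-1], if (fbins) down[-1])
    lo <- pmin(bounds[-length(bounds)], bounds[-1])
    hi <- pmax(bounds[-length(bounds)], bounds[-1])
    lo <- pmax(lo, 0); hi <- pmax(hi, lo + 1e-9)
    acc[i, ] <- interval_signal(track, g$chrom[i], lo, hi, mode = "mean")
  }
  values <- colMeans(acc)
  structure(list(values = values, cumulative = cumsum(values),
                 flank_bins_up = fbins, body_bins = body_bins,
                 flank_bins_down = fbins, flank_bp = flank_bp,
                 flank_bin_bp = flank_bin_bp, n_genes = nrow(g),
                 gene_set_label = gene_set_label),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile over", x$n_genes, "gene(s) [", x$gene_set_label,
      "]:", x$flank_bins_up, "+", x$body_bins, "+", x$flank_bins_down,
      "bins; mean signal range",
      sprintf("%.4g..%.4g", min(x$values), max(x$values)), "\n")
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, cumulative = FALSE, ...) {
  y <- if (cumulative) x$cumulative else x$values
  n <- length(y)
  graphics::plot(seq_len(n), y, type = "l", xlab = "bin (5' to 3')",
                 ylab = if (cumulative) "cumulative mean signal"
                        else "mean signal",
                 main = x$gene_set_label, ...)
  graphics::abline(v = c(x$flank_bins_up + 0.5,
                         x$flank_bins_up + x$body_bins + 0.5), lty = 3)
  invisible(x)
}

#' Write a metagene profile as TSV
#' @param profile a `metagene_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metagene_tsv <- function(profile, path) {
  df <- data.frame(bin = seq_along(profile$values), mean = profile$values,
                   cumulative = profile$cumulative)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count fragments whose midpoints fall in disjoint peaks
#'
#' A fragment is counted for the unique peak containing its midpoint
#' (half-open convention: a midpoint exactly at `start` is inside, at `end`
#' is outside). Peaks must be disjoint (merge first).
#'
#' @param fragments a named list (one element per sample) of interval
#'   data frames `chrom`, `start`, `end`.
#' @param peaks data.frame of disjoint peak intervals.
#' @return integer matrix, peaks x samples.
#' @export
count_fragments_in_peaks <- function(fragments, peaks) {
  peaks <- as.data.frame(validate_intervals(peaks, "peaks"))
  ord_chk <- order(peaks$chrom, peaks$start)
  same <- peaks$chrom[ord_chk][-1] == peaks$chrom[ord_chk][-nrow(peaks)]
  if (nrow(peaks) > 1 &&
      any(same & peaks$start[ord_chk][-1] < peaks$end[ord_chk][-nrow(peaks)]))
    stop("peaks overlap; merge them first (see merge_intervals)")
  if (is.data.frame(fragments)) fragments <- list(sample1 = fragments)
  counts <- matrix(0L, nrow(peaks), length(fragments),
                   dimnames = list(NULL, names(fragments)))
  ord <- order(peaks$chrom, peaks$start)
  for (s in seq_along(fragments)) {
    fr <- as.data.frame(validate_intervals(fragments[[s]], "fragments"))
    if (!nrow(fr)) next
    mid <- .midpoint(fr$start, fr$end)
    for (ch in unique(as.character(fr$chrom))) {
      pi <- ord[peaks$chrom[ord] == ch]
      if (!length(pi)) next
      m <- mid[fr$chrom == ch]
      k <- findInterval(m, peaks$start[pi])
      inside <- k > 0 & m < peaks$end[pi][pmax(k, 1)]
      hits <- table(pi[k[inside]])
      counts[as.integer(names(hits)), s] <-
        counts[as.integer(names(hits)), s] + as.integer(hits)
    }
  }
  counts
}
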