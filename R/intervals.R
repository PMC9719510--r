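#' chromexpr: region-stratified integration of chromatin signal and expression
#'
#' All genomic coordinates handled by this package are 0-based, half-open
#' (`[start, end)`), the native convention of BED/bedGraph. GTF input
#' (1-based, closed) is converted on read. Intervals are plain data frames
#' with columns `chrom`, `start`, `end` and optionally `strand`.
#'
#' @importFrom stats cor pt p.adjust rnbinom rpois runif rnorm sd median
#'   setNames phyper rlnorm fisher.test cor.test aggregate complete.cases
#' @importFrom utils read.table write.table head adist packageVersion
#' @keywords internal
"_PACKAGE"

#' Validate a genomic interval data frame
#'
#' Checks the interval invariants: non-empty `chrom`, `0 <= start < end`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly, with `start`/`end` coerced to numeric.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " must be a data.frame with columns chrom, start, end")
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (nrow(x)) {
    if (any(is.na(x$start) | is.na(x$end)))
      stop(what, ": NA coordinates")
    if (any(!nzchar(as.character(x$chrom))))
      stop(what, ": empty chromosome name")
    if (any(x$start < 0))
      stop(what, ": start must be >= 0")
    if (any(x$end <= x$start))
      stop(what, ": end must be > start")
  }
  invisible(x)
}

# data.frame [start, end) -> IRanges (1-based closed), one chromosome
.iranges <- function(start, end) IRanges::IRanges(start = start + 1, end = end)

# IRanges -> 0-based half-open start/end columns
.from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

#' Merge genomic intervals into a disjoint sorted union
#'
#' Computes the positional union of the input intervals. Overlapping and
#' bookended intervals (`end == next start`) are merged, mirroring the
#' default behaviour of `bedtools merge`. Strand is ignored.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based, half-open).
#' @return data.frame of disjoint intervals sorted by `(chrom, start)`.
#' @examples
#' merge_intervals(data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 15)))
#' @export
merge_intervals <- function(intervals) {
  intervals <- as.data.frame(validate_intervals(intervals))
  if (!nrow(intervals))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  parts <- split(intervals, as.character(intervals$chrom))
  out <- lapply(names(parts), function(ch) {
    red <- IRanges::reduce(.iranges(parts[[ch]]$start, parts[[ch]]$end))
    cbind(chrom = ch, .from_iranges(red))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# total length covered by an interval set (after merging)
.covered_length <- function(intervals) {
  m <- merge_intervals(intervals)
  sum(m$end - m$start)
}

# midpoint position of [start, end), 0-based
.midpoint <- function(start, end) floor((start + end) / 2)

# For each query point (0-based position) on `chrom`, the indices of
# subject intervals containing it. Returns a Hits-like data.frame.
.point_overlaps <- function(pos, chrom, subject) {
  if (!nrow(subject)) {
    return(data.frame(query = integer(), subject = integer()))
  }
  res <- vector("list", 0)
  for (ch in unique(as.character(chrom))) {
    qi <- which(chrom == ch)
    si <- which(as.character(subject$chrom) == ch)
    if (!length(si)) next
    hits <- IRanges::findOverlaps(
      .iranges(pos[qi], pos[qi] + 1),
      .iranges(subject$start[si], subject$end[si])
    )
    res[[ch]] <- data.frame(
      query = qi[S4Vectors::queryHits(hits)],
      subject = si[S4Vectors::subjectHits(hits)]
    )
  }
  if (!length(res)) return(data.frame(query = integer(), subject = integer()))
  do.call(rbind, unname(res))
}
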