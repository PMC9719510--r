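make_track <- function(...) signal_track(data.frame(...))

test_that("rpkm_normalize applies the closed-form unit scale", {
  # 10 fragments spread over 1 kb = density 0.01 / bp; library 1e6 -> 10 RPKM
  tr <- make_track(chrom = "c1", start = 0, end = 1000, value = 10 / 1000)
  norm <- rpkm_normalize(tr, 1e6)
  expect_equal(interval_signal(norm, "c1", 0, 1000, mode = "mean"), 10)
  # density 1 per base at library 1e9 stays 1
  tr2 <- make_track(chrom = "c1", start = 0, end = 50, value = 1)
  expect_equal(rpkm_normalize(tr2, 1e9)$value, 1)
  # zero track stays zero; bad library size errors
  tr0 <- make_track(chrom = "c1", start = 0, end = 10, value = 0)
  expect_equal(rpkm_normalize(tr0, 5e6)$value, 0)
  expect_error(rpkm_normalize(tr, 0), "positive")
})

test_that("interval_signal integrates steps with the half-open convention", {
  tr <- make_track(chrom = "c1", start = c(0, 10), end = c(10, 20),
                   value = c(1, 3))
  expect_equal(interval_signal(tr, "c1", 0, 20, mode = "sum"), 40)
  expect_equal(interval_signal(tr, "c1", 0, 20, mode = "mean"), 2)
  expect_equal(interval_signal(tr, "c1", 5, 15, mode = "sum"), 5 + 15)
  expect_equal(interval_signal(tr, "c1", 100, 200, mode = "sum"), 0)
  expect_warning(out <- interval_signal(tr, "c9", 0, 10), "absent")
  expect_equal(out, 0)
})

test_that("interval_signal(sum) is additive over partitions of an interval", {
  set.seed(301)
  for (rep in 1:50) {
    iv <- random_intervals()
    iv$chrom <- "c1"
    iv <- merge_intervals(iv)
    iv$value <- runif(nrow(iv), 0, 5)
    tr <- signal_track(iv)
    cuts <- sort(sample(0:1000, 5))
    lo <- c(0, cuts); hi <- c(cuts, 1001)
    total <- interval_signal(tr, "c1", 0, 1001, mode = "sum")
    parts <- sum(interval_signal(tr, "c1", lo, hi, mode = "sum"))
    expect_equal(parts, total, tolerance = 1e-12)
  }
})

test_that("bedGraph round-trips through write/read", {
  tr <- make_track(chrom = c("c1", "c1", "c2"), start = c(0, 50, 10),
                   end = c(20, 80, 30), value = c(1.5, 2, 0.25))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  expect_equal(as.data.frame(read_bedgraph(path)), as.data.frame(tr))
})

test_that("metagene profile is flat on constant coverage and finds TES skew", {
  cfg <- synthetic_config(seed = 8, n_genes = 15)
  gm <- generate_genome(cfg)
  flat <- make_track(chrom = "chrS", start = 0,
                     end = attr(gm, "chrom_length"), value = 4)
  mp <- metagene_profile(flat, gm)
  expect_equal(length(mp$values),
               mp$flank_bins_up + mp$body_bins + mp$flank_bins_down)
  expect_equal(unname(mp$values), rep(4, length(mp$values)))
  expect_equal(mp$cumulative, cumsum(mp$values))
  ramp <- generate_signal_track(gm, cfg)
  mpr <- metagene_profile(ramp, gm)
  body <- mpr$values[(mpr$flank_bins_up + 1):(mpr$flank_bins_up + mpr$body_bins)]
  expect_gt(body[length(body)], body[1])
})

test_that("minus-strand signal lands in transcript orientation", {
  g <- data.frame(gene_id = "gm", chrom = "c1", strand = "-", start = 1000,
                  end = 3000, biotype = "protein_coding", tss = 3000,
                  tes = 1000)
  ex <- data.frame(gene_id = "gm", chrom = "c1", start = 1000, end = 3000)
  gm <- chromexpr:::.gene_models(g, ex, ex[0, ], ex[0, ])
  # signal only near the TSS-proximal (right) end of this minus-strand gene
  tr <- make_track(chrom = "c1", start = 2800, end = 3000, value = 10)
  mp <- metagene_profile(tr, gm, body_bins = 10, flank_bp = 0)
  expect_gt(mp$values[1], 0)
  expect_equal(unname(mp$values[6:10]), rep(0, 5))
})

test_that("metagene profile of two genes is the mean of single-gene profiles", {
  cfg <- synthetic_config(seed = 9, n_genes = 2)
  gm <- generate_genome(cfg)
  tr <- generate_signal_track(gm, cfg)
  take <- function(i) {
    sub <- gm
    sub$genes <- gm$genes[i, , drop = FALSE]
    metagene_profile(tr, sub)$values
  }
  both <- metagene_profile(tr, gm)$values
  expect_equal(both, (take(1) + take(2)) / 2, tolerance = 1e-12)
})

test_that("metagene profile is invariant under genome reflection with strand flip", {
  cfg <- synthetic_config(seed = 10, n_genes = 10)
  gm <- generate_genome(cfg)
  tr <- generate_signal_track(gm, cfg)
  L <- attr(gm, "chrom_length")
  flip <- function(df) {
    out <- df
    out$start <- L - df$end
    out$end <- L - df$start
    out
  }
  gm2 <- gm
  gm2$genes <- flip(gm$genes[, c("gene_id", "chrom", "start", "end",
                                 "biotype")])
  gm2$genes$strand <- ifelse(gm$genes$strand == "+", "-", "+")
  gm2$genes$tss <- ifelse(gm2$genes$strand == "+", gm2$genes$start,
                          gm2$genes$end)
  gm2$genes$tes <- ifelse(gm2$genes$strand == "+", gm2$genes$end,
                          gm2$genes$start)
  gm2$exons <- flip(gm$exons); gm2$utr5 <- flip(gm$utr5)
  gm2$utr3 <- flip(gm$utr3)
  tr2 <- signal_track(flip(as.data.frame(tr)))
  expect_equal(metagene_profile(tr2, gm2)$values,
               metagene_profile(tr, gm)$values, tolerance = 1e-10)
})

test_that("fragment counting is midpoint-based, half-open, and conservative", {
  peaks <- data.frame(chrom = "c1", start = c(10, 40), end = c(20, 60))
  frs <- list(
    s1 = data.frame(chrom = "c1", start = c(8, 12, 14, 95),
                    end = c(16, 20, 22, 99)),   # midpoints 12, 16, 18, 97
    s2 = data.frame(chrom = character(), start = numeric(), end = numeric()))
  counts <- count_fragments_in_peaks(frs, peaks)
  expect_equal(counts[, "s1"], c(3, 0))
  expect_equal(counts[, "s2"], c(0, 0))
  # midpoint exactly at start counts, at end does not
  p <- data.frame(chrom = "c1", start = 10, end = 20)
  at_start <- data.frame(chrom = "c1", start = 5, end = 15)   # midpoint 10
  at_end <- data.frame(chrom = "c1", start = 15, end = 25)    # midpoint 20
  expect_equal(as.vector(count_fragments_in_peaks(list(a = at_start), p)), 1)
  expect_equal(as.vector(count_fragments_in_peaks(list(a = at_end), p)), 0)
  expect_error(
    count_fragments_in_peaks(frs, data.frame(chrom = "c1", start = c(0, 5),
                                             end = c(10, 15))),
    "merge")
})

test_that("fragments assigned never exceed fragments supplied; equality when peaks tile", {
  set.seed(303)
  for (rep in 1:20) {
    fr <- random_intervals(max_n = 40)
    fr <- fr[fr$chrom == "c1", , drop = FALSE]
    peaks <- merge_intervals(random_intervals())
    peaks <- peaks[peaks$chrom == "c1", , drop = FALSE]
    if (!nrow(peaks) || !nrow(fr)) next
    counts <- count_fragments_in_peaks(list(s = fr), peaks)
    expect_lte(sum(counts), nrow(fr))
    tiling <- data.frame(chrom = "c1", start = c(0, 500), end = c(500, 1100))
    expect_equal(sum(count_fragments_in_peaks(list(s = fr), tiling)),
                 nrow(fr))
  }
})
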