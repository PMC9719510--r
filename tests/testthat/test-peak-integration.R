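test_that("consensus peaks merge across conditions with provenance", {
  sets <- list(ctrl = data.frame(chrom = "c1", start = 100, end = 200),
               ko = data.frame(chrom = "c1", start = c(150, 400),
                               end = c(250, 450)))
  cons <- build_consensus_peaks(sets)
  expect_equal(cons$start, c(100, 400))
  expect_equal(cons$end, c(250, 450))
  expect_equal(cons$sources, c("ctrl,ko", "ko"))
  # idempotence and condition-order invariance
  again <- build_consensus_peaks(list(ctrl = cons[, 1:3], ko = cons[, 1:3]))
  expect_equal(again[, 1:3], cons[, 1:3])
  rev_order <- build_consensus_peaks(rev(sets))
  expect_equal(rev_order[, 1:3], cons[, 1:3])
})

test_that("size factors follow median-of-ratios with the documented fallback", {
  m <- matrix(c(5, 9, 13, 5, 9, 13), ncol = 2)
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2)
  expect_equal(unname(size_factors(m2)), c(2^-0.5, 2^0.5))
  # every row contains a zero -> library-size fallback
  m3 <- matrix(c(0, 4, 4, 0), ncol = 2)
  expect_message(f <- size_factors(m3), "library-size")
  expect_equal(unname(f), c(1, 1))
  expect_error(size_factors(matrix(0, 2, 2)), "all-zero")
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  # odd row count and no zeros: the median-of-ratios statistic is then the
  # same single middle element on both the ratio and the log-ratio scale
  m <- matrix(rnbinom(404, mu = outer(rlnorm(101, 5, 1), c(1, 1.6, 0.7, 1.2)),
                      size = 10) + 1, ncol = 4)
  colnames(m) <- paste0("s", 1:4)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("peak_log2fc computes pseudocounted ratios of normalized means", {
  counts <- rbind(c(10, 10, 10, 10), c(4, 4, 9, 9))
  colnames(counts) <- c("a1", "a2", "b1", "b2")
  pd <- peak_log2fc(counts, factors = rep(1, 4),
                    condition = c("a", "a", "b", "b"), pseudocount = 1)
  expect_equal(pd$log2fc[1], 0)
  expect_equal(pd$log2fc[2], 1)  # log2((9+1)/(4+1))
  expect_equal(attr(pd, "conditions"), c("a", "b"))
  expect_error(peak_log2fc(counts, factors = rep(1, 4),
                           condition = rep("a", 4)), "two conditions")
})

test_that("degenerate variance and single-replicate paths are guarded", {
  counts <- rbind(c(8, 8, 16, 16), c(8, 8, 8, 8))
  colnames(counts) <- c("a1", "a2", "b1", "b2")
  pd <- peak_log2fc(counts, factors = rep(1, 4),
                    condition = c("a", "a", "b", "b"))
  expect_gt(pd$pvalue[1], 0)       # exact-equal variance guard, p in (0,1]
  expect_lt(pd$pvalue[1], 1e-100)
  expect_equal(pd$pvalue[2], 1)
  one_rep <- rbind(c(8, 40), c(8, 8))
  colnames(one_rep) <- c("a1", "b1")
  single <- peak_log2fc(one_rep, factors = c(1, 1), condition = c("a", "b"))
  expect_true(all(is.na(single$pvalue)))
  expect_true(attr(single, "proxy_significance"))
  expect_equal(single$significant_up, c(TRUE, FALSE))
})

test_that("scaling one sample rescales its relative factor and leaves log2fc unchanged", {
  set.seed(404)
  counts <- matrix(rnbinom(200 * 4, mu = 100, size = 20) + 1, ncol = 4)
  colnames(counts) <- c("a1", "a2", "b1", "b2")
  cond <- c("a", "a", "b", "b")
  base_f <- size_factors(counts)
  base <- peak_log2fc(counts, condition = cond, pseudocount = 0)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 4
  sf <- size_factors(scaled)
  # size factors are defined up to a common scale: the scaled sample's
  # factor grows by k relative to every other sample
  expect_equal((sf[2] / sf[1]) / (base_f[2] / base_f[1]), 4,
               tolerance = 1e-12, ignore_attr = TRUE)
  got <- peak_log2fc(scaled, condition = cond, pseudocount = 0)
  expect_equal(got$log2fc, base$log2fc, tolerance = 1e-12)
  # with a pseudocount the invariance is numerical, not exact
  got_pc <- peak_log2fc(scaled, condition = cond)
  base_pc <- peak_log2fc(counts, condition = cond)
  expect_equal(got_pc$log2fc, base_pc$log2fc, tolerance = 0.05)
})

test_that("gene_summed_fc matches the summed-counts reduction", {
  ann <- data.frame(region_class = c("promoter_5utr", "genebody",
                                     "distal_intergenic"),
                    gene_id = c("g1", "g1", NA),
                    nearest_gene = c("g1", "g1", "g1"))
  counts <- rbind(c(2, 4), c(3, 6), c(50, 50))
  colnames(counts) <- c("s1", "s2")
  out <- gene_summed_fc(ann, counts, factors = c(1, 1),
                        condition = c("ctrl", "ko"), pseudocount = 0)
  # summed ctrl = 5, summed ko = 10 over the two locus peaks
  expect_equal(out$summed_log2fc, 1)
  expect_equal(out$n_peaks, 2)
  # single-peak gene reduces to that peak's summed-count log2fc
  ann1 <- data.frame(region_class = "genebody", gene_id = "g2",
                     nearest_gene = "g2")
  one <- gene_summed_fc(ann1, matrix(c(7, 21), 1,
                                     dimnames = list(NULL, c("s1", "s2"))),
                        factors = c(1, 1), condition = c("ctrl", "ko"),
                        pseudocount = 0)
  expect_equal(one$summed_log2fc, log2(3))
  # all-zero counts with pseudocount 1 give 0; peakless genes are absent
  zero <- gene_summed_fc(ann1, matrix(c(0, 0), 1,
                                      dimnames = list(NULL, c("s1", "s2"))),
                         factors = c(1, 1), condition = c("ctrl", "ko"),
                         pseudocount = 1)
  expect_equal(zero$summed_log2fc, 0)
  expect_false("g1" %in% zero$gene_id)
})

test_that("gene_region_avg_log2fc averages per class and matches the oracle", {
  pd <- data.frame(log2fc = c(1, 3, -0.5, 2))
  ann <- data.frame(region_class = c("promoter_5utr", "promoter_5utr",
                                     "genebody", "distal_intergenic"),
                    gene_id = c("g1", "g1", "g1", NA),
                    nearest_gene = c("g1", "g1", "g1", "g2"))
  out <- gene_region_avg_log2fc(pd, ann)
  expect_equal(out$avg_log2fc[out$gene_id == "g1" &
                                out$region_class == "promoter_5utr"], 2)
  expect_equal(out$avg_log2fc[out$gene_id == "g1" &
                                out$region_class == "genebody"], -0.5)
  # the intergenic peak contributes to its nearest gene only
  expect_equal(out$region_class[out$gene_id == "g2"], "distal_intergenic")
  set.seed(505)
  for (rep in 1:1000) {
    n <- sample(3:12, 1)
    lfc <- round(rnorm(n), 3)
    cls <- sample(REGION_CLASSES, n, replace = TRUE)
    gid <- sample(c("gA", "gB", "gC", NA), n, replace = TRUE)
    near <- sample(c("gA", "gB", "gC"), n, replace = TRUE)
    gid[cls != "distal_intergenic" & is.na(gid)] <- "gA"
    ann_r <- data.frame(region_class = cls,
                        gene_id = ifelse(cls == "distal_intergenic", NA, gid),
                        nearest_gene = near)
    key <- ifelse(cls == "distal_intergenic", near,
                  ann_r$gene_id)
    got <- gene_region_avg_log2fc(data.frame(log2fc = lfc), ann_r)
    want <- oracle_region_avg(lfc, key, cls)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("peak BED and count TSV readers handle BED3 and narrowPeak", {
  bed <- withr::local_tempfile(lines = c("c1\t100\t200", "c1\t300\t350"),
                               fileext = ".bed")
  expect_equal(read_peaks(bed)$start, c(100, 300))
  np <- withr::local_tempfile(
    lines = "c1\t10\t80\tpk1\t100\t.\t5.5\t3.2\t2.8\t35",
    fileext = ".narrowPeak")
  got <- read_peaks(np)
  expect_equal(c(got$start, got$end), c(10, 80))
  cnts <- withr::local_tempfile(
    lines = c("chrom\tstart\tend\tctrl_1\tko_1", "c1\t5\t50\t12\t30"),
    fileext = ".tsv")
  parsed <- read_peak_counts(cnts)
  expect_equal(parsed$counts[1, ], c(ctrl_1 = 12, ko_1 = 30))
})
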