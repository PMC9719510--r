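test_that("GTF coordinates convert to 0-based half-open and strand sets the TSS", {
  gtf <- c(
    'chr1\tsrc\tgene\t1001\t1100\t.\t+\t.\tgene_id "gA"; gene_biotype "protein_coding";',
    'chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t";',
    'chr1\tsrc\tgene\t5001\t8000\t.\t-\t.\tgene_id "gB"; gene_biotype "lincRNA";',
    'chr1\tsrc\texon\t5001\t8000\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t";'
  )
  path <- withr::local_tempfile(lines = gtf, fileext = ".gtf")
  gm <- read_gene_annotation(path)
  g <- gm$genes
  expect_equal(g$start[g$gene_id == "gA"], 1000)
  expect_equal(g$end[g$gene_id == "gA"], 1100)
  # minus-strand gene spanning [5000, 8000): tss at the right end
  expect_equal(g$tss[g$gene_id == "gB"], 8000)
  expect_equal(g$tes[g$gene_id == "gB"], 5000)
  expect_equal(g$biotype, c("protein_coding", "lincRNA"))
})

test_that("malformed GTF lines are reported by number; bad records rejected", {
  bad <- withr::local_tempfile(
    lines = c('chr1\tsrc\tgene\t1\t100\t.\t+\t.\tgene_id "g";',
              "chr1 only-three fields"),
    fileext = ".gtf")
  expect_error(read_gene_annotation(bad), "line 2")
  rev_coords <- withr::local_tempfile(
    lines = c('chr1\tsrc\tgene\t1\t100\t.\t+\t.\tgene_id "g"; gene_biotype "x";',
              'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g"; transcript_id "g.t";',
              'chr1\tsrc\texon\t90\t50\t.\t+\t.\tgene_id "g"; transcript_id "g.t";'),
    fileext = ".gtf")
  expect_warning(gm <- read_gene_annotation(rev_coords), "rejected")
  expect_equal(nrow(gm$exons), 1)
})

test_that("annotation round-trips through write_gtf", {
  gm <- generate_genome(synthetic_config(seed = 4, n_genes = 12))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gm, path)
  gm2 <- read_gene_annotation(path)
  expect_equal(gm2$genes[, c("gene_id", "chrom", "strand", "start", "end",
                             "tss", "tes", "biotype")],
               gm$genes[, c("gene_id", "chrom", "strand", "start", "end",
                            "tss", "tes", "biotype")])
  expect_equal(gm2$exons, gm$exons, ignore_attr = TRUE)
})

test_that("merge_intervals unions, merges bookended neighbours, keeps chroms apart", {
  out <- merge_intervals(data.frame(chrom = "chr1", start = c(0, 5),
                                    end = c(10, 15)))
  expect_equal(out$start, 0)
  expect_equal(out$end, 15)
  out <- merge_intervals(data.frame(chrom = "chr1", start = c(0, 10),
                                    end = c(10, 20)))
  expect_equal(nrow(out), 1)
  expect_equal(out$end, 20)
  out <- merge_intervals(data.frame(chrom = c("c2", "c1"), start = c(0, 0),
                                    end = c(5, 5)))
  expect_equal(out$chrom, c("c1", "c2"))
  expect_equal(nrow(merge_intervals(data.frame(chrom = character(),
                                               start = numeric(),
                                               end = numeric()))), 0)
})

test_that("merge_intervals equals a per-base brute-force union and preserves covered length", {
  set.seed(101)
  for (i in 1:300) {
    iv <- random_intervals()
    got <- merge_intervals(iv)
    expect_equal(got, oracle_merge(iv), ignore_attr = TRUE)
    expect_equal(sum(got$end - got$start), chromexpr:::.covered_length(iv))
  }
})

test_that("partition covers the promoter window and gene body as documented", {
  g <- data.frame(gene_id = "g1", chrom = "c1", strand = "+", start = 10000,
                  end = 20000, biotype = "protein_coding", tss = 10000,
                  tes = 20000)
  ex <- data.frame(gene_id = "g1", chrom = "c1", start = 10000, end = 20000)
  empty <- ex[0, ]
  gm <- chromexpr:::.gene_models(g, ex, empty, empty)
  part <- partition_regions(gm, c(3000, 3000))
  prom <- part$intervals[part$intervals$region_class == "promoter_5utr", ]
  body <- part$intervals[part$intervals$region_class == "genebody", ]
  expect_equal(c(prom$start, prom$end), c(7000, 13000))
  expect_equal(c(body$start, body$end), c(13000, 20000))
  # promoter and genebody never overlap within a gene
  expect_equal(chromexpr:::.covered_length(part$intervals),
               sum(part$intervals$end - part$intervals$start))
})

test_that("assign_region follows precedence, distance and lexicographic tie-breaks", {
  set.seed(202)
  checked <- 0
  for (rep in 1:25) {
    gm <- make_toy_genome(n_genes = 8)
    window <- c(50, 50)
    part <- partition_regions(gm, window)
    peaks <- random_intervals(n = 50)
    ann <- assign_region(peaks, part)
    for (j in seq_len(nrow(peaks))) {
      want <- oracle_assign(ann$midpoint[j], as.character(peaks$chrom[j]),
                            gm, window)
      expect_identical(ann$region_class[j], want$class)
      expect_identical(ann$gene_id[j], want$gene)
      if (want$class == "distal_intergenic")
        expect_identical(ann$nearest_gene[j], want$nearest)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 1000)
})

test_that("peaks on unknown chromosomes fall back to distal_intergenic with a warning", {
  gm <- make_toy_genome(n_genes = 4, chrom = "c1")
  part <- partition_regions(gm, c(50, 50))
  expect_warning(
    ann <- assign_region(data.frame(chrom = "cX", start = 10, end = 30), part),
    "absent")
  expect_equal(ann$region_class, "distal_intergenic")
  expect_true(is.na(ann$gene_id))
})

test_that("promoter precedence beats another gene's body", {
  g <- data.frame(gene_id = c("gA", "gB"), chrom = "c1", strand = "+",
                  start = c(0, 5000), end = c(20000, 9000),
                  biotype = "protein_coding", tss = c(0, 5000),
                  tes = c(20000, 9000))
  ex <- data.frame(gene_id = g$gene_id, chrom = "c1", start = g$start,
                   end = g$end)
  gm <- chromexpr:::.gene_models(g, ex, ex[0, ], ex[0, ])
  part <- partition_regions(gm, c(1000, 1000))
  # midpoint 5500 is inside gA's genebody and gB's promoter window
  ann <- assign_region(data.frame(chrom = "c1", start = 5400, end = 5600),
                       part)
  expect_equal(ann$region_class, "promoter_5utr")
  expect_equal(ann$gene_id, "gB")
})
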