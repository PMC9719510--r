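# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic study generator
#'
#' Defines a toy genome, replicated peak-count data for two conditions
#' (`ctrl`, `ko`), coverage tracks, and a gene-level DE table in which the
#' mRNA log2 fold change carries a planted correlation with the per-gene
#' regulatory effect of each region class. All numeric choices are the study
#' conditions the generator emulates; see the package vignette.
#'
#' @param seed integer master seed; all four generation stages derive their
#'   own streams from it (identical config => byte-identical outputs).
#' @param n_genes number of genes (>= 1).
#' @param chrom chromosome name of the toy genome.
#' @param chrom_length optional; computed from gene placement when `NULL`,
#'   an error if given but too small.
#' @param gene_length min/max gene span (bp).
#' @param intergenic_gap min/max gap between consecutive genes (bp).
#' @param promoter_window promoter window passed to [partition_regions()].
#' @param peak_rate named Poisson means of peaks per gene for classes
#'   `promoter_5utr`, `genebody`, `distal_intergenic`.
#' @param peak_width min/max peak width (bp).
#' @param baseline_mean mean negative-binomial peak count (per replicate).
#' @param dispersion negative-binomial size parameter (replicate
#'   overdispersion; larger = less overdispersed).
#' @param n_replicates replicates per condition for peak counts.
#' @param planted_rho named target correlations between each class's
#'   per-gene regulatory effect and the mRNA log2FC; `sum(rho^2)` must be
#'   <= 1.
#' @param effect_sd SD of the per-gene, per-class regulatory effect (log2).
#' @param mrna_lfc_sd SD of the mRNA log2 fold change.
#' @param noise_sd per-sample FPKM noise SD (log2).
#' @param fraction_significant fraction of genes (largest `|log2FC|` first)
#'   given p-values below 0.05.
#' @param decoy_fraction fraction of genes given a non-protein-coding
#'   biotype.
#' @param rna_replicates FPKM columns per condition in the DE table.
#' @param track_base baseline coverage density of the signal track.
#' @param track_shape `"tes_ramp"` (signal rising toward the TES),
#'   `"flat"`, or `"zero"`.
#' @param call_threshold mean raw count above which a peak is listed in a
#'   condition's peak-call BED.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, n_genes = 200, chrom = "chrS",
                             chrom_length = NULL,
                             gene_length = c(8000, 16000),
                             intergenic_gap = c(8000, 16000),
                             promoter_window = c(3000, 3000),
                             peak_rate = c(promoter_5utr = 2, genebody = 1.5,
                                           distal_intergenic = 1),
                             peak_width = c(200, 800),
                             baseline_mean = 300, dispersion = 30,
                             n_replicates = 2,
                             planted_rho = c(promoter_5utr = 0.8,
                                             genebody = 0,
                                             distal_intergenic = 0),
                             effect_sd = 1.2, mrna_lfc_sd = 1.5,
                             noise_sd = 0.15, fraction_significant = 0.4,
                             decoy_fraction = 0.1, rna_replicates = 3,
                             track_base = 5,
                             track_shape = c("tes_ramp", "flat", "zero"),
                             call_threshold = 30) {
  track_shape <- match.arg(track_shape)
  if (n_genes < 1) stop("n_genes must be >= 1")
  planted_rho <- planted_rho[REGION_CLASSES]
  planted_rho[is.na(planted_rho)] <- 0
  names(planted_rho) <- REGION_CLASSES
  if (any(abs(planted_rho) > 1)) stop("planted_rho must lie in [-1, 1]")
  if (sum(planted_rho^2) > 1)
    stop("sum of squared planted_rho must be <= 1")
  stopifnot(effect_sd > 0, mrna_lfc_sd > 0, noise_sd >= 0,
            baseline_mean > 0, dispersion > 0, n_replicates >= 1,
            fraction_significant >= 0, fraction_significant <= 1,
            decoy_fraction >= 0, decoy_fraction < 1)
  peak_rate <- peak_rate[REGION_CLASSES]
  peak_rate[is.na(peak_rate)] <- 0
  names(peak_rate) <- REGION_CLASSES
  cfg <- list(seed = seed, n_genes = n_genes, chrom = chrom,
              chrom_length = chrom_length, gene_length = gene_length,
              intergenic_gap = intergenic_gap,
              promoter_window = promoter_window, peak_rate = peak_rate,
              peak_width = peak_width, baseline_mean = baseline_mean,
              dispersion = dispersion, n_replicates = n_replicates,
              planted_rho = planted_rho, effect_sd = effect_sd,
              mrna_lfc_sd = mrna_lfc_sd, noise_sd = noise_sd,
              fraction_significant = fraction_significant,
              decoy_fraction = decoy_fraction,
              rna_replicates = rna_replicates, track_base = track_base,
              track_shape = track_shape, call_threshold = call_threshold)
  cfg$stage_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1, 4))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate the toy genome
#'
#' Places `n_genes` non-overlapping genes with random strand on one
#' chromosome, each with 2-8 exons and terminal UTRs; a configured fraction
#' get a non-protein-coding decoy biotype. Deterministic under the config
#' seed.
#'
#' @param config a `synthetic_config`.
#' @return a `gene_models` object.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$stage_seeds[1], {
    n <- config$n_genes
    lens <- round(runif(n, config$gene_length[1], config$gene_length[2]))
    gaps <- round(runif(n, config$intergenic_gap[1], config$intergenic_gap[2]))
    starts <- cumsum(gaps) + cumsum(c(0, lens[-n]))
    ends <- starts + lens
    needed <- ends[n] + config$intergenic_gap[2]
    if (!is.null(config$chrom_length) && config$chrom_length < needed)
      stop("chrom_length ", config$chrom_length, " too small; need >= ",
           needed)
    chrom_length <- if (is.null(config$chrom_length)) needed
                    else config$chrom_length
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("G%04d", seq_len(n))
    biotype <- rep("protein_coding", n)
    n_decoy <- round(config$decoy_fraction * n)
    if (n_decoy > 0) {
      decoys <- sample(n, n_decoy)
      biotype[decoys] <- sample(c("lincRNA", "processed_pseudogene", "miRNA"),
                                n_decoy, replace = TRUE)
    }
    ex_gene <- ex_start <- ex_end <- vector("list", n)
    u5_start <- u5_end <- u3_start <- u3_end <- numeric(n)
    ks <- sample(2:8, n, replace = TRUE)
    for (i in seq_len(n)) {
      k <- ks[i]
      w <- runif(2 * k - 1, 0.5, 1.5)
      seg <- round(lens[i] * w / sum(w))
      seg[length(seg)] <- lens[i] - sum(seg[-length(seg)])
      bounds <- starts[i] + cumsum(c(0, seg))
      ex_idx <- seq(1, 2 * k - 1, by = 2)
      ex_gene[[i]] <- rep(ids[i], k)
      ex_start[[i]] <- bounds[ex_idx]
      ex_end[[i]] <- bounds[ex_idx + 1]
      first <- c(bounds[1], bounds[2]); last <- c(bounds[2 * k - 1],
                                                  bounds[2 * k])
      u5len <- min(200, floor((first[2] - first[1]) / 2))
      u3len <- min(300, floor((last[2] - last[1]) / 2))
      if (strand[i] == "+") {
        u5_start[i] <- first[1]; u5_end[i] <- first[1] + u5len
        u3_start[i] <- last[2] - u3len; u3_end[i] <- last[2]
      } else {
        u5_start[i] <- last[2] - u5len; u5_end[i] <- last[2]
        u3_start[i] <- first[1]; u3_end[i] <- first[1] + u3len
      }
    }
    exons <- data.frame(gene_id = unlist(ex_gene), chrom = config$chrom,
                        start = unlist(ex_start), end = unlist(ex_end),
                        stringsAsFactors = FALSE)
    utr5 <- data.frame(gene_id = ids, chrom = config$chrom, start = u5_start,
                       end = u5_end, stringsAsFactors = FALSE)
    utr3 <- data.frame(gene_id = ids, chrom = config$chrom, start = u3_start,
                       end = u3_end, stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = ids, chrom = config$chrom, strand = strand,
                        start = starts, end = ends, biotype = biotype,
                        stringsAsFactors = FALSE)
    genes$tss <- ifelse(strand == "+", starts, ends)
    genes$tes <- ifelse(strand == "+", ends, starts)
    gm <- .gene_models(genes, exons, utr5, utr3)
    attr(gm, "chrom_length") <- chrom_length
    gm
  })
}

# place n disjoint peaks with midpoints inside the class intervals `ivs`;
# intervals are shrunk by `edge` bp so peak tails never leave their class
.place_peaks <- function(ivs, n, wmin, wmax, edge = 450) {
  if (!n || !nrow(ivs)) return(NULL)
  s <- ivs$start + edge; e <- ivs$end - edge
  keep <- e - s > 0
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(NULL)
  lens <- e - s
  total <- sum(lens)
  n_eff <- min(n, floor(total / (wmax + 100)))
  if (n_eff < 1) return(NULL)
  slot <- total / n_eff
  jitter <- runif(n_eff, -0.5, 0.5) * max(0, slot - wmax - 50)
  u <- (seq_len(n_eff) - 0.5) * slot + jitter
  cumbefore <- c(0, cumsum(lens))
  k <- findInterval(u, cumbefore, rightmost.closed = TRUE)
  mid <- s[k] + (u - cumbefore[k])
  w <- runif(n_eff, wmin, wmax)
  data.frame(start = round(mid - w / 2), end = round(mid + w / 2))
}

#' Generate peaks and replicate count matrices with planted effects
#'
#' Draws a Poisson number of peaks per gene per region class, placed so that
#' [assign_region()] recovers the intended class and (for intergenic peaks)
#' the intended nearest gene. Every peak of a gene-class pair shares that
#' pair's regulatory effect `e ~ N(0, effect_sd)`: replicate counts are
#' negative binomial with mean `baseline` for `ctrl` and `baseline * 2^e`
#' for `ko`.
#'
#' @param gm genome from [generate_genome()].
#' @param config a `synthetic_config`.
#' @return list with `peaks` (data.frame incl. `true_gene`, `true_class`,
#'   `true_effect`, `true_multiplier`), `counts` (matrix), `condition`
#'   (named vector), `called` (list of per-condition peak data frames) and
#'   `truth` (per-gene-per-class effect matrix).
#' @export
generate_peaks_and_counts <- function(gm, config) {
  part <- partition_regions(gm, config$promoter_window)
  g <- gm$genes
  chrom_length <- attr(gm, "chrom_length")
  if (is.null(chrom_length)) chrom_length <- max(g$end) + 20000
  # distal territory of each gene: the Voronoi cell of its TSS minus all
  # promoter/genebody intervals, so the nearest-gene rule recovers the gene
  covered <- merge_intervals(part$intervals[, c("chrom", "start", "end")])
  free_ir <- IRanges::setdiff(.iranges(0, chrom_length),
                              .iranges(covered$start, covered$end))
  free <- .from_iranges(free_ir)
  ord <- order(g$tss)
  bounds <- c(0, .midpoint(g$tss[ord][-nrow(g)], g$tss[ord][-1]), chrom_length)
  # split the free (intergenic) intervals over the TSS Voronoi cells
  free_n <- length(free_ir)
  fs <- IRanges::start(free_ir) - 1; fe <- IRanges::end(free_ir)
  cell_of <- lapply(seq_len(nrow(g)), function(oi) NULL)
  if (free_n) {
    hits <- IRanges::findOverlaps(free_ir, .iranges(bounds[-length(bounds)],
                                                    bounds[-1]))
    qi <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
    pieces <- data.frame(cell = ci,
                         start = pmax(fs[qi], bounds[ci]),
                         end = pmin(fe[qi], bounds[ci + 1]))
    pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]
    cell_of <- split(pieces[, c("start", "end")], factor(pieces$cell,
                                                         levels = seq_len(nrow(g))))
  }
  # per-gene promoter/genebody intervals, precomputed once
  iv_key <- paste(part$intervals$gene_id, part$intervals$region_class)
  iv_split <- split(part$intervals[, c("start", "end")], iv_key)
  .with_seed(config$stage_seeds[2], {
    effects <- matrix(rnorm(nrow(g) * 3, 0, config$effect_sd), nrow(g), 3,
                      dimnames = list(g$gene_id, REGION_CLASSES))
    wmin <- config$peak_width[1]; wmax <- config$peak_width[2]
    n_pk <- matrix(rpois(nrow(g) * 3, rep(config$peak_rate[REGION_CLASSES],
                                          each = nrow(g))),
                   nrow(g), 3, dimnames = list(g$gene_id, REGION_CLASSES))
    acc_s <- acc_e <- acc_eff <- numeric(0)
    acc_gene <- acc_cls <- character(0)
    for (oi in seq_len(nrow(g))) {
      i <- ord[oi]
      for (cls in REGION_CLASSES) {
        nn <- n_pk[i, cls]
        if (!nn) next
        ivs <- if (cls == "distal_intergenic") cell_of[[oi]]
               else iv_split[[paste(g$gene_id[i], cls)]]
        if (is.null(ivs)) next
        pk <- .place_peaks(ivs, nn, wmin, wmax)
        if (is.null(pk)) next
        acc_s <- c(acc_s, pk$start); acc_e <- c(acc_e, pk$end)
        acc_gene <- c(acc_gene, rep(g$gene_id[i], nrow(pk)))
        acc_cls <- c(acc_cls, rep(cls, nrow(pk)))
        acc_eff <- c(acc_eff, rep(effects[g$gene_id[i], cls], nrow(pk)))
      }
    }
    peaks <- data.frame(chrom = config$chrom, start = acc_s, end = acc_e,
                        true_gene = acc_gene, true_class = acc_cls,
                        true_effect = acc_eff, stringsAsFactors = FALSE)
    peaks <- peaks[order(peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL
    peaks$true_multiplier <- 2^peaks$true_effect
    np <- nrow(peaks); nr <- config$n_replicates
    samples <- c(paste0("ctrl_", seq_len(nr)), paste0("ko_", seq_len(nr)))
    condition <- setNames(rep(c("ctrl", "ko"), each = nr), samples)
    mu_base <- runif(np, 0.5, 1.5) * config$baseline_mean
    counts <- matrix(0L, np, 2 * nr, dimnames = list(NULL, samples))
    for (j in seq_len(nr)) {
      counts[, j] <- rnbinom(np, mu = mu_base, size = config$dispersion)
      counts[, nr + j] <- rnbinom(np, mu = mu_base * peaks$true_multiplier,
                                  size = config$dispersion)
    }
    called <- lapply(c(ctrl = "ctrl", ko = "ko"), function(cond) {
      m <- rowMeans(counts[, condition == cond, drop = FALSE])
      peaks[m >= config$call_threshold, c("chrom", "start", "end"),
            drop = FALSE]
    })
    list(peaks = peaks, counts = counts, condition = condition,
         called = called, truth = list(effects = effects))
  })
}

#' Generate a gene-level DE table with a planted correlation
#'
#' The mRNA log2 fold change of gene `g` is
#' `lfc_g = mrna_lfc_sd * (sum_c b_c e_gc + eps_g)` with
#' `b_c = rho_c / effect_sd` and `sd(eps) = sqrt(1 - sum(rho^2))`, so that
#' `cor(e_gc, lfc) = rho_c` for every region class by construction. FPKM
#' values are log-normal with per-sample noise; p-values are generated (not
#' fitted): the `fraction_significant` genes with largest `|lfc|` draw from
#' Uniform(1e-8, 0.05), the rest from Uniform(0.05, 1).
#'
#' @param gm genome from [generate_genome()].
#' @param truth the `truth` element of [generate_peaks_and_counts()].
#' @param config a `synthetic_config`.
#' @return list with `de_table` (data.frame), `de_conditions` (named map
#'   sample -> condition) and `bookkeeping` (incl. `n_pass_filter`, the
#'   number of rows satisfying the three significance criteria).
#' @export
generate_expression <- function(gm, truth, config) {
  g <- gm$genes
  n <- nrow(g)
  rho <- config$planted_rho
  .with_seed(config$stage_seeds[3], {
    b <- rho / config$effect_sd
    eps_sd <- sqrt(max(0, 1 - sum(rho^2)))
    z <- as.numeric(truth$effects %*% b) + rnorm(n, 0, eps_sd)
    lfc <- config$mrna_lfc_sd * z
    base <- rlnorm(n, meanlog = 3, sdlog = 1)
    nr <- config$rna_replicates
    samples <- c(paste0("rna_ctrl_", seq_len(nr)),
                 paste0("rna_ko_", seq_len(nr)))
    de_conditions <- setNames(rep(c("ctrl", "ko"), each = nr), samples)
    fpkm <- matrix(0, n, 2 * nr, dimnames = list(NULL, samples))
    for (j in seq_len(nr)) {
      fpkm[, j] <- base * 2^rnorm(n, 0, config$noise_sd)
      fpkm[, nr + j] <- base * 2^lfc * 2^rnorm(n, 0, config$noise_sd)
    }
    p <- runif(n, 0.05, 1)
    m <- round(config$fraction_significant * n)
    if (m > 0) {
      sig <- order(-abs(lfc))[seq_len(m)]
      p[sig] <- runif(m, 1e-8, 0.05 - 1e-9)
    }
    de <- data.frame(gene_id = g$gene_id, biotype = g$biotype,
                     log2fc = lfc, pvalue = p, stringsAsFactors = FALSE)
    for (s in samples) de[[paste0("fpkm_", s)]] <- fpkm[, s]
    m1 <- rowMeans(fpkm[, de_conditions == "ctrl", drop = FALSE])
    m2 <- rowMeans(fpkm[, de_conditions == "ko", drop = FALSE])
    pass <- p < 0.05 & g$biotype == "protein_coding" & (m1 > 5 | m2 > 5)
    list(de_table = de, de_conditions = de_conditions,
         bookkeeping = list(n_pass_filter = sum(pass),
                            pass_filter = g$gene_id[pass],
                            n_decoy = sum(g$biotype != "protein_coding")))
  })
}

#' Generate a coverage track over the toy genome
#'
#' Piecewise-constant density over gene bodies; the default `tes_ramp` shape
#' rises from the TSS toward the TES (the gene-body deposition profile of a
#' co-transcriptional mark), `flat` is constant over genes, `zero` is an
#' empty track.
#'
#' @param gm genome from [generate_genome()].
#' @param config a `synthetic_config`.
#' @param multipliers optional named per-gene scaling (e.g.
#'   `2^effect` for a perturbed condition).
#' @return a `signal_track`.
#' @export
generate_signal_track <- function(gm, config, multipliers = NULL) {
  if (config$track_shape == "zero") return(signal_track(data.frame()))
  g <- gm$genes
  nseg <- 10
  ramp <- if (config$track_shape == "tes_ramp")
    seq(0.5, 2, length.out = nseg) else rep(1, nseg)
  n <- nrow(g)
  frac <- matrix(rep(seq(0, 1, length.out = nseg + 1), each = n), n)
  bounds <- round(g$start + (g$end - g$start) * frac)
  v <- matrix(rep(config$track_base * ramp, each = n), n)
  minus <- g$strand == "-"
  v[minus, ] <- v[minus, rev(seq_len(nseg)), drop = FALSE]  # follow strand
  mult <- rep(1, n)
  if (!is.null(multipliers)) {
    mm <- multipliers[g$gene_id]
    mult <- ifelse(is.na(mm), 1, mm)
  }
  signal_track(data.frame(
    chrom = rep(g$chrom, nseg),
    start = as.vector(bounds[, -(nseg + 1)]),
    end = as.vector(bounds[, -1]),
    value = as.vector(v * mult), stringsAsFactors = FALSE))
}

#' Generate a complete synthetic study
#'
#' Runs all four generators and bundles genome, partition, peaks/counts,
#' per-condition peak calls, DE table, coverage tracks and ground truth.
#'
#' @param config a `synthetic_config` (default settings when omitted).
#' @return a `synthetic_study` list.
#' @export
simulate_study <- function(config = synthetic_config()) {
  gm <- generate_genome(config)
  pk <- generate_peaks_and_counts(gm, config)
  ex <- generate_expression(gm, pk$truth, config)
  eff_body <- setNames(2^pk$truth$effects[, "genebody"],
                       rownames(pk$truth$effects))
  tracks <- list(ctrl = generate_signal_track(gm, config),
                 ko = generate_signal_track(gm, config,
                                            multipliers = eff_body))
  structure(list(config = config, genome = gm,
                 partition = partition_regions(gm, config$promoter_window),
                 peaks = pk$peaks, counts = pk$counts,
                 condition = pk$condition, called = pk$called,
                 de_table = ex$de_table, de_conditions = ex$de_conditions,
                 truth = c(pk$truth, ex$bookkeeping), tracks = tracks),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study: seed", x$config$seed, "-", nrow(x$genome$genes),
      "genes,", nrow(x$peaks), "peaks,", ncol(x$counts), "samples\n")
  cat("  planted rho:",
      paste(names(x$config$planted_rho), x$config$planted_rho, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study to disk in standard formats
#'
#' Emits `annotation.gtf`, `peaks_<condition>.bed`, `counts.tsv`,
#' `de_table.tsv`, `track_<condition>.bedGraph`, `truth_effects.tsv` and
#' `config.yaml` under `dir`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_gtf(study$genome, fp("annotation.gtf"))
  for (cond in names(study$called))
    write_bed(study$called[[cond]], fp(paste0("peaks_", cond, ".bed")))
  counts_tab <- cbind(study$peaks[, c("chrom", "start", "end")],
                      as.data.frame(study$counts))
  write.table(counts_tab, fp("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_de_table(study$de_table, fp("de_table.tsv"))
  for (cond in names(study$tracks))
    write_bedgraph(study$tracks[[cond]],
                   fp(paste0("track_", cond, ".bedGraph")))
  eff <- study$truth$effects
  write.table(data.frame(gene_id = rownames(eff), eff, check.names = FALSE),
              fp("truth_effects.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- study$config
  cfg$stage_seeds <- NULL
  yaml::write_yaml(unclass(cfg), fp("config.yaml"))
  invisible(dir)
}
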