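.config_schema <- list(
  annotation   = list(required = TRUE,  type = "path"),
  peaks        = list(required = TRUE,  type = "named_paths"),
  counts       = list(required = TRUE,  type = "path"),
  de_table     = list(required = TRUE,  type = "path"),
  coverage     = list(required = FALSE, type = "named_paths"),
  samples      = list(required = TRUE,  type = "named_lists"),
  de_samples   = list(required = TRUE,  type = "named_lists"),
  ref_condition = list(required = FALSE, type = "character", default = NULL),
  promoter_window = list(required = FALSE, type = "numeric2",
                         default = c(3000, 3000)),
  pseudocount  = list(required = FALSE, type = "number", default = 1,
                      range = c(0, Inf)),
  alpha        = list(required = FALSE, type = "number", default = 0.05,
                      range = c(0, 1)),
  fpkm_cutoff  = list(required = FALSE, type = "number", default = 5,
                      range = c(0, Inf)),
  p_cutoff     = list(required = FALSE, type = "number", default = 0.05,
                      range = c(0, 1)),
  top_n        = list(required = FALSE, type = "number", default = 200,
                      range = c(0, Inf)),
  rank_by      = list(required = FALSE, type = "character",
                      default = "pvalue", choices = c("pvalue")),
  region_classes = list(required = FALSE, type = "character",
                        default = c("promoter_5utr", "genebody",
                                    "distal_intergenic")),
  outdir       = list(required = FALSE, type = "character",
                      default = "chromexpr_out"),
  seed         = list(required = FALSE, type = "number", default = 1,
                      range = c(0, .Machine$integer.max)),
  verbosity    = list(required = FALSE, type = "number", default = 1,
                      range = c(0, 2))
)

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or an equivalent list), fills defaults,
#' rejects unknown keys (suggesting the closest known key) and out-of-range
#' values, and checks that every referenced input path exists.
#'
#' @param config path to a YAML file, a YAML string, or a named list.
#' @param check_paths verify referenced files exist (default TRUE).
#' @return a `pipeline_config` list.
#' @export
validate_config <- function(config, check_paths = TRUE) {
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
  }
  if (!is.list(config)) stop("config must be a YAML file/string or a list")
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown)) {
    hint <- names(.config_schema)[
      apply(adist(unknown, names(.config_schema)), 1, which.min)]
    stop("unknown config key(s): ",
         paste0(unknown, " (did you mean '", hint, "'?)", collapse = ", "))
  }
  out <- list()
  for (key in names(.config_schema)) {
    sch <- .config_schema[[key]]
    val <- config[[key]]
    if (is.null(val)) {
      if (sch$required) stop("missing required config key: ", key)
      val <- sch$default
    }
    if (!is.null(val)) {
      if (sch$type %in% c("number", "numeric2")) {
        val <- as.numeric(unlist(val))
        if (sch$type == "number" && length(val) != 1)
          stop(key, " must be a single number")
        if (sch$type == "numeric2" && length(val) != 2)
          stop(key, " must be two numbers")
        if (!is.null(sch$range) && any(val < sch$range[1] | val > sch$range[2]))
          stop(key, " = ", paste(val, collapse = ","),
               " out of allowed range [", sch$range[1], ", ", sch$range[2], "]")
      }
      if (sch$type == "character") {
        val <- as.character(unlist(val))
        if (!is.null(sch$choices) && !all(val %in% sch$choices))
          stop(key, " must be one of: ", paste(sch$choices, collapse = ", "))
      }
      if (sch$type == "path" && check_paths && !file.exists(val))
        stop("config key '", key, "': file not found: ", val)
      if (sch$type == "named_paths") {
        val <- lapply(val, as.character)
        if (is.null(names(val)) || any(!nzchar(names(val))))
          stop(key, " must be a named mapping (condition: path)")
        if (check_paths) {
          missing <- unlist(val)[!file.exists(unlist(val))]
          if (length(missing))
            stop("config key '", key, "': file(s) not found: ",
                 paste(missing, collapse = ", "))
        }
      }
      if (sch$type == "named_lists") {
        if (is.null(names(val)))
          stop(key, " must be a named mapping (condition: [sample, ...])")
        if (length(val) != 2) stop(key, " must name exactly two conditions")
      }
    }
    out[[key]] <- val
  }
  structure(out, class = "pipeline_config")
}

# condition map sample -> condition from a samples: {cond: [ids]} block
.condition_map <- function(block) {
  conds <- rep(names(block), lengths(block))
  setNames(conds, unlist(block))
}

#' Run the integration pipeline
#'
#' Executes the full stage sequence: read annotation, partition regions,
#' read per-condition peak calls and build consensus peaks, read the count
#' table, normalize (median-of-ratios), per-peak differential statistics,
#' per-gene summed and region-averaged fold changes, DE filtering and top-N
#' selection, region-stratified correlation/quadrant statistics, and overlap
#' enrichment of significantly-up peak genes with mRNA-up genes. Writes all
#' primary tables plus a run log to `outdir`.
#'
#' @param config a `pipeline_config` (see [validate_config()]).
#' @return a `run_report`.
#' @export
run_integration <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (config$verbosity > 0) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(config$outdir, ...)

  gm <- stage("annotation", read_gene_annotation(config$annotation))
  say("annotation: ", nrow(gm$genes), " genes")
  part <- stage("partition", partition_regions(gm, config$promoter_window))
  write_partition_bed(part, fp("partition.bed"))

  peak_sets <- stage("peaks", lapply(config$peaks, read_peaks))
  consensus <- stage("merge-peaks", build_consensus_peaks(peak_sets))
  say("consensus peaks: ", nrow(consensus))
  write_bed(cbind(consensus[, c("chrom", "start", "end")],
                  name = consensus$sources), fp("consensus_peaks.bed"))

  cnt <- stage("counts", read_peak_counts(config$counts))
  cond <- .condition_map(config$samples)
  if (!all(colnames(cnt$counts) %in% names(cond)))
    stop("pipeline stage 'counts': samples block does not cover count ",
         "columns: ",
         paste(setdiff(colnames(cnt$counts), names(cond)), collapse = ", "))
  cond <- cond[colnames(cnt$counts)]
  ann <- stage("annotate", assign_region(cnt$peaks, part))
  class_tab <- table(factor(ann$region_class, levels = REGION_CLASSES))
  say("peaks per class: ",
      paste(names(class_tab), class_tab, sep = "=", collapse = ", "))

  factors <- stage("normalize", size_factors(cnt$counts))
  pd <- stage("peak-log2fc",
              peak_log2fc(cnt$counts, factors, cond,
                          ref = config$ref_condition,
                          pseudocount = config$pseudocount,
                          alpha = config$alpha))
  write.table(cbind(ann, as.data.frame(pd)), fp("peak_differential.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summed <- stage("gene-fc",
                  gene_summed_fc(ann, cnt$counts, factors, cond,
                                 ref = config$ref_condition,
                                 pseudocount = config$pseudocount))
  region_fc <- stage("gene-fc", gene_region_avg_log2fc(pd, ann))
  write.table(summed, fp("gene_summed_fc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(region_fc, fp("gene_region_fc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  de <- stage("de-table", read_de_table(config$de_table))
  de_cond <- .condition_map(config$de_samples)
  if (!any(de$gene_id %in% gm$genes$gene_id))
    stop("pipeline stage 'de-table': no DE gene_id matches the annotation")
  filtered <- stage("filter-genes",
                    filter_significant_genes(de, de_cond,
                                             p_cutoff = config$p_cutoff,
                                             fpkm_cutoff = config$fpkm_cutoff))
  say("DE genes passing filters: ", nrow(filtered), " of ", nrow(de))
  top <- stage("top-genes",
               suppressWarnings(top_changed_genes(filtered, config$top_n)))

  results <- list()
  for (cls in config$region_classes) {
    results[[cls]] <- stage(
      paste0("integrate-", cls),
      correlate_expression_signal(filtered, region_fc, cls, gene_set = top))
    say(sprintf("%s: n = %d, r = %.3f (p = %.3g)", cls,
                results[[cls]]$n_genes, results[[cls]]$pearson_r,
                results[[cls]]$pearson_p))
  }
  int_tab <- integration_table(results)
  write.table(int_tab, fp("integration.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  up_peak_genes <- unique(ann$gene_id[pd$significant_up & !is.na(ann$gene_id)])
  universe <- intersect(de$gene_id, gm$genes$gene_id)
  mrna_up <- de$gene_id[de$pvalue < config$p_cutoff & de$log2fc > 0]
  overlap <- stage("overlap",
                   overlap_enrichment(intersect(up_peak_genes, universe),
                                      intersect(mrna_up, universe), universe))

  if (!is.null(config$coverage)) {
    for (cond_nm in names(config$coverage)) {
      track <- stage("metagene", read_bedgraph(config$coverage[[cond_nm]]))
      prof <- stage("metagene", metagene_profile(track, gm,
                                                 gene_set_label = cond_nm))
      write_metagene_tsv(prof, fp(paste0("metagene_", cond_nm, ".tsv")))
    }
  }

  fingerprint <- paste0("chromexpr-", packageVersion("chromexpr"), ":",
                        paste(deparse(unclass(config)), collapse = ""))
  report <- structure(
    list(config = config,
         counts = list(genes = nrow(gm$genes),
                       consensus_peaks = nrow(consensus),
                       counted_peaks = nrow(cnt$peaks),
                       peaks_per_class = as.list(class_tab),
                       de_genes = nrow(de), de_filtered = nrow(filtered),
                       top_n_used = length(top$gene_ids)),
         integration = results, integration_table = int_tab,
         overlap = overlap,
         fingerprint = fingerprint),
    class = "run_report")
  writeLines(c(log_lines, paste0("fingerprint-length: ",
                                 nchar(fingerprint))), fp("run_log.txt"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("chromexpr run_report\n")
  cat("  genes:", x$counts$genes, "| consensus peaks:",
      x$counts$consensus_peaks, "| DE filtered:", x$counts$de_filtered,
      "\n")
  print(x$integration_table[, c("region_class", "n_genes", "pearson_r",
                                "pearson_p", "significance")])
  print(x$overlap)
  invisible(x)
}

#' Run the integration chain on an in-memory synthetic study
#'
#' Convenience wrapper chaining [assign_region()], [size_factors()],
#' [peak_log2fc()], [gene_region_avg_log2fc()], [gene_summed_fc()] and
#' [correlate_expression_signal()] on a `synthetic_study`, without file I/O.
#'
#' @param study a `synthetic_study` (see [simulate_study()]).
#' @param classes region classes to correlate.
#' @param gene_set optional `gene_set` restriction (default: all genes).
#' @return list with `annotation`, `peak_diff`, `region_fc`, `summed` and
#'   `integration` (list of `integration_result` per class).
#' @export
integrate_study <- function(study, classes = REGION_CLASSES,
                            gene_set = NULL) {
  ann <- assign_region(study$peaks, study$partition)
  factors <- size_factors(study$counts)
  pd <- peak_log2fc(study$counts, factors, study$condition, ref = "ctrl")
  region_fc <- gene_region_avg_log2fc(pd, ann)
  summed <- gene_summed_fc(ann, study$counts, factors, study$condition,
                           ref = "ctrl")
  integration <- lapply(setNames(classes, classes), function(cls) {
    correlate_expression_signal(study$de_table, region_fc, cls,
                                gene_set = gene_set)
  })
  list(annotation = ann, peak_diff = pd, region_fc = region_fc,
       summed = summed, integration = integration)
}
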