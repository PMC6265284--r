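# End-to-end orchestration: identify -> classify -> enrichment calls ->
# neighbor pairs -> (optional) sRNA QC, with a machine-readable manifest
# and a human-readable report.  Every output is a pure function of
# (inputs, config); re-running with the same config is bit-identical.

#' Validate a pipeline configuration
#'
#' @param annotation,reference,seqs,expression,samples,hits Paths to the
#'   assembled GTF, reference coding GTF, transcript FASTA, FPKM matrix,
#'   sample sheet and homology-hit TSV.
#' @param srna Optional path to a BED-like sRNA count table.
#' @param out_dir Output directory.
#' @param min_len,min_fpkm_max,evalue_max,min_aln_aa,min_identity,min_cov
#'   Identification thresholds (see [identify_lncrnas()]).
#' @param window_bp Classifier/pairing window (bp).
#' @param fold_incrna_into INCRNA handling (see [classify_all()]).
#' @param fraction_a,fraction_b Fraction labels for enrichment calls.
#' @param alpha,fc_min,eps Enrichment gates.
#' @param pcc_min Concordant-set threshold (strict `>`).
#' @param correlation_fraction Sample fraction label whose samples enter the
#'   pair correlations (default `"total"`, the condition-profiling samples).
#' @param k,seed Heatmap clustering parameters.
#' @return Validated `PipelineConfig` list.
#' @export
pipeline_config <- function(annotation, reference, seqs, expression, samples,
                            hits, srna = NULL, out_dir,
                            min_len = 150, min_fpkm_max = 1,
                            evalue_max = 1e-4, min_aln_aa = 40,
                            min_identity = 35, min_cov = 35,
                            window_bp = 1000,
                            fold_incrna_into = "keep",
                            fraction_a = "fraction_a",
                            fraction_b = "fraction_b",
                            alpha = 0.05, fc_min = 2, eps = 1,
                            pcc_min = 0.6, correlation_fraction = "total",
                            k = 6, seed = 1) {
  cfg <- as.list(environment())
  req <- c("annotation", "reference", "seqs", "expression", "samples", "hits")
  for (f in req) {
    if (is.null(cfg[[f]])) stop("pipeline config missing input: ", f)
    if (!file.exists(cfg[[f]])) stop("input file does not exist: ", cfg[[f]],
                                     " (", f, ")")
  }
  if (!is.null(cfg$srna) && !file.exists(cfg$srna))
    stop("input file does not exist: ", cfg$srna, " (srna)")
  if (is.null(cfg$seed)) stop("seed is mandatory")
  structure(cfg, class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Stages: lncRNA identification cascade, NAT/lincRNA classification,
#' fraction-enrichment calls, k-means ordering of the enriched set,
#' neighbor-pair correlations with category comparisons and the concordant
#' set, and (when an sRNA table is configured) region RPM summaries.  All
#' tables are written under `config$out_dir` together with `manifest.json`
#' (inputs, parameters, output checksums) and `report.md`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every in-memory result plus `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  anno <- stage("read_inputs", read_annotation(config$annotation))
  ref <- stage("read_inputs", read_annotation(config$reference,
                                              default_biotype = "coding"))
  seqs <- stage("read_inputs", read_transcript_seqs(config$seqs))
  expr <- stage("read_inputs", read_expression_table(config$expression,
                                                     config$samples))
  hits <- stage("read_inputs", read_homology_hits(config$hits))

  ident <- stage("identify", identify_lncrnas(
    anno, expr, hits, seqs, ref,
    min_len = config$min_len, min_fpkm_max = config$min_fpkm_max,
    evalue_max = config$evalue_max, min_aln_aa = config$min_aln_aa,
    min_identity = config$min_identity, min_cov = config$min_cov))

  cls <- stage("classify", classify_all(
    ident$lncrnas, ref, window_bp = config$window_bp,
    fold_incrna_into = config$fold_incrna_into))
  lnc_out <- ident$lncrnas
  lab <- setNames(cls$records$lnc_class, cls$records$transcript_id)
  lnc_out$transcripts[, lnc_class := lab[transcript_id]]

  enr <- stage("enrich", {
    lnc_expr <- structure(list(
      values = expr$values[intersect(rownames(expr$values),
                                     lnc_out$transcripts$transcript_id), ,
                           drop = FALSE],
      samples = expr$samples), class = "ExpressionTable")
    fraction_enrichment(lnc_expr, config$fraction_a, config$fraction_b,
                        alpha = config$alpha, fc_min = config$fc_min,
                        eps = config$eps)
  })
  clust <- stage("cluster", {
    called <- enr$calls[status != "ns", feature_id]
    if (length(called) >= max(2L, config$k)) {
      cond_samples <- expr$samples[fraction == config$correlation_fraction,
                                   sample_id]
      kmeans_order(expr$values[called, cond_samples, drop = FALSE],
                   k = min(config$k, length(called)), seed = config$seed)
    } else NULL
  })

  prs <- stage("pairs", {
    pairs <- assign_pairs(cls$records, ref, window_bp = config$window_bp,
                          lncs = lnc_out)
    use_samples <- expr$samples[fraction == config$correlation_fraction,
                                sample_id]
    records <- pair_correlations(pairs, expr, ref,
                                 min_fpkm_max = config$min_fpkm_max,
                                 samples = use_samples)
    present <- unique(records[excluded == FALSE, pair_type])
    comps <- list()
    for (i in seq_along(present)) for (j in seq_along(present)) {
      if (i == j) next
      cmp <- compare_pair_categories(records, present[i], present[j])
      comps[[length(comps) + 1L]] <- data.table(
        cat_a = present[i], cat_b = present[j], p_value = cmp$p_value,
        u = cmp$u, method = cmp$method,
        median_a = cmp$summary$median[1L], median_b = cmp$summary$median[2L])
    }
    list(records = records,
         comparisons = if (length(comps)) rbindlist(comps) else
           data.table(cat_a = character(0), cat_b = character(0),
                      p_value = numeric(0), u = numeric(0),
                      method = character(0), median_a = numeric(0),
                      median_b = numeric(0)),
         concordant = concordant_set(records, pcc_min = config$pcc_min))
  })

  srna_stat <- if (!is.null(config$srna)) stage("srna_qc", {
    srna <- read_srna_counts(config$srna)
    per_lnc <- lnc_out$transcripts[, {
      q <- rpm_quantify(srna, data.table(chrom = chrom, start = start,
                                         end = end, strand = strand))
      list(read_count = q$read_count, rpm = q$rpm)
    }, by = transcript_id]
    per_lnc[order(transcript_id)]
  }) else NULL

  p <- function(f) file.path(config$out_dir, f)
  paths <- list(lncrna_gtf = p("lncrna.gtf"),
                assessment = p("coding_assessment.tsv"),
                filter_report = p("filter_report.tsv"),
                removals = p("filter_removals.tsv"),
                classification = p("classification.tsv"),
                class_summary = p("class_summary.tsv"),
                enrichment = p("fraction_enrichment.tsv"),
                enrichment_summary = p("fraction_enrichment_summary.tsv"),
                cluster_order = p("cluster_order.tsv"),
                pairs = p("pairs.tsv"),
                comparisons = p("category_comparison.tsv"),
                concordant = p("concordant_pairs.tsv"),
                srna = p("srna_rpm.tsv"),
                manifest = p("manifest.json"), report = p("report.md"))
  write_annotation(lnc_out, paths$lncrna_gtf)
  fwrite(ident$assessment, paths$assessment, sep = "\t")
  fwrite(ident$report$stages, paths$filter_report, sep = "\t")
  fwrite(ident$report$removals, paths$removals, sep = "\t")
  fwrite(cls$records, paths$classification, sep = "\t")
  fwrite(data.table(lnc_class = names(cls$summary),
                    n = as.integer(cls$summary)), paths$class_summary,
         sep = "\t")
  fwrite(enr$calls, paths$enrichment, sep = "\t")
  fwrite(data.table(status = names(enr$summary),
                    n = as.integer(enr$summary)),
         paths$enrichment_summary, sep = "\t")
  if (!is.null(clust))
    fwrite(data.table(feature_id = clust$order,
                      cluster = as.integer(clust$cluster[clust$order])),
           paths$cluster_order, sep = "\t")
  fwrite(prs$records, paths$pairs, sep = "\t")
  fwrite(prs$comparisons, paths$comparisons, sep = "\t")
  fwrite(prs$concordant, paths$concordant, sep = "\t")
  if (!is.null(srna_stat)) fwrite(srna_stat, paths$srna, sep = "\t")

  written <- unlist(paths[vapply(paths, file.exists, logical(1L))])
  manifest <- list(
    inputs = config[c("annotation", "reference", "seqs", "expression",
                      "samples", "hits", "srna")],
    parameters = config[setdiff(names(config),
      c("annotation", "reference", "seqs", "expression", "samples", "hits",
        "srna", "out_dir"))],
    outputs = as.list(tools::md5sum(setdiff(written,
      c(paths$manifest, paths$report)))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  report <- c(
    "# Pipeline report", "",
    sprintf("Input transcripts: %d", n_transcripts(anno)),
    sprintf("Identified lncRNAs: %d", n_transcripts(lnc_out)), "",
    "## Filter cascade",
    sprintf("- %s: %d in, %d removed, %d out", ident$report$stages$stage,
            ident$report$stages$n_in, ident$report$stages$n_removed,
            ident$report$stages$n_out), "",
    "## Classes",
    sprintf("- %s: %d", names(cls$summary), as.integer(cls$summary)), "",
    "## Fraction enrichment",
    sprintf("- %s: %d", names(enr$summary), as.integer(enr$summary)), "",
    "## Neighbor pairs",
    sprintf("- scored pairs: %d (excluded %d)",
            sum(!prs$records$excluded), sum(prs$records$excluded)),
    sprintf("- concordant %s pairs (pcc > %.2g): %d", "NCO",
            config$pcc_min, nrow(prs$concordant)))
  writeLines(report, paths$report)
  invisible(list(anno = anno, ref = ref, identification = ident,
                 classification = cls, lncrnas = lnc_out, enrichment = enr,
                 clustering = clust, pairs = prs, srna = srna_stat,
                 paths = paths, manifest = manifest))
}
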