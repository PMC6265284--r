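#' @import data.table
#' @importFrom stats cor median quantile rnorm runif sd setNames t.test kmeans pnorm
#' @importFrom utils head tail
NULL

utils::globalVariables(c(
  ".", ".N", ".SD", "transcript_id", "gene_id", "chrom", "start", "end",
  "strand", "class_code", "biotype", "lnc_class", "exon_rank", "width",
  "feature_id", "sample_id", "condition", "fraction", "replicate",
  "query_id", "subject_id", "aln_len_aa", "pct_identity", "query_cov_pct",
  "subject_cov_pct", "evalue", "count", "role", "partner_gene_id",
  "pair_type", "a_id", "b_id", "pcc", "excluded", "reason", "stage",
  "n_in", "n_removed", "n_out", "status", "pvalue", "log2fc", "cluster",
  "gap_bp", "overlap_bp", "rho", "enriched", "type"
))

# Internal coordinate convention: 0-based half-open [start, end) on a named
# chromosome with strand '+' or '-'.  GTF I/O is the only conversion point.

STRANDS <- c("+", "-")

#' Construct a genomic interval table row
#'
#' Intervals are 0-based half-open: `start` is the first base (0-based),
#' `end` is one past the last.  Used internally by every module.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (integer, >= 0).
#' @param end 0-based exclusive end (> start).
#' @param strand `"+"` or `"-"`.
#' @return A one-row `data.table` with columns chrom/start/end/strand.
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  dt <- data.table(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand))
  validate_intervals(dt)
  dt
}

validate_intervals <- function(dt, what = "interval") {
  if (any(is.na(dt$start)) || any(is.na(dt$end)))
    stop(what, ": NA coordinates")
  if (any(dt$start < 0L))
    stop(what, ": negative start coordinate")
  if (any(dt$end <= dt$start))
    stop(what, ": end <= start after conversion to 0-based half-open")
  if (!all(dt$strand %in% STRANDS))
    stop(what, ": strand must be one of '+', '-'")
  invisible(dt)
}

#' Construct and validate an annotation set
#'
#' An `AnnotationSet` bundles a transcript table (span coordinates, assembler
#' class code, biotype) with an exon table, both in 0-based half-open
#' coordinates.  Invariants enforced: unique transcript ids; exons sorted,
#' non-overlapping and spanning exactly the transcript interval; total exonic
#' length positive.
#'
#' @param transcripts `data.frame` with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `class_code`, `biotype` and optionally
#'   `lnc_class`.
#' @param exons `data.frame` with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(transcripts, exons) {
  tx <- as.data.table(transcripts)
  ex <- as.data.table(exons)
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand",
           "class_code", "biotype")
  miss <- setdiff(req, names(tx))
  if (length(miss)) stop("transcripts table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"lnc_class" %in% names(tx)) tx[, lnc_class := NA_character_]
  miss <- setdiff(c("transcript_id", "chrom", "start", "end", "strand"),
                  names(ex))
  if (length(miss)) stop("exon table missing columns: ",
                         paste(miss, collapse = ", "))
  tx[, `:=`(start = as.integer(start), end = as.integer(end),
            chrom = as.character(chrom), strand = as.character(strand),
            transcript_id = as.character(transcript_id),
            gene_id = as.character(gene_id),
            class_code = as.character(class_code),
            biotype = as.character(biotype))]
  ex[, `:=`(start = as.integer(start), end = as.integer(end),
            chrom = as.character(chrom), strand = as.character(strand),
            transcript_id = as.character(transcript_id))]
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript_id in annotation")
  if (nrow(tx)) validate_intervals(tx, "transcript span")
  if (nrow(ex)) validate_intervals(ex, "exon")
  if (!all(tx$biotype %in% c("coding", "known_ncRNA", "unknown", "lncRNA")))
    stop("biotype must be coding, known_ncRNA, unknown or lncRNA")
  orphan <- setdiff(ex$transcript_id, tx$transcript_id)
  if (length(orphan)) stop("exons reference unknown transcripts: ",
                           paste(head(orphan, 3), collapse = ", "))
  setkey(ex, transcript_id, start)
  # per-transcript structural invariants, vectorised
  if (nrow(ex)) {
    chk <- ex[, {
      ok_sorted <- !is.unsorted(start)
      ok_disjoint <- .N == 1L || all(start[-1L] >= end[-.N])
      list(ex_start = min(start), ex_end = max(end),
       ok = ok_sorted && ok_disjoint,
       len = sum(end - start),
       one_chrom = uniqueN(chrom) == 1L, one_strand = uniqueN(strand) == 1L)
    }, by = transcript_id]
    if (!all(chk$ok)) stop("exons overlap within a transcript")
    if (!all(chk$one_chrom & chk$one_strand))
      stop("exons of one transcript on multiple chromosomes/strands")
    m <- merge(tx, chk, by = "transcript_id")
    if (!all(m$start == m$ex_start & m$end == m$ex_end))
      stop("transcript span does not match exon extent")
    if (!all(m$len > 0L)) stop("transcript with zero exonic length")
  }
  no_ex <- setdiff(tx$transcript_id, ex$transcript_id)
  if (length(no_ex)) stop("transcripts without exons: ",
                          paste(head(no_ex, 3), collapse = ", "))
  setkey(tx, chrom, start, transcript_id)
  structure(list(transcripts = tx[], exons = ex[]), class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d transcripts, %d genes, %d exons\n",
              nrow(x$transcripts), uniqueN(x$transcripts$gene_id),
              nrow(x$exons)))
  if (nrow(x$transcripts)) {
    tab <- table(x$transcripts$class_code)
    cat("class codes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of transcripts in an AnnotationSet
#' @param anno An `AnnotationSet`.
#' @return Integer count.
#' @export
n_transcripts <- function(anno) nrow(anno$transcripts)

#' Exonic transcript lengths
#'
#' @param anno An `AnnotationSet`.
#' @return Named integer vector of summed exon lengths (nt) per transcript.
#' @export
transcript_lengths <- function(anno) {
  if (!nrow(anno$exons)) return(setNames(integer(0), character(0)))
  len <- anno$exons[, list(len = sum(end - start)), by = transcript_id]
  setNames(len$len, len$transcript_id)
}

#' Subset an AnnotationSet by transcript id
#' @param anno An `AnnotationSet`.
#' @param ids Character vector of transcript ids to keep.
#' @return A new `AnnotationSet`.
#' @export
subset_annotation <- function(anno, ids) {
  annotation_set(anno$transcripts[transcript_id %in% ids],
                 anno$exons[transcript_id %in% ids])
}

# validation-free single-transcript view; for tight oracle loops
single_transcript <- function(anno, id) {
  structure(list(transcripts = anno$transcripts[id, on = "transcript_id"],
                 exons = anno$exons[id, on = "transcript_id"]),
            class = "AnnotationSet")
}

#' Gene-level span table
#'
#' Collapses transcripts to one row per gene: chromosome, union span and
#' strand.  Genes whose transcripts disagree on chromosome or strand are
#' rejected.
#'
#' @param anno An `AnnotationSet`.
#' @return `data.table` with columns gene_id, chrom, start, end, strand.
#' @export
gene_spans <- function(anno) {
  tx <- anno$transcripts
  if (!nrow(tx))
    return(data.table(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  g <- tx[, list(chrom = chrom[1L], start = min(start), end = max(end),
                 strand = strand[1L],
                 ok = uniqueN(chrom) == 1L && uniqueN(strand) == 1L),
          by = gene_id]
  if (!all(g$ok)) stop("gene with transcripts on multiple chromosomes/strands")
  g[, ok := NULL]
  setkey(g, chrom, start, gene_id)
  g[]
}

# Intron table for a set of transcripts: gaps between consecutive exons.
intron_table <- function(anno) {
  ex <- anno$exons
  if (nrow(ex) < 2L)
    return(data.table(transcript_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  ex <- ex[order(transcript_id, start)]
  intr <- ex[, if (.N > 1L)
    list(chrom = chrom[1L], start = end[-.N], end = start[-1L],
         strand = strand[1L]), by = transcript_id]
  if (!"end" %in% names(intr))    # no multi-exon transcript at all
    return(data.table(transcript_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  intr[end > start]
}

#' Construct and validate an expression table
#'
#' FPKM matrix (features x samples) plus a sample sheet.  All values must be
#' finite and non-negative; every sample column must have metadata; replicate
#' indices must be distinct within a condition/fraction group.
#'
#' @param values Numeric matrix with feature ids as rownames and sample ids
#'   as colnames.
#' @param samples `data.frame` with columns `sample_id`, `condition`,
#'   `timepoint`, `fraction`, `replicate`.
#' @return An object of class `ExpressionTable`.
#' @export
expression_table <- function(values, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- as.data.table(samples)
  req <- c("sample_id", "condition", "timepoint", "fraction", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("expression matrix has missing values")
  if (any(values < 0)) stop("negative FPKM value in expression matrix")
  extra <- setdiff(colnames(values), samples$sample_id)
  if (length(extra)) stop("samples absent from sample sheet: ",
                          paste(extra, collapse = ", "))
  extra <- setdiff(samples$sample_id, colnames(values))
  if (length(extra)) stop("sample sheet lists samples not in the matrix: ",
                          paste(extra, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id)]
  dup <- samples[, list(bad = anyDuplicated(replicate) > 0L),
                 by = list(condition, fraction)]
  if (any(dup$bad)) stop("duplicate replicate index within a condition group")
  structure(list(values = values, samples = samples[]),
            class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable: %d features x %d samples (%d conditions)\n",
              nrow(x$values), ncol(x$values), uniqueN(x$samples$condition)))
  invisible(x)
}

#' Maximum FPKM of a feature across all samples
#'
#' FPKM_max is the abundance statistic the length/abundance filter and the
#' pair-correlation exclusion rule both threshold on.
#'
#' @param expr An `ExpressionTable`.
#' @param feature_id Feature id (single string).
#' @return Numeric scalar.
#' @export
fpkm_max <- function(expr, feature_id) {
  if (!feature_id %in% rownames(expr$values))
    stop("feature not in expression table: ", feature_id)
  max(expr$values[feature_id, ])
}

#' Gene-level expression by summing isoform FPKM
#'
#' Coding genes enter neighbor-pair correlations at gene level; summing the
#' FPKM of a gene's isoforms is the standard gene-level convention.
#'
#' @param expr An `ExpressionTable` keyed by transcript id.
#' @param anno `AnnotationSet` providing the gene/transcript mapping.
#' @return Numeric matrix gene_id x sample_id.
#' @export
gene_expression <- function(expr, anno) {
  tx <- anno$transcripts[transcript_id %in% rownames(expr$values)]
  if (!nrow(tx)) return(matrix(0, 0, ncol(expr$values),
                               dimnames = list(NULL, colnames(expr$values))))
  m <- expr$values[tx$transcript_id, , drop = FALSE]
  rs <- rowsum(m, group = tx$gene_id)
  rs[order(rownames(rs)), , drop = FALSE]
}
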