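# External formats: GTF (1-based inclusive), FPKM TSV + sample sheet,
# blast-tabular homology hits (outfmt 6 + qcovs/scovs), transcript FASTA,
# BED-like sRNA region counts.  All conversion to/from the internal 0-based
# half-open convention happens here and nowhere else.

#' Read a GTF annotation into an AnnotationSet
#'
#' GTF coordinates (1-based, inclusive) are converted to the internal 0-based
#' half-open convention.  Exon lines are grouped per `transcript_id` and
#' sorted by start; transcript spans are taken from transcript lines when
#' present, otherwise from the exon extent.  The attributes `class_code`,
#' `biotype` and `lnc_class` are honored when present; transcripts without a
#' `class_code` attribute get the assembler code `"="` (matches reference).
#'
#' @param path Path to a GTF file.
#' @param default_biotype Biotype assigned to transcripts lacking a `biotype`
#'   attribute (default `"unknown"`; use `"coding"` when reading a reference
#'   protein-coding annotation).
#' @return An `AnnotationSet`.
#' @export
read_annotation <- function(path, default_biotype = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  bad <- body[nf != 9L]
  if (length(bad))
    stop("malformed GTF line ", bad[1L], ": expected 9 tab-separated fields, got ",
         nf[which(body == bad[1L])])
  if (!length(body)) {
    return(annotation_set(
      data.table(transcript_id = character(0), gene_id = character(0),
                 chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), class_code = character(0),
                 biotype = character(0)),
      data.table(transcript_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0))))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id))
  for (col in c("class_code", "biotype", "lnc_class")) {
    v <- S4Vectors::mcols(gr)[[col]]
    dt[, (col) := if (is.null(v)) NA_character_ else as.character(v)]
  }
  if (any(is.na(dt$transcript_id)))
    stop("GTF record without transcript_id attribute")
  ex <- dt[type == "exon",
           list(transcript_id, chrom, start, end, strand)]
  if (!nrow(ex)) stop("GTF contains no exon records")
  # per-transcript attributes: prefer the transcript line, fall back to exons
  attr_of <- function(col) {
    a <- dt[, list(v = {
      x <- get(col)[match("transcript", type)]
      if (is.na(x)) x <- get(col)[!is.na(get(col))][1L]
      x
    }), by = transcript_id]
    setNames(a$v, a$transcript_id)
  }
  span <- ex[order(transcript_id, start),
             list(chrom = chrom[1L], start = min(start), end = max(end),
                  strand = strand[1L]), by = transcript_id]
  gid <- attr_of("gene_id"); cc <- attr_of("class_code")
  bt <- attr_of("biotype"); lc <- attr_of("lnc_class")
  tx <- span[, list(transcript_id, gene_id = gid[transcript_id],
                    chrom, start, end, strand,
                    class_code = cc[transcript_id],
                    biotype = bt[transcript_id],
                    lnc_class = lc[transcript_id])]
  tx[is.na(class_code), class_code := "="]
  tx[is.na(biotype), biotype := default_biotype]
  tx[is.na(gene_id), gene_id := transcript_id]
  annotation_set(tx, ex)
}

#' Write an AnnotationSet to GTF
#'
#' Emits 1-based inclusive GTF with one `transcript` line (carrying
#' `class_code`, `biotype` and, when assigned, `lnc_class` attributes)
#' followed by its `exon` lines, in deterministic (chrom, start,
#' transcript_id) order.  Writing the same AnnotationSet twice yields
#' byte-identical files.
#'
#' @param anno An `AnnotationSet`.
#' @param path Output path.
#' @param source_tag String for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(anno, path, source_tag = "natlnc") {
  tx <- copy(anno$transcripts)[order(chrom, start, transcript_id)]
  if (!nrow(tx)) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  ex <- anno$exons[order(transcript_id, start)]
  ex <- ex[tx[, list(transcript_id)], on = "transcript_id"]  # transcript order
  meta <- tx[, list(transcript_id, gene_id, class_code, biotype, lnc_class)]
  exm <- meta[ex, on = "transcript_id"]
  rows <- rbind(
    tx[, list(chrom, start, end, strand, type = "transcript", transcript_id,
              gene_id, class_code, biotype, lnc_class, ord3 = 0L)],
    exm[, list(chrom, start, end, strand, type = "exon", transcript_id,
               gene_id, class_code, biotype, lnc_class, ord3 = 1L)])
  span_start <- setNames(tx$start, tx$transcript_id)
  rows[, ord1 := span_start[transcript_id]]
  rows <- rows[order(chrom, ord1, transcript_id, ord3, start)]
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = rows$strand)
  gr$source <- source_tag
  gr$type <- rows$type
  gr$gene_id <- rows$gene_id
  gr$transcript_id <- rows$transcript_id
  gr$class_code <- rows$class_code
  gr$biotype <- rows$biotype
  if (any(!is.na(rows$lnc_class))) gr$lnc_class <- rows$lnc_class
  rtracklayer::export(gr, path, format = "gtf")
  # drop the volatile date header so identical inputs give identical bytes
  lines <- readLines(path)
  writeLines(lines[!grepl("^##(date|source-version)", lines)], path)
  invisible(path)
}

#' Read an FPKM matrix and its sample sheet
#'
#' @param path TSV with feature ids in the first column and one numeric
#'   column per sample.
#' @param sample_sheet TSV with columns `sample_id`, `condition`,
#'   `timepoint`, `fraction`, `replicate` covering every matrix column.
#' @return An `ExpressionTable`.
#' @export
read_expression_table <- function(path, sample_sheet) {
  for (p in c(path, sample_sheet))
    if (!file.exists(p)) stop("no such file: ", p)
  m <- fread(path, sep = "\t", header = TRUE)
  if (ncol(m) < 2L) stop("expression matrix needs at least one sample column")
  ids <- as.character(m[[1L]])
  vals <- as.matrix(m[, -1L, with = FALSE])
  if (!is.numeric(vals)) stop("non-numeric value in expression matrix")
  rownames(vals) <- ids
  sheet <- fread(sample_sheet, sep = "\t", header = TRUE,
                 colClasses = list(character = "sample_id"))
  expression_table(vals, sheet)
}

#' Write an ExpressionTable to TSV (matrix + sample sheet)
#' @param expr An `ExpressionTable`.
#' @param path Output path for the matrix TSV.
#' @param sample_sheet Output path for the sample sheet TSV.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path, sample_sheet) {
  dt <- data.table(feature_id = rownames(expr$values))
  dt <- cbind(dt, as.data.table(expr$values))
  fwrite(dt, path, sep = "\t")
  fwrite(expr$samples, sample_sheet, sep = "\t")
  invisible(path)
}

HITS_COLS <- c("query_id", "subject_id", "pct_identity", "aln_len_aa",
               "mismatches", "gap_opens", "q_start", "q_end", "s_start",
               "s_end", "evalue", "bit_score", "query_cov_pct",
               "subject_cov_pct")

#' Read protein-homology hits (blast-tabular + coverage columns)
#'
#' The dialect is blast `outfmt 6` (12 columns, no header) extended with two
#' coverage columns (`qcovs`-style percent of query covered, `scovs`-style
#' percent of subject covered), 14 columns total.  For translated searches
#' the alignment length column is in amino acids.
#'
#' @param path TSV path.
#' @return `data.table` with columns `query_id`, `subject_id`, `aln_len_aa`,
#'   `pct_identity`, `query_cov_pct`, `subject_cov_pct`, `evalue`.
#' @export
read_homology_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.table(query_id = character(0), subject_id = character(0),
                      aln_len_aa = integer(0), pct_identity = numeric(0),
                      query_cov_pct = numeric(0), subject_cov_pct = numeric(0),
                      evalue = numeric(0))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 14L))
    stop("homology hits row ", which(nf != 14L)[1L],
         ": expected 14 columns, got ", nf[nf != 14L][1L])
  raw <- as.data.table(do.call(rbind, parts))
  setnames(raw, HITS_COLS)
  num_cols <- setdiff(HITS_COLS, c("query_id", "subject_id"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v))
      stop("homology hits row ", which(is.na(v))[1L],
           ": non-numeric value in column ", col)
    set(raw, j = col, value = v)
  }
  hits <- raw[, list(query_id, subject_id,
                     aln_len_aa = as.integer(aln_len_aa), pct_identity,
                     query_cov_pct, subject_cov_pct, evalue)]
  if (any(hits$aln_len_aa < 1L)) stop("homology hit with alignment length < 1")
  for (col in c("pct_identity", "query_cov_pct", "subject_cov_pct")) {
    v <- hits[[col]]
    if (any(v < 0 | v > 100)) stop("homology hit with ", col, " outside [0, 100]")
  }
  if (any(hits$evalue < 0)) stop("homology hit with negative e-value")
  hits[]
}

#' Write homology hits in the 14-column blast-tabular dialect
#' @param hits `data.table` as returned by [read_homology_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homology_hits <- function(hits, path) {
  hits <- as.data.table(hits)
  out <- hits[, list(query_id, subject_id, pct_identity, aln_len_aa,
                     mismatches = 0L, gap_opens = 0L, q_start = 1L,
                     q_end = pmax(1L, aln_len_aa * 3L), s_start = 1L,
                     s_end = aln_len_aa, evalue, bit_score = 0,
                     query_cov_pct, subject_cov_pct)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read transcript sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_transcript_seqs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write transcript sequences to FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a BED-like sRNA region count table
#'
#' Format: a header line `# total_mapped=<N>` followed by tab-separated
#' columns chrom, start, end, strand, count with 0-based half-open
#' coordinates (BED convention, no conversion needed).
#'
#' @param path TSV path.
#' @return List with `counts` (`data.table`) and `total_mapped` (integer).
#' @export
read_srna_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#\\s*total_mapped=", lines, value = TRUE)
  if (!length(hdr)) stop("sRNA counts file lacks a '# total_mapped=' header")
  total <- as.numeric(sub("^#\\s*total_mapped=", "", hdr[1L]))
  if (!is.finite(total) || total < 1) stop("total_mapped must be >= 1")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) {
    counts <- data.table(chrom = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         count = integer(0))
  } else {
    counts <- fread(text = body, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "strand", "count"))
    counts[, `:=`(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), strand = as.character(strand),
                  count = as.integer(count))]
    validate_intervals(counts, "sRNA region")
    if (any(counts$count < 0L)) stop("negative sRNA read count")
  }
  list(counts = counts[], total_mapped = as.integer(total))
}

#' Write a BED-like sRNA region count table
#' @param counts `data.table` with chrom/start/end/strand/count.
#' @param total_mapped Total mapped reads for RPM normalization.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_srna_counts <- function(counts, total_mapped, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_mapped=%d", as.integer(total_mapped)), con)
  if (nrow(counts))
    write.table(counts[order(chrom, start, end, strand)], con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
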