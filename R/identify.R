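# The lncRNA selection cascade: assembler class codes -> length/abundance ->
# protein-coding evidence (homology OR positive coding-potential score) ->
# sense-overlap removal.  Every stage partitions its input and records a
# per-transcript removal reason, so counts are conserved end to end.

RETAINED_CODES <- c("u", "x", "i")

filter_result <- function(anno, removed_ids, reasons) {
  removed <- data.table(transcript_id = removed_ids, reason = reasons)
  list(retained = subset_annotation(anno,
         setdiff(anno$transcripts$transcript_id, removed_ids)),
       removed = removed[order(transcript_id)])
}

#' Stage 1: retain novel assembler class codes
#'
#' Keeps transcripts with class code `u` (intergenic), `x` (antisense exonic
#' overlap) or `i` (intronic); everything else — reference matches (`=`) and
#' any other code — is removed as known/other.
#'
#' @param anno An `AnnotationSet` whose transcripts all carry a class code.
#' @return List with `retained` (`AnnotationSet`) and `removed`
#'   (`data.table` of transcript_id, reason).
#' @export
class_code_filter <- function(anno) {
  tx <- anno$transcripts
  out <- tx[!class_code %in% RETAINED_CODES, transcript_id]
  filter_result(anno, out, rep("known/other class code", length(out)))
}

#' Stage 2: remove short or lowly expressed transcripts
#'
#' A transcript is removed iff its exonic length is `< min_len` nt or its
#' FPKM_max (maximum FPKM over all samples) is `< min_fpkm_max` — both
#' strict, so length 150 and FPKM_max 1.0 are retained.  Transcripts absent
#' from the expression matrix have undefined FPKM_max and are removed with
#' their own reason code.
#'
#' @param anno An `AnnotationSet`.
#' @param expr An `ExpressionTable`.
#' @param min_len Minimum exonic length (nt).
#' @param min_fpkm_max Minimum FPKM_max.
#' @return List with `retained` and `removed` (with per-criterion reasons).
#' @export
length_abundance_filter <- function(anno, expr, min_len = 150,
                                    min_fpkm_max = 1) {
  tx <- anno$transcripts$transcript_id
  lens <- transcript_lengths(anno)[tx]
  present <- tx %in% rownames(expr$values)
  fmax <- rep(NA_real_, length(tx))
  fmax[present] <- apply(expr$values[tx[present], , drop = FALSE], 1L, max)
  short <- lens < min_len
  low <- !is.na(fmax) & fmax < min_fpkm_max
  absent <- !present
  reason <- character(length(tx))
  reason[short] <- "short_length"
  reason[low] <- ifelse(short[low], "short_length;low_abundance",
                        "low_abundance")
  reason[absent & !short] <- "absent_from_expression"
  reason[absent & short] <- "short_length;absent_from_expression"
  drop <- short | low | absent
  filter_result(anno, tx[drop], reason[drop])
}

#' Scan the three forward frames of a transcript for ORFs
#'
#' An ORF is an `ATG` followed in-frame by a stop codon; its length in amino
#' acids excludes the stop.  `N` never matches in start or stop recognition.
#' The sequence is the already-stranded transcript sequence, so only the
#' three forward frames are scanned.
#'
#' @param seq Nucleotide string over A/C/G/T/U/N (case-insensitive).
#' @return List with `orf_max_aa` and `orfs` (`data.table` of frame,
#'   start_nt (0-based within the sequence), aa_len).
#' @export
scan_orfs <- function(seq) {
  s <- toupper(gsub("U", "T", toupper(seq)))
  if (grepl("[^ACGTN]", s)) stop("invalid character in sequence")
  n <- nchar(s)
  orfs <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    codons <- substring(s, frame + 3L * (seq_len(ncod) - 1L) + 1L,
                        frame + 3L * seq_len(ncod))
    starts <- which(codons == "ATG")
    stops <- which(codons %in% STOPS)
    if (!length(starts) || !length(stops)) next
    # index of the first stop strictly after each start, NA if none
    nxt <- stops[findInterval(starts, stops) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    orfs[[length(orfs) + 1L]] <- data.table(
      frame = frame,
      start_nt = frame + 3L * (starts[ok] - 1L),
      aa_len = nxt[ok] - starts[ok])
  }
  orfs <- if (length(orfs)) rbindlist(orfs) else
    data.table(frame = integer(0), start_nt = integer(0), aa_len = integer(0))
  list(orf_max_aa = if (nrow(orfs)) max(orfs$aa_len) else 0L, orfs = orfs[])
}

#' Does a transcript have a protein-coding homology hit?
#'
#' TRUE iff some hit satisfies e-value `< evalue_max` AND alignment length
#' `>= min_aln_aa` amino acids AND percent identity `>= min_identity` AND
#' coverage of the alignment region in either query or subject
#' `>= min_cov` — boundary semantics exactly as stated (strict e-value,
#' inclusive everything else).
#'
#' @param transcript_id Transcript id.
#' @param hits Homology hit table (see [read_homology_hits()]); rows for
#'   other transcripts are ignored.
#' @param evalue_max,min_aln_aa,min_identity,min_cov Thresholds.
#' @return Logical scalar.
#' @export
homology_coding_filter <- function(transcript_id, hits, evalue_max = 1e-4,
                                   min_aln_aa = 40, min_identity = 35,
                                   min_cov = 35) {
  transcript_id %in% homology_coding_ids(hits, evalue_max, min_aln_aa,
                                         min_identity, min_cov)
}

# all query ids with at least one qualifying hit
homology_coding_ids <- function(hits, evalue_max = 1e-4, min_aln_aa = 40,
                                min_identity = 35, min_cov = 35) {
  hits <- as.data.table(hits)
  if (!nrow(hits)) return(character(0))
  unique(hits[evalue < evalue_max & aln_len_aa >= min_aln_aa &
              pct_identity >= min_identity &
              (query_cov_pct >= min_cov | subject_cov_pct >= min_cov),
              query_id])
}

#' Signed coding-potential score
#'
#' Pluggable scorer honoring the sign contract of coding-potential
#' calculators: positive score means protein-coding.  The built-in scorer is
#' a monotone function of ORF features —
#' `score = (orf_max_aa / 100 - 1) + (orf_coverage / 0.5 - 1)` where
#' `orf_coverage` is the fraction of the transcript occupied by the longest
#' ORF (stop codon included) — so a transcript with a sub-100-aa ORF covering
#' less than half its length always scores negative, and a transcript that is
#' one long ORF scores strongly positive.  Absolute values of external
#' coding-potential tools are deliberately not reproduced; only the sign is
#' consumed downstream.
#'
#' @param transcript_id Transcript id (used in error messages).
#' @param seq Transcript sequence.
#' @param scorer Optional replacement `function(transcript_id, seq)`
#'   returning a signed numeric score.
#' @return Numeric score; positive implies coding.
#' @export
score_coding_potential <- function(transcript_id, seq, scorer = NULL) {
  if (!is.null(scorer)) {
    sc <- tryCatch(scorer(transcript_id, seq), error = function(e)
      stop("coding-potential scorer failed for ", transcript_id, ": ",
           conditionMessage(e)))
    return(as.numeric(sc))
  }
  orf <- scan_orfs(seq)
  aa <- orf$orf_max_aa
  cov <- if (aa > 0L) 3 * (aa + 1L) / nchar(seq) else 0
  (aa / 100 - 1) + (cov / 0.5 - 1)
}

#' Stage 4: remove sense-overlapping transcripts
#'
#' Removes transcripts whose span overlaps a coding-gene span by >= 1 bp on
#' the same strand.  Transcripts contained entirely within a single intron
#' of the overlapped gene (sense-intronic, assembler code `i`) are exempt:
#' they have no exonic sense overlap and are classified downstream.
#' Antisense overlap is always retained.
#'
#' @param anno An `AnnotationSet` of candidate transcripts.
#' @param coding_anno Reference `AnnotationSet`; all transcripts must have
#'   biotype `"coding"`.
#' @return List with `retained` and `removed`.
#' @export
sense_overlap_filter <- function(anno, coding_anno) {
  if (!all(coding_anno$transcripts$biotype == "coding"))
    stop("coding_anno must contain only biotype=coding transcripts")
  tx <- anno$transcripts
  if (!nrow(tx)) return(filter_result(anno, character(0), character(0)))
  genes <- gene_spans(coding_anno)
  hit <- overlap_same_strand(tx, genes)
  if (nrow(hit)) {
    intr <- intron_table(coding_anno)
    intr <- merge(intr, coding_anno$transcripts[, list(transcript_id, gene_id)],
                  by = "transcript_id")
    hit[, contained := mapply(function(id, g) {
      r <- tx[transcript_id == id]
      any(intr$gene_id == g & intr$chrom == r$chrom &
          intr$strand == r$strand &
          intr$start <= r$start & r$end <= intr$end)
    }, transcript_id, gene_id)]
    hit <- hit[, list(all_contained = all(contained)), by = transcript_id]
    out <- hit[all_contained == FALSE, transcript_id]
  } else out <- character(0)
  filter_result(anno, out, rep("sense overlap with coding gene", length(out)))
}

# transcript/gene same-strand span overlaps (>= 1 bp); returns tx id, gene id
overlap_same_strand <- function(tx, genes) {
  if (!nrow(tx) || !nrow(genes))
    return(data.table(transcript_id = character(0), gene_id = character(0)))
  gr_tx <- GenomicRanges::GRanges(tx$chrom,
             IRanges::IRanges(tx$start + 1L, tx$end), strand = tx$strand)
  gr_g <- GenomicRanges::GRanges(genes$chrom,
            IRanges::IRanges(genes$start + 1L, genes$end),
            strand = genes$strand)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_tx, gr_g))
  data.table(transcript_id = tx$transcript_id[S4Vectors::queryHits(ov)],
             gene_id = genes$gene_id[S4Vectors::subjectHits(ov)])
}

#' Run the full lncRNA identification cascade
#'
#' Applies, in order: class-code retention (`u`/`x`/`i`), length/abundance
#' filter, protein-coding filter (qualifying homology hit OR positive
#' coding-potential score removes), and sense-overlap removal.  Survivors
#' are annotated with biotype `"lncRNA"`.
#'
#' @param anno Assembled transcriptome `AnnotationSet` with class codes.
#' @param expr `ExpressionTable` covering (at least) the candidates.
#' @param hits Homology hit table.
#' @param seqs Named character vector of transcript sequences.
#' @param coding_anno Reference coding `AnnotationSet`.
#' @param min_len,min_fpkm_max,evalue_max,min_aln_aa,min_identity,min_cov
#'   Stage thresholds (strict removal thresholds, inclusive hit criteria).
#' @param scorer Optional external coding-potential scorer (see
#'   [score_coding_potential()]).
#' @return List with `lncrnas` (`AnnotationSet`), `assessment`
#'   (per-candidate coding evidence), and `report` (list of `stages` — a
#'   count-conserving `FilterReport` table — and per-transcript `removals`).
#' @export
identify_lncrnas <- function(anno, expr, hits, seqs, coding_anno,
                             min_len = 150, min_fpkm_max = 1,
                             evalue_max = 1e-4, min_aln_aa = 40,
                             min_identity = 35, min_cov = 35, scorer = NULL) {
  stages <- list(); removals <- list()
  note <- function(name, n_in, removed) {
    stages[[length(stages) + 1L]] <<- data.table(
      stage = name, n_in = n_in, n_removed = nrow(removed),
      n_out = n_in - nrow(removed))
    if (nrow(removed))
      removals[[length(removals) + 1L]] <<- cbind(stage = name, removed)
  }

  s1 <- class_code_filter(anno)
  note("class_code", n_transcripts(anno), s1$removed)

  s2 <- length_abundance_filter(s1$retained, expr, min_len, min_fpkm_max)
  note("length_abundance", n_transcripts(s1$retained), s2$removed)

  cand <- s2$retained
  ids <- cand$transcripts$transcript_id
  missing_seq <- setdiff(ids, names(seqs))
  if (length(missing_seq))
    stop("stage coding_potential: missing sequence for ",
         paste(head(missing_seq, 3), collapse = ", "))
  hom_ids <- homology_coding_ids(hits, evalue_max, min_aln_aa, min_identity,
                                 min_cov)
  assessment <- data.table(transcript_id = ids)
  assessment[, homology_coding := transcript_id %in% hom_ids]
  assessment[, orf_max_aa := vapply(seqs[transcript_id],
               function(s) as.integer(scan_orfs(s)$orf_max_aa), 1L)]
  assessment[, cp_score := vapply(transcript_id,
               function(id) score_coding_potential(id, seqs[[id]], scorer),
               1.0)]
  assessment[, coding := homology_coding | cp_score > 0]
  coding_ids <- assessment[coding == TRUE, transcript_id]
  reasons <- assessment[coding == TRUE,
    ifelse(homology_coding & cp_score > 0, "homology_hit;positive_cp_score",
           ifelse(homology_coding, "homology_hit", "positive_cp_score"))]
  s3 <- filter_result(cand, coding_ids, reasons)
  note("coding_potential", length(ids), s3$removed)

  s4 <- sense_overlap_filter(s3$retained, coding_anno)
  note("sense_overlap", n_transcripts(s3$retained), s4$removed)

  lnc <- s4$retained
  lnc$transcripts[, biotype := "lncRNA"]
  report <- list(stages = rbindlist(stages),
                 removals = if (length(removals)) rbindlist(removals) else
                   data.table(stage = character(0),
                              transcript_id = character(0),
                              reason = character(0)))
  stopifnot(all(report$stages$n_out ==
                report$stages$n_in - report$stages$n_removed))
  list(lncrnas = lnc, assessment = assessment[], report = report)
}
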