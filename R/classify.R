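# Strand-aware classification of lncRNAs relative to protein-coding genes.
# Priority: antisense span overlap (NAT_OVERLAPPING) > sense-intronic
# containment (INCRNA) > head-to-head within the window (NAT_DIVERGENT) >
# tail-to-tail within the window (NAT_CONVERGENT) > LINCRNA.  Ties among
# candidate partners break by smallest gap, then smallest gene_id.

LNC_CLASSES <- c("NAT_OVERLAPPING", "INCRNA", "NAT_DIVERGENT",
                 "NAT_CONVERGENT", "LINCRNA")

empty_class_records <- function() {
  data.table(transcript_id = character(0), lnc_class = character(0),
             partner_gene_id = character(0), overlap_bp = integer(0),
             end_gap_bp = integer(0), exonic_overlap = logical(0))
}

#' Classify every lncRNA against the coding annotation
#'
#' Vectorised classifier over all lncRNAs.  See [classify_lncrna()] for the
#' decision procedure; [brute_force_classify()] is the index-free oracle
#' used to verify it.
#'
#' @param lncs `AnnotationSet` of lncRNAs.
#' @param coding_anno Reference coding `AnnotationSet`.
#' @param window_bp Maximum end-to-end gap for divergent/convergent pairing.
#' @param fold_incrna_into `"keep"` reports INCRNA as its own class;
#'   `"lincRNA"` relabels sense-intronic transcripts as LINCRNA;
#'   `"drop"` removes them.
#' @return List with `records` (one `ClassificationRecord` row per lncRNA)
#'   and `summary` (named count per class, all five classes always present).
#' @export
classify_all <- function(lncs, coding_anno, window_bp = 1000,
                         fold_incrna_into = c("keep", "lincRNA", "drop")) {
  fold_incrna_into <- match.arg(fold_incrna_into)
  W <- as.integer(window_bp)
  tx <- lncs$transcripts
  genes <- gene_spans(coding_anno)
  if (nrow(tx)) {
    bad <- setdiff(tx$chrom, unique(coding_anno$transcripts$chrom))
    if (length(bad)) stop("lncRNA on unknown chromosome: ",
                          paste(bad, collapse = ", "))
  }
  if (!nrow(tx)) {
    return(list(records = empty_class_records(),
                summary = setNames(integer(length(LNC_CLASSES)), LNC_CLASSES)))
  }
  lt <- tx[, list(transcript_id, chrom, lstart = start, lend = end,
                  lstrand = strand)]
  gt <- genes[, list(gene_id, chrom, gstart = start, gend = end,
                     gstrand = strand)]
  cand <- merge(lt, gt, by = "chrom", allow.cartesian = TRUE)
  cand[, opp := lstrand != gstrand]
  cand[, ovl := pmin(lend, gend) - pmax(lstart, gstart)]
  cand[, gap := fifelse(gend <= lstart, lstart - gend,
                fifelse(gstart >= lend, gstart - lend, 0L))]
  # geometry of the facing ends for non-overlapping opposite-strand genes
  cand[, head_to_head := opp & ovl <= 0L &
         ((lstrand == "+" & gend <= lstart) |
          (lstrand == "-" & gstart >= lend))]
  cand[, tail_to_tail := opp & ovl <= 0L &
         ((lstrand == "+" & gstart >= lend) |
          (lstrand == "-" & gend <= lstart))]
  # best candidate per lncRNA and class (smallest gap, then gene_id), fully
  # vectorised; classes then combine in priority order
  best_of <- function(d) d[order(transcript_id, gap, gene_id)][
    !duplicated(transcript_id)]
  ovl_b <- best_of(cand[opp == TRUE & ovl > 0L][, gap := 0L])
  div_b <- best_of(cand[head_to_head == TRUE & gap <= W])
  con_b <- best_of(cand[tail_to_tail == TRUE & gap <= W])
  intr <- intron_table(coding_anno)
  intr <- merge(intr, coding_anno$transcripts[, list(transcript_id, gene_id)],
                by = "transcript_id")
  inc_cand <- merge(lt, intr[, list(gene_id, chrom, strand, istart = start,
                                    iend = end)],
                    by = "chrom", allow.cartesian = TRUE)
  inc_cand <- inc_cand[lstrand == strand & istart <= lstart & lend <= iend]
  inc_b <- inc_cand[, gap := 0L][order(transcript_id, gene_id)][
    !duplicated(transcript_id)]
  # assemble records, later assignments (higher priority) win
  records <- data.table(transcript_id = lt$transcript_id,
                        lnc_class = "LINCRNA",
                        partner_gene_id = NA_character_, overlap_bp = 0L,
                        end_gap_bp = NA_integer_, exonic_overlap = FALSE,
                        key = "transcript_id")
  assign_class <- function(b, cls, overlap, gapcol) {
    if (!nrow(b)) return()
    records[b$transcript_id,
            `:=`(lnc_class = cls, partner_gene_id = b$gene_id,
                 overlap_bp = overlap, end_gap_bp = gapcol)]
  }
  assign_class(con_b, "NAT_CONVERGENT", 0L, as.integer(con_b$gap))
  assign_class(div_b, "NAT_DIVERGENT", 0L, as.integer(div_b$gap))
  assign_class(inc_b, "INCRNA",
               as.integer(inc_b$lend - inc_b$lstart), NA_integer_)
  assign_class(ovl_b, "NAT_OVERLAPPING", as.integer(ovl_b$ovl), NA_integer_)
  # exon-level overlap flag for the overlapping NATs, against their partner
  if (nrow(ovl_b)) {
    ex_lnc <- lncs$exons[transcript_id %in% ovl_b$transcript_id]
    ex_cod <- merge(coding_anno$exons,
                    coding_anno$transcripts[, list(transcript_id, gene_id)],
                    by = "transcript_id")
    gr_l <- GenomicRanges::GRanges(ex_lnc$chrom,
      IRanges::IRanges(ex_lnc$start + 1L, ex_lnc$end))
    gr_c <- GenomicRanges::GRanges(ex_cod$chrom,
      IRanges::IRanges(ex_cod$start + 1L, ex_cod$end))
    ov <- GenomicRanges::findOverlaps(gr_l, gr_c, ignore.strand = TRUE)
    hit_pairs <- unique(paste(ex_lnc$transcript_id[S4Vectors::queryHits(ov)],
                              ex_cod$gene_id[S4Vectors::subjectHits(ov)]))
    records[ovl_b$transcript_id,
            exonic_overlap := paste(transcript_id, partner_gene_id) %in%
              hit_pairs]
  }
  if (fold_incrna_into == "lincRNA") {
    records[lnc_class == "INCRNA",
            `:=`(lnc_class = "LINCRNA", partner_gene_id = NA_character_,
                 overlap_bp = 0L)]
  } else if (fold_incrna_into == "drop") {
    records <- records[lnc_class != "INCRNA"]
  }
  summary <- setNames(integer(length(LNC_CLASSES)), LNC_CLASSES)
  tab <- table(records$lnc_class)
  summary[names(tab)] <- as.integer(tab)
  list(records = records[order(transcript_id)], summary = summary)
}

any_exon_overlap <- function(ex_a, ex_b) {
  if (!nrow(ex_a) || !nrow(ex_b)) return(FALSE)
  for (i in seq_len(nrow(ex_a)))
    for (j in seq_len(nrow(ex_b)))
      if (ex_a$chrom[i] == ex_b$chrom[j] &&
          min(ex_a$end[i], ex_b$end[j]) -
          max(ex_a$start[i], ex_b$start[j]) > 0L) return(TRUE)
  FALSE
}

#' Classify a single lncRNA
#'
#' Decision procedure, in priority order: (1) NAT_OVERLAPPING on >= 1 bp
#' span overlap with an opposite-strand coding gene (with an exon-level
#' overlap flag); (2) INCRNA when contained entirely within an intron of a
#' same-strand coding gene; (3) NAT_DIVERGENT when the nearest
#' opposite-strand non-overlapping gene is head-to-head (both 5' ends flank
#' the gap) within `window_bp`; (4) NAT_CONVERGENT likewise tail-to-tail;
#' (5) LINCRNA otherwise.
#'
#' @param lnc A single-transcript `AnnotationSet`.
#' @param coding_anno Reference coding `AnnotationSet`.
#' @param window_bp Pairing window (bp).
#' @return One-row `ClassificationRecord` `data.table`.
#' @export
classify_lncrna <- function(lnc, coding_anno, window_bp = 1000) {
  if (n_transcripts(lnc) != 1L) stop("classify_lncrna expects one transcript")
  classify_all(lnc, coding_anno, window_bp)$records
}

#' Index-free oracle classifier
#'
#' Same contract as [classify_lncrna()], implemented as an exhaustive scalar
#' scan over every coding gene with no vectorisation or index structures.
#' Used in tests to verify the production classifier.
#'
#' @inheritParams classify_lncrna
#' @return One-row `ClassificationRecord` `data.table`.
#' @export
brute_force_classify <- function(lnc, coding_anno, window_bp = 1000) {
  if (n_transcripts(lnc) != 1L) stop("brute_force_classify expects one transcript")
  r <- lnc$transcripts[1L]
  chroms <- unique(coding_anno$transcripts$chrom)
  if (!r$chrom %in% chroms)
    stop("lncRNA on unknown chromosome: ", r$chrom)
  genes <- gene_spans(coding_anno)
  g_id <- genes$gene_id; g_chrom <- genes$chrom
  g_start <- genes$start; g_end <- genes$end; g_strand <- genes$strand
  ex <- coding_anno$exons[order(transcript_id, start)]
  ex_gene <- coding_anno$transcripts[match(ex$transcript_id,
                                           transcript_id), gene_id]
  e_tid <- ex$transcript_id; e_start <- ex$start; e_end <- ex$end
  best <- list(ovl = NULL, inc = NULL, div = NULL, con = NULL)
  better <- function(cur, gap, gid)
    is.null(cur) || gap < cur$gap || (gap == cur$gap && gid < cur$gid)
  for (i in seq_along(g_id)) {
    if (g_chrom[i] != r$chrom) next
    ovl <- min(r$end, g_end[i]) - max(r$start, g_start[i])
    opp <- g_strand[i] != r$strand
    if (opp && ovl > 0L) {
      if (better(best$ovl, 0L, g_id[i]))
        best$ovl <- list(gap = 0L, gid = g_id[i], ovl = ovl)
      next
    }
    if (!opp && ovl > 0L) {
      # same-strand overlap: intron containment check, exon by exon
      idx <- which(ex_gene == g_id[i])
      for (k in idx) {
        nxt <- k + 1L
        if (nxt > length(e_tid) || e_tid[nxt] != e_tid[k]) next
        if (e_end[k] <= r$start && r$end <= e_start[nxt] &&
            better(best$inc, 0L, g_id[i]))
          best$inc <- list(gap = 0L, gid = g_id[i])
      }
      next
    }
    if (opp && ovl <= 0L) {
      gene_left <- g_end[i] <= r$start
      gap <- if (gene_left) r$start - g_end[i] else g_start[i] - r$end
      head_to_head <- (r$strand == "+" && gene_left) ||
                      (r$strand == "-" && !gene_left)
      if (gap <= window_bp) {
        if (head_to_head) {
          if (better(best$div, gap, g_id[i]))
            best$div <- list(gap = gap, gid = g_id[i])
        } else {
          if (better(best$con, gap, g_id[i]))
            best$con <- list(gap = gap, gid = g_id[i])
        }
      }
    }
  }
  if (!is.null(best$ovl)) {
    ex_cod <- merge(coding_anno$exons,
                    coding_anno$transcripts[, list(transcript_id, gene_id)],
                    by = "transcript_id")
    exov <- any_exon_overlap(lnc$exons, ex_cod[gene_id == best$ovl$gid])
    return(data.table(transcript_id = r$transcript_id,
      lnc_class = "NAT_OVERLAPPING", partner_gene_id = best$ovl$gid,
      overlap_bp = as.integer(best$ovl$ovl), end_gap_bp = NA_integer_,
      exonic_overlap = exov))
  }
  if (!is.null(best$inc))
    return(data.table(transcript_id = r$transcript_id, lnc_class = "INCRNA",
      partner_gene_id = best$inc$gid,
      overlap_bp = as.integer(r$end - r$start), end_gap_bp = NA_integer_,
      exonic_overlap = FALSE))
  if (!is.null(best$div))
    return(data.table(transcript_id = r$transcript_id,
      lnc_class = "NAT_DIVERGENT", partner_gene_id = best$div$gid,
      overlap_bp = 0L, end_gap_bp = as.integer(best$div$gap),
      exonic_overlap = FALSE))
  if (!is.null(best$con))
    return(data.table(transcript_id = r$transcript_id,
      lnc_class = "NAT_CONVERGENT", partner_gene_id = best$con$gid,
      overlap_bp = 0L, end_gap_bp = as.integer(best$con$gap),
      exonic_overlap = FALSE))
  data.table(transcript_id = r$transcript_id, lnc_class = "LINCRNA",
             partner_gene_id = NA_character_, overlap_bp = 0L,
             end_gap_bp = NA_integer_, exonic_overlap = FALSE)
}
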