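# sRNA-based RNAi-artifact checks: region RPM quantification, detection of
# secondary siRNAs outside an amiRNA target site, and amiRNA* (passenger
# strand) specificity checks against the sense mRNA.

#' RPM quantification of a genomic region
#'
#' Sums the read counts of all regions overlapping the query by >= 1 bp
#' (strand-agnostic by default) and normalises to reads per million:
#' `rpm = read_count / total_mapped * 1e6`.
#'
#' @param srna List with `counts` and `total_mapped` from
#'   [read_srna_counts()] or [generate_srna_counts()].
#' @param region One-row interval table (see [genomic_interval()]).
#' @param stranded If TRUE, only count reads on the region's strand.
#' @return List with `region`, `read_count`, `total_mapped`, `rpm`.
#' @export
rpm_quantify <- function(srna, region, stranded = FALSE) {
  if (is.null(srna$total_mapped) || srna$total_mapped < 1)
    stop("total_mapped must be >= 1")
  validate_intervals(region, "region")
  cts <- srna$counts
  hit <- cts$chrom == region$chrom & cts$start < region$end &
         cts$end > region$start
  if (stranded) hit <- hit & cts$strand == region$strand
  rc <- sum(cts$count[hit])
  list(region = region, read_count = rc, total_mapped = srna$total_mapped,
       rpm = rc / srna$total_mapped * 1e6)
}

#' Detect secondary siRNAs outside an amiRNA target site
#'
#' Quantifies sRNA abundance on the transcript span excluding the target
#' site plus `flank_bp` on each side.  Secondary siRNAs are called present
#' when that outside abundance reaches `min_outside_rpm` RPM — the planted
#' positive/negative cases of the synthetic generator sit far on either
#' side of this threshold.
#'
#' @param srna sRNA counts list (see [rpm_quantify()]).
#' @param transcript One-row transcript span (chrom/start/end/strand).
#' @param target_site One-row interval inside the transcript span.
#' @param flank_bp Flank excluded around the target site (bp).
#' @param min_outside_rpm Detection threshold (RPM).
#' @return List with `detected`, `inside_rpm`, `outside_rpm`.
#' @export
secondary_sirna_check <- function(srna, transcript, target_site,
                                  flank_bp = 50, min_outside_rpm = 1) {
  validate_intervals(transcript, "transcript span")
  validate_intervals(target_site, "target site")
  if (target_site$chrom != transcript$chrom ||
      target_site$start < transcript$start ||
      target_site$end > transcript$end)
    stop("target site outside transcript span")
  if (is.null(srna$total_mapped) || srna$total_mapped < 1)
    stop("total_mapped must be >= 1")
  cts <- srna$counts
  ex_lo <- target_site$start - flank_bp
  ex_hi <- target_site$end + flank_bp
  on_tx <- cts$chrom == transcript$chrom & cts$start < transcript$end &
           cts$end > transcript$start
  in_site <- on_tx & cts$start < ex_hi & cts$end > ex_lo
  outside <- on_tx & !in_site
  inside_rpm <- sum(cts$count[in_site]) / srna$total_mapped * 1e6
  outside_rpm <- sum(cts$count[outside]) / srna$total_mapped * 1e6
  list(detected = outside_rpm >= min_outside_rpm,
       inside_rpm = inside_rpm, outside_rpm = outside_rpm)
}

RC_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' amiRNA* specificity check against a sense mRNA
#'
#' Finds the best ungapped antisense match of the star (passenger) strand in
#' the sense mRNA — the alignment maximising Watson-Crick base pairs (G:U
#' wobble not counted unless `allow_gu`) — and reports the mismatch
#' positions relative to the star 5' end, whether any falls in the critical
#' cleavage-site window, and whether the star strand begins with a 5'
#' uridine (which favors loading into the silencing effector).  T and U are
#' interchangeable in both inputs.
#'
#' @param star_seq amiRNA* sequence (5'->3').
#' @param sense_mrna_seq Sense mRNA sequence (5'->3').
#' @param critical_positions Positions (1-based from the star 5' end) whose
#'   mismatches abolish target cleavage; default 9-11.
#' @param allow_gu Count G:U wobble pairs as matches.
#' @return List with `star_seq`, `has_5p_U`, `n_complementary`,
#'   `mismatch_positions`, `critical_mismatch`, `match_offset` (0-based
#'   offset of the best alignment in the mRNA, NA when the mRNA is shorter
#'   than the star).
#' @export
amirna_star_check <- function(star_seq, sense_mrna_seq,
                              critical_positions = 9:11, allow_gu = FALSE) {
  norm <- function(s) {
    s <- gsub("U", "T", toupper(s))
    if (!nchar(s)) stop("empty sequence")
    if (grepl("[^ACGTN]", s)) stop("invalid character in sequence")
    s
  }
  star <- norm(star_seq); mrna <- norm(sense_mrna_seq)
  L <- nchar(star); M <- nchar(mrna)
  star_v <- strsplit(star, "")[[1]]
  mrna_v <- strsplit(mrna, "")[[1]]
  has_5p_u <- star_v[1L] == "T"
  pairs_with <- function(star_base, mrna_base) {
    wc <- RC_MAP[[star_base]] == mrna_base && star_base != "N"
    if (wc) return(TRUE)
    allow_gu && ((star_base == "G" && mrna_base == "T") ||
                 (star_base == "T" && mrna_base == "G"))
  }
  if (M < L) {
    return(list(star_seq = star_seq, has_5p_U = has_5p_u,
                n_complementary = 0L, mismatch_positions = seq_len(L),
                critical_mismatch = any(seq_len(L) %in% critical_positions),
                match_offset = NA_integer_))
  }
  # star pairs antisense: star position p aligns with mRNA position
  # offset + (L - p + 1); scan every ungapped offset
  best_n <- -1L; best_off <- 0L; best_matched <- logical(L)
  for (off in 0:(M - L)) {
    matched <- vapply(seq_len(L), function(p)
      pairs_with(star_v[p], mrna_v[off + L - p + 1L]), logical(1L))
    n <- sum(matched)
    if (n > best_n) { best_n <- n; best_off <- off; best_matched <- matched }
  }
  mism <- which(!best_matched)
  list(star_seq = star_seq, has_5p_U = has_5p_u,
       n_complementary = as.integer(best_n),
       mismatch_positions = mism,
       critical_mismatch = any(mism %in% critical_positions),
       match_offset = as.integer(best_off))
}
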