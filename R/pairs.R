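# Neighbor-pair construction and co-expression.  Pair vocabulary:
#   CCO/CCD/CCC  coding-coding pairs (overlapped / divergent / convergent)
#   NCO/NCD/NCC  NAT-lncRNA with its cognate or closest gene
#   LC           lincRNA with its closest gene
# Correlations are Pearson on FPKM vectors; pairs with a low-abundance
# member (FPKM_max < 1) or a constant vector are excluded, not zeroed.

PAIR_TYPES <- c("CCO", "CCD", "CCC", "NCO", "NCD", "NCC", "LC")

#' Build neighbor pairs from classification records and the gene annotation
#'
#' NCO/NCD/NCC pairs come directly from each NAT's classification partner;
#' LC pairs link each lincRNA to its closest coding gene (span-gap distance
#' on either strand, 0 if touching, ties by smaller gene_id); CC* pairs are
#' immediately adjacent coding-gene pairs typed by the same geometry rules
#' as the NAT classes (antisense overlap, head-to-head or tail-to-tail
#' within the window).  Each unordered pair appears once.
#'
#' @param class_records Records from [classify_all()].
#' @param coding_anno Reference coding `AnnotationSet`.
#' @param window_bp Pairing window for divergent/convergent geometry.
#' @param lncs The classified lncRNA `AnnotationSet`; required when the
#'   records contain lincRNAs (their coordinates drive the closest-gene
#'   lookup).
#' @return `data.table` with columns a_id, b_id, pair_type.
#' @export
assign_pairs <- function(class_records, coding_anno, window_bp = 1000,
                         lncs = NULL) {
  rec <- as.data.table(class_records)
  if (is.null(lncs)) {
    if (any(rec$lnc_class == "LINCRNA"))
      stop("assign_pairs needs the lncRNA AnnotationSet (lncs=) to pair ",
           "lincRNAs with their closest gene")
    lncs <- list(transcripts = data.table(transcript_id = character(0),
                                          chrom = character(0),
                                          start = integer(0), end = integer(0),
                                          strand = character(0)))
  }
  build_pairs(rec, lncs, coding_anno, window_bp)
}

#' Build all neighbor pairs (records plus lncRNA coordinates)
#'
#' @param class_records Records from [classify_all()].
#' @param lncs The classified lncRNA `AnnotationSet` (for lincRNA
#'   coordinates).
#' @param coding_anno Reference coding `AnnotationSet`.
#' @param window_bp Pairing window (bp).
#' @return `data.table` with columns a_id, b_id, pair_type.
#' @export
build_pairs <- function(class_records, lncs, coding_anno, window_bp = 1000) {
  rec <- as.data.table(class_records)
  genes <- gene_spans(coding_anno)
  W <- as.integer(window_bp)
  out <- list()
  nat <- rec[lnc_class %in% c("NAT_OVERLAPPING", "NAT_DIVERGENT",
                              "NAT_CONVERGENT")]
  if (nrow(nat))
    out$nat <- nat[, list(a_id = transcript_id, b_id = partner_gene_id,
      pair_type = c(NAT_OVERLAPPING = "NCO", NAT_DIVERGENT = "NCD",
                    NAT_CONVERGENT = "NCC")[lnc_class])]
  linc_ids <- rec[lnc_class == "LINCRNA", transcript_id]
  if (length(linc_ids) && nrow(genes)) {
    lt <- lncs$transcripts[transcript_id %in% linc_ids]
    lc <- lt[, {
      gap <- pmax(genes$start - end, start - genes$end, 0L)
      same_chrom <- genes$chrom == chrom
      if (any(same_chrom)) {
        idx <- which(same_chrom)[order(gap[same_chrom],
                                       genes$gene_id[same_chrom])][1L]
        list(b_id = genes$gene_id[idx])
      } else list(b_id = NA_character_)
    }, by = transcript_id]
    lc <- lc[!is.na(b_id)]
    if (nrow(lc))
      out$lc <- lc[, list(a_id = transcript_id, b_id, pair_type = "LC")]
  }
  # coding-coding pairs: immediately adjacent genes, typed by geometry
  if (nrow(genes) >= 2L) {
    g <- genes[order(chrom, start, gene_id)]
    a <- g[-.N]; b <- g[-1L]
    adj <- data.table(
      chrom_ok = a$chrom == b$chrom,
      a_id = a$gene_id, b_id = b$gene_id,
      a_start = a$start, a_end = a$end, a_strand = a$strand,
      b_start = b$start, b_end = b$end, b_strand = b$strand)
    adj <- adj[chrom_ok == TRUE][, chrom_ok := NULL]
    if (nrow(adj)) {
      adj[, ovl := pmin(a_end, b_end) - pmax(a_start, b_start)]
      adj[, gap := pmax(b_start - a_end, 0L)]
      adj[, pair_type := NA_character_]
      adj[a_strand != b_strand & ovl > 0L, pair_type := "CCO"]
      # left gene's and right gene's facing ends decide the geometry
      adj[a_strand == "-" & b_strand == "+" & ovl <= 0L & gap <= W,
          pair_type := "CCD"]
      adj[a_strand == "+" & b_strand == "-" & ovl <= 0L & gap <= W,
          pair_type := "CCC"]
      cc <- adj[!is.na(pair_type), list(a_id, b_id, pair_type)]
      if (nrow(cc)) out$cc <- unique(cc)
    }
  }
  res <- if (length(out)) rbindlist(out) else
    data.table(a_id = character(0), b_id = character(0),
               pair_type = character(0))
  # one row per unordered pair
  res[, key := paste(pmin(a_id, b_id), pmax(a_id, b_id))]
  res <- res[!duplicated(key)][, key := NULL]
  res[order(pair_type, a_id)]
}

#' Pearson correlations for neighbor pairs
#'
#' The first member of an N*/LC pair is a lncRNA quantified at transcript
#' level; coding members are quantified at gene level (isoform FPKM summed).
#' A pair is excluded (with reason) when a member is absent from the
#' expression table, when either member's FPKM_max over the used samples is
#' below `min_fpkm_max`, or when either vector is constant.
#'
#' @param pairs Pair table from [build_pairs()].
#' @param expr An `ExpressionTable` keyed by transcript id.
#' @param anno Annotation covering the coding genes (for isoform summing).
#' @param min_fpkm_max Abundance exclusion threshold (strict `<` excludes).
#' @param samples Optional character vector restricting the sample columns
#'   used (default: all samples).
#' @return `data.table` of PairRecords: a_id, b_id, pair_type, pcc,
#'   n_samples, excluded, reason.
#' @export
pair_correlations <- function(pairs, expr, anno, min_fpkm_max = 1,
                              samples = NULL) {
  pairs <- as.data.table(pairs)
  vals <- expr$values
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(vals))
    if (length(missing)) stop("unknown samples: ",
                              paste(missing, collapse = ", "))
    vals <- vals[, samples, drop = FALSE]
  }
  gm <- gene_expression(list(values = vals,
                             samples = expr$samples[sample_id %in% colnames(vals)]) |>
                          structure(class = "ExpressionTable"), anno)
  get_vec <- function(id) {
    if (id %in% rownames(gm)) gm[id, ]
    else if (id %in% rownames(vals)) vals[id, ]
    else NULL
  }
  n <- nrow(pairs)
  pcc <- rep(NA_real_, n); excl <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    x <- get_vec(pairs$a_id[i]); y <- get_vec(pairs$b_id[i])
    if (is.null(x) || is.null(y)) {
      excl[i] <- TRUE; reason[i] <- "missing_expression"; next
    }
    if (max(x) < min_fpkm_max || max(y) < min_fpkm_max) {
      excl[i] <- TRUE; reason[i] <- "low_abundance"; next
    }
    if (sd(x) == 0 || sd(y) == 0) {
      excl[i] <- TRUE; reason[i] <- "constant"; next
    }
    pcc[i] <- cor(x, y)
  }
  data.table(pairs[, list(a_id, b_id, pair_type)], pcc = pcc,
             n_samples = ncol(vals), excluded = excl, reason = reason)
}

#' One-tailed Mann-Whitney U test (greater)
#'
#' Tests H1: values of `x` are stochastically greater than values of `y`.
#' When both samples have n <= `exact_max` the p-value is computed by
#' exhaustive enumeration of all C(n1+n2, n1) group assignments of the
#' pooled values (ties handled naturally, observed assignment included);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest group size for exact enumeration.
#' @return List with `u` (U statistic of `x`), `p_value`, `method`.
#' @export
mann_whitney_one_tailed <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) stop("empty category in Mann-Whitney test")
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u <- u_stat(x, y)
  if (n1 <= exact_max && n2 <= exact_max) {
    pool <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2L, function(ii) u_stat(pool[ii], pool[-ii]))
    p <- mean(us >= u - 1e-12)
    return(list(u = u, p_value = p, method = "exact enumeration"))
  }
  N <- n1 + n2
  r <- rank(c(x, y))
  ties <- table(r)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (u - mu - 0.5) / sqrt(sigma2)
  list(u = u, p_value = pnorm(z, lower.tail = FALSE),
       method = "normal approximation")
}

#' Compare the pcc distributions of two pair categories
#'
#' One-tailed Mann-Whitney U test of H1: category `cat_a`'s correlations are
#' stochastically greater than `cat_b`'s, plus the boxplot summary (median,
#' quartiles, whiskers at 1.5 x IQR) for each category.
#'
#' @param records PairRecords from [pair_correlations()].
#' @param cat_a,cat_b Pair types to compare (e.g. `"NCO"`, `"CCO"`).
#' @return List with `p_value`, `u`, `method`, and `summary` (one row per
#'   category: n, median, q1, q3, whisker_lo, whisker_hi).
#' @export
compare_pair_categories <- function(records, cat_a, cat_b) {
  records <- as.data.table(records)
  vx <- records[pair_type == cat_a & excluded == FALSE, pcc]
  vy <- records[pair_type == cat_b & excluded == FALSE, pcc]
  if (!length(vx)) stop("no scored pairs in category ", cat_a)
  if (!length(vy)) stop("no scored pairs in category ", cat_b)
  mw <- mann_whitney_one_tailed(vx, vy)
  box <- function(v, lab) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    data.table(category = lab, n = length(v), median = q[2],
               q1 = q[1], q3 = q[3],
               whisker_lo = max(min(v), q[1] - 1.5 * iqr),
               whisker_hi = min(max(v), q[3] + 1.5 * iqr))
  }
  list(p_value = mw$p_value, u = mw$u, method = mw$method,
       summary = rbind(box(vx, cat_a), box(vy, cat_b)))
}

#' Extract the concordant pair set
#'
#' Pairs of the requested type with Pearson correlation strictly greater
#' than `pcc_min` (0.6 exactly is excluded).
#'
#' @param records PairRecords from [pair_correlations()].
#' @param pcc_min Strict lower bound on pcc.
#' @param pair_type Pair category to filter (default overlapping-NAT pairs).
#' @return Filtered PairRecords.
#' @export
concordant_set <- function(records, pcc_min = 0.6, pair_type = "NCO") {
  records <- as.data.table(records)
  pt <- pair_type
  records[excluded == FALSE & records$pair_type == pt & pcc > pcc_min]
}
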