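# FPKM-based two-group calls (Welch t-test on log2(FPKM + eps), fold-change
# on pseudo-count-stabilised FPKM means) and k-means row ordering for
# heatmaps.  The enrichment gates are P < alpha AND fold-change >= fc_min,
# with strict p and inclusive fold-change gates; p-values are raw by default.

#' Define a two-group contrast
#'
#' @param group_a,group_b Disjoint character vectors of sample ids, each
#'   with at least two samples.
#' @param label Contrast label.
#' @return A `Contrast` list.
#' @export
contrast <- function(group_a, group_b, label = "a_vs_b") {
  if (length(intersect(group_a, group_b)))
    stop("contrast groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each contrast group needs >= 2 samples")
  structure(list(group_a = group_a, group_b = group_b, label = label),
            class = "Contrast")
}

# vectorised Welch t-test on rows of two matrices (log scale)
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1L, stats::var); v2 <- apply(b, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: no variance in either group
  flat <- se2 == 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
  p
}

#' Two-group differential/enrichment call per feature
#'
#' Welch two-sample t-test on `log2(FPKM + eps)` with a fold-change computed
#' on pseudo-count-stabilised FPKM means,
#' `log2fc = log2((mean_a + eps) / (mean_b + eps))`.  A feature is called
#' `enriched_a` iff `pvalue < alpha` and `log2fc >= log2(fc_min)`,
#' `enriched_b` symmetrically, otherwise `ns`.  Two zero-variance groups
#' with equal means give p = 1.
#'
#' @param expr An `ExpressionTable`.
#' @param ctr A [contrast()].
#' @param alpha Significance threshold (strict `<`).
#' @param fc_min Minimum fold-change on the called side (inclusive `>=`).
#' @param eps Pseudo-FPKM added before logs and ratios.
#' @param fdr If TRUE, apply Benjamini-Hochberg correction to the p-values
#'   before gating (off by default to match the raw-p criterion).
#' @return `data.table` with feature_id, mean_a, mean_b, log2fc, pvalue,
#'   status.
#' @export
differential_call <- function(expr, ctr, alpha = 0.05, fc_min = 2, eps = 1,
                              fdr = FALSE) {
  stopifnot(inherits(ctr, "Contrast"))
  missing <- setdiff(c(ctr$group_a, ctr$group_b), colnames(expr$values))
  if (length(missing)) stop("contrast samples not in expression table: ",
                            paste(missing, collapse = ", "))
  a <- expr$values[, ctr$group_a, drop = FALSE]
  b <- expr$values[, ctr$group_b, drop = FALSE]
  p <- welch_rows(log2(a + eps), log2(b + eps))
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  lfc <- log2((mean_a + eps) / (mean_b + eps))
  status <- rep("ns", nrow(a))
  status[p < alpha & lfc >= log2(fc_min)] <- "enriched_a"
  status[p < alpha & -lfc >= log2(fc_min)] <- "enriched_b"
  data.table(feature_id = rownames(a), mean_a = mean_a, mean_b = mean_b,
             log2fc = lfc, pvalue = p, status = status)
}

#' Fraction-enrichment calls (poly(A)+/- or nuclear/cytosolic)
#'
#' Wraps [differential_call()] over the samples of two fraction labels and
#' summarises the calls.
#'
#' @param expr An `ExpressionTable` whose sample sheet carries the fractions.
#' @param fraction_a,fraction_b Fraction labels from the sample sheet
#'   (`enriched_a` means enriched in `fraction_a`).
#' @param alpha,fc_min,eps,fdr Passed to [differential_call()].
#' @return List with `calls` (per-feature table) and `summary` (named counts
#'   `enriched_a`, `enriched_b`, `ns`, partitioning the features).
#' @export
fraction_enrichment <- function(expr, fraction_a, fraction_b, alpha = 0.05,
                                fc_min = 2, eps = 1, fdr = FALSE) {
  sheet <- expr$samples
  for (f in c(fraction_a, fraction_b))
    if (!f %in% sheet$fraction)
      stop("fraction label not in sample sheet: ", f)
  ctr <- contrast(sheet[fraction == fraction_a, sample_id],
                  sheet[fraction == fraction_b, sample_id],
                  label = paste0(fraction_a, "_vs_", fraction_b))
  calls <- differential_call(expr, ctr, alpha, fc_min, eps, fdr)
  summary <- setNames(integer(3L), c("enriched_a", "enriched_b", "ns"))
  tab <- table(calls$status)
  summary[names(tab)] <- as.integer(tab)
  list(calls = calls, summary = summary)
}

#' K-means ordering of expression rows for heatmap display
#'
#' Rows are scaled to fractional density (each row divided by its maximum)
#' and clustered with `stats::kmeans` (10 random restarts, best total
#' within-cluster sum of squares) under a fixed seed.  Clusters are ordered
#' by the position of their centroid's center of mass along the sample axis,
#' and features within a cluster by their own profile's center of mass,
#' giving a deterministic display order.
#'
#' @param values Numeric matrix (features x samples) or `ExpressionTable`.
#' @param k Number of clusters (1 <= k <= number of features).
#' @param seed Mandatory integer seed.
#' @return List with `order` (feature ids in display order), `cluster`
#'   (named integer labels in 1..k), `k`, `seed`.
#' @export
kmeans_order <- function(values, k, seed) {
  if (inherits(values, "ExpressionTable")) values <- values$values
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(values)) stop("k exceeds the number of features")
  if (missing(seed)) stop("seed is mandatory")
  rmax <- apply(values, 1L, max)
  scaled <- values / ifelse(rmax == 0, 1, rmax)
  cl <- with_seed(as.integer(seed), {
    if (k == 1L) list(cluster = rep(1L, nrow(values)))
    else stats::kmeans(scaled, centers = k, nstart = 10L, iter.max = 50L)
  })
  labels <- cl$cluster
  pos <- seq_len(ncol(scaled))
  com <- as.numeric(scaled %*% pos) / pmax(rowSums(scaled), .Machine$double.eps)
  cl_com <- tapply(com, labels, mean)
  cl_rank <- rank(cl_com, ties.method = "first")
  new_label <- as.integer(cl_rank[as.character(labels)])
  ord <- order(new_label, com, rownames(values))
  list(order = rownames(values)[ord],
       cluster = setNames(new_label, rownames(values)),
       k = as.integer(k), seed = as.integer(seed))
}
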