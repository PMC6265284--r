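test_that("pair assignment maps classes and types correctly", {
  d <- default_gen()
  id <- identify_lncrnas(d$gen$anno, d$expr, d$hits, d$gen$seqs, d$ref)
  cls <- classify_all(id$lncrnas, d$ref)
  pairs <- assign_pairs(cls$records, d$ref, lncs = id$lncrnas)
  tab <- table(pairs$pair_type)
  # one pair per planted NAT/lincRNA, plus the planted coding-coding pairs
  expect_equal(unname(tab[c("NCO", "NCD", "NCC", "LC")]), rep(10L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(tab[c("CCO", "CCD", "CCC")]), rep(5L, 3),
               ignore_attr = TRUE)
  # NCO pairs carry the classification partner
  nco <- pairs[pair_type == "NCO"]
  truth <- d$gen$truth$transcripts
  m <- merge(nco, truth, by.x = "a_id", by.y = "transcript_id")
  expect_equal(m$b_id, m$partner_gene_id)
  # each unordered pair appears once
  key <- paste(pmin(pairs$a_id, pairs$b_id), pmax(pairs$a_id, pairs$b_id))
  expect_false(anyDuplicated(key) > 0)
  # truth's nearest-gene bookkeeping agrees with the LC partner choice
  lc <- pairs[pair_type == "LC"]
  m2 <- merge(lc, truth, by.x = "a_id", by.y = "transcript_id")
  expect_equal(m2$b_id, m2$partner_gene_id)
})

test_that("coding-coding geometry follows the NAT rules, lincRNA ties break by id", {
  g <- function(id, start, end, strand) list(
    tx = data.table::data.table(transcript_id = paste0(id, ".1"),
      gene_id = id, chrom = "chr1", start = start, end = end,
      strand = strand, class_code = "=", biotype = "coding"),
    ex = data.table::data.table(transcript_id = paste0(id, ".1"),
      chrom = "chr1", start = start, end = end, strand = strand))
  # A/B overlap antisense; C/D divergent (gap 400); D/E same strand (no pair)
  gs <- list(g("A", 1000L, 2000L, "+"), g("B", 1900L, 2900L, "-"),
             g("C", 6000L, 7000L, "-"), g("D", 7400L, 8400L, "+"),
             g("E", 9000L, 9900L, "+"))
  ref <- annotation_set(data.table::rbindlist(lapply(gs, `[[`, "tx")),
                        data.table::rbindlist(lapply(gs, `[[`, "ex")))
  # a lincRNA exactly equidistant between D and E (gap 100 both sides)
  linc <- one_lnc(8500L, 8900L, "+", id = "LINC")
  rec <- data.table::data.table(transcript_id = "LINC",
    lnc_class = "LINCRNA", partner_gene_id = NA_character_,
    overlap_bp = 0L, end_gap_bp = NA_integer_, exonic_overlap = FALSE)
  pairs <- assign_pairs(rec, ref, lncs = linc)
  expect_equal(pairs[pair_type == "CCO", paste(a_id, b_id)], "A B")
  expect_equal(pairs[pair_type == "CCD", paste(a_id, b_id)], "C D")
  expect_equal(pairs[pair_type == "LC", b_id], "D")   # tie -> smaller gene_id
  expect_false("CCC" %in% pairs$pair_type)
})

test_that("pair correlations use hand-checkable Pearson values and exclusions", {
  ids <- c("L1", "L2", "L3", "G1.1", "G2.1", "G3.1")
  m <- rbind(L1 = c(1, 2, 3), L2 = c(1, 2, 4), L3 = c(2, 2, 2),
             G1.1 = c(2, 4, 6), G2.1 = c(1, 3, 5), G3.1 = c(0.5, 0.9, 0.2))
  colnames(m) <- paste0("s", 1:3)
  expr <- expression_table(m, data.table::data.table(
    sample_id = colnames(m), condition = "c", timepoint = 1L,
    fraction = "total", replicate = 1:3))
  anno <- annotation_set(
    data.table::data.table(transcript_id = c("G1.1", "G2.1", "G3.1"),
      gene_id = c("G1", "G2", "G3"), chrom = "chr1",
      start = c(0L, 1000L, 2000L), end = c(500L, 1500L, 2500L),
      strand = "+", class_code = "=", biotype = "coding"),
    data.table::data.table(transcript_id = c("G1.1", "G2.1", "G3.1"),
      chrom = "chr1", start = c(0L, 1000L, 2000L),
      end = c(500L, 1500L, 2500L), strand = "+"))
  pairs <- data.table::data.table(
    a_id = c("L1", "L1", "L2", "L3", "L1"),
    b_id = c("G1", "G3", "G2", "G1", "G2"),
    pair_type = c("NCO", "NCO", "NCO", "NCO", "NCD"))
  rec <- pair_correlations(pairs, expr, anno)
  expect_equal(rec[a_id == "L1" & b_id == "G1", pcc], 1)       # (1,2,3)/(2,4,6)
  expect_equal(rec[a_id == "L2" & b_id == "G2", pcc],
               3 / sqrt(7 / 3 * 4))                            # hand Pearson
  # member with FPKM_max 0.9 -> excluded as low abundance
  expect_true(rec[b_id == "G3", excluded])
  expect_equal(rec[b_id == "G3", reason], "low_abundance")
  # constant vector -> excluded with reason
  expect_equal(rec[a_id == "L3", reason], "constant")
  # perfect anticorrelation
  m2 <- m; m2["L1", ] <- c(3, 2, 1)
  expr2 <- expression_table(m2, expr$samples)
  rec2 <- pair_correlations(pairs[1], expr2, anno)
  expect_equal(rec2$pcc, -1)
  # exclusion partitions the pair set
  expect_equal(sum(rec$excluded) + sum(!rec$excluded), nrow(pairs))
  # symmetry in the two members
  swapped <- pair_correlations(
    data.table::data.table(a_id = "G1", b_id = "L1", pair_type = "NCO"),
    expr, anno)
  expect_equal(swapped$pcc, rec[a_id == "L1" & b_id == "G1", pcc])
})

test_that("one-tailed Mann-Whitney matches enumeration and wilcox.test", {
  # hand-enumerable case: C(4,2) = 6 assignments, one as extreme
  mw <- mann_whitney_one_tailed(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(mw$p_value, 1 / 6)
  expect_equal(mw$method, "exact enumeration")
  # identical single observations split across groups: p = 0.5 at U = n/2
  expect_equal(mann_whitney_one_tailed(5, 5)$p_value, 1)
  expect_equal(mann_whitney_one_tailed(c(1, 2), c(1, 2))$p_value, 5 / 6)
  # agreement with wilcox.test exact p for tie-free small samples
  set.seed(11)
  for (k in 1:30) {
    x <- round(runif(sample(2:8, 1)), 6)
    y <- round(runif(sample(2:8, 1)), 6)
    ref <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                        exact = TRUE)$p.value)
    expect_equal(mann_whitney_one_tailed(x, y)$p_value, ref,
                 tolerance = 1e-12)
  }
  # agreement with the tie/continuity-corrected normal approximation
  set.seed(12)
  for (k in 1:10) {
    x <- sample(seq(0, 1, 0.1), 15, replace = TRUE)
    y <- sample(seq(0, 1, 0.1), 12, replace = TRUE)
    ref <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                        exact = FALSE, correct = TRUE)$p.value)
    res <- mann_whitney_one_tailed(x, y)
    expect_equal(res$method, "normal approximation")
    expect_equal(res$p_value, ref, tolerance = 1e-9)
  }
})

test_that("category comparison reports medians, quartiles and a one-tailed p", {
  rec <- data.table::data.table(
    a_id = paste0("a", 1:8), b_id = paste0("b", 1:8),
    pair_type = rep(c("NCO", "CCO"), each = 4),
    pcc = c(0.8, 0.9, 0.7, 0.85, 0.1, 0.2, 0.15, 0.05),
    n_samples = 10L, excluded = FALSE, reason = NA_character_)
  cmp <- compare_pair_categories(rec, "NCO", "CCO")
  expect_equal(cmp$p_value, 1 / choose(8, 4))   # complete separation
  expect_equal(cmp$summary$median, c(0.825, 0.125))
  expect_equal(cmp$summary$n, c(4L, 4L))
  expect_error(compare_pair_categories(rec, "NCO", "LC"), "no scored pairs")
  # label split of identically drawn values -> p near 0.5
  set.seed(3)
  v <- rnorm(40)
  rec2 <- data.table::data.table(
    a_id = paste0("a", 1:40), b_id = paste0("b", 1:40),
    pair_type = rep(c("X", "Y"), 20), pcc = v, n_samples = 10L,
    excluded = FALSE, reason = NA_character_)
  cmp2 <- compare_pair_categories(rec2, "X", "Y")
  expect_gt(cmp2$p_value, 0.1)
  expect_lt(cmp2$p_value, 0.9)
})

test_that("concordant set applies a strict pcc threshold to one pair type", {
  rec <- data.table::data.table(
    a_id = c("a1", "a2", "a3", "a4"), b_id = c("b1", "b2", "b3", "b4"),
    pair_type = c("NCO", "NCO", "NCO", "CCO"),
    pcc = c(0.6, 0.61, 0.9, 0.95), n_samples = 10L,
    excluded = FALSE, reason = NA_character_)
  cs <- concordant_set(rec)
  expect_setequal(cs$a_id, c("a2", "a3"))   # 0.60 exactly is out, CCO is out
  expect_equal(nrow(concordant_set(rec[0])), 0L)
})
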