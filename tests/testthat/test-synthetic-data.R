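test_that("generator produces the configured counts and is deterministic", {
  cfg <- synthetic_config(n_coding_genes = 50, n_per_lnc_class = 10, seed = 7)
  gen <- generate_annotation(cfg)
  tt <- gen$truth$transcripts
  expect_equal(nrow(tt), 100L)              # 50 coding + 5 classes x 10
  expect_equal(sum(tt$role == "coding"), 50L)
  expect_equal(unname(table(tt$role)[c("NAT_OVERLAPPING", "NAT_DIVERGENT",
                                       "NAT_CONVERGENT", "LINCRNA",
                                       "INCRNA")]),
               rep(10L, 5), ignore_attr = TRUE)
  gen2 <- generate_annotation(cfg)
  expect_identical(gen$anno$transcripts, gen2$anno$transcripts)
  expect_identical(gen$seqs, gen2$seqs)
  # roles are mutually exclusive and every NAT names its partner
  expect_false(anyDuplicated(tt$transcript_id) > 0)
  nat <- tt[role %in% c("NAT_OVERLAPPING", "NAT_DIVERGENT", "NAT_CONVERGENT",
                        "INCRNA")]
  expect_false(any(is.na(nat$partner_gene_id)))
})

test_that("planted geometry respects the classifier window and margins", {
  d <- default_gen()
  tt <- d$gen$truth$transcripts
  tx <- d$gen$anno$transcripts
  genes <- gene_spans(d$ref)
  W <- d$cfg$pairing_window_bp; M <- d$cfg$class_margin_bp
  span <- function(id) tx[transcript_id == id]
  gspan <- function(g) genes[gene_id == g]
  for (i in which(tt$role == "NAT_DIVERGENT")) {
    l <- span(tt$transcript_id[i]); g <- gspan(tt$partner_gene_id[i])
    expect_true(l$strand != g$strand)
    ovl <- min(l$end, g$end) - max(l$start, g$start)
    expect_lte(ovl, 0L)                      # zero span overlap
    gap <- if (g$end <= l$start) l$start - g$end else g$start - l$end
    expect_lt(gap, W)                        # 5'-5' gap inside the window
    expect_lte(gap, W - M)                   # and clear of the boundary
    # head-to-head: the two 5' ends flank the gap
    gene_left <- g$end <= l$start
    expect_true((l$strand == "+" && gene_left) ||
                (l$strand == "-" && !gene_left))
  }
  for (i in which(tt$role == "NAT_OVERLAPPING")) {
    l <- span(tt$transcript_id[i]); g <- gspan(tt$partner_gene_id[i])
    expect_true(l$strand != g$strand)
    expect_gte(min(l$end, g$end) - max(l$start, g$start), 1L)
  }
  for (i in which(tt$role == "LINCRNA")) {
    l <- span(tt$transcript_id[i])
    gap <- pmax(genes$start - l$end, l$start - genes$end, 0L)
    expect_gte(min(gap), W + M)              # far from every gene
  }
  for (i in which(tt$role == "INCRNA")) {
    l <- span(tt$transcript_id[i]); g <- gspan(tt$partner_gene_id[i])
    expect_identical(l$strand, g$strand)
    intr <- natlnc:::intron_table(subset_annotation(d$ref,
      d$ref$transcripts[gene_id == g$gene_id, transcript_id]))
    expect_true(any(intr$start <= l$start & l$end <= intr$end))
  }
})

test_that("infeasible placement fails with a configuration error", {
  cfg <- synthetic_config(chrom_length = 10000, seed = 1)
  expect_error(generate_annotation(cfg), "chrom_length")
})

test_that("expression model plants exact correlations in degenerate settings", {
  cfg <- synthetic_config(n_coding_genes = 20, n_per_lnc_class = 5,
                          chrom_length = 1e6, rho_nco = 1, noise_sd = 0,
                          seed = 3)
  gen <- generate_annotation(cfg)
  expr <- generate_expression(gen$truth, cfg)
  expect_true(all(expr$values > 0))
  samp <- expr$samples[fraction == "total", sample_id]
  pr <- gen$truth$pairs[pair_type == "NCO"]
  r <- mapply(function(a, b) cor(expr$values[a, samp], expr$values[b, samp]),
              pr$a_feature, pr$b_feature)
  expect_equal(unname(r), rep(1, nrow(pr)))
})

test_that("null enrichment configuration plants no fraction effect", {
  cfg <- synthetic_config(n_coding_genes = 20, n_per_lnc_class = 5,
                          chrom_length = 1e6, enrichment_log2fc = 0,
                          n_enriched = 5, seed = 4)
  gen <- generate_annotation(cfg)
  expr <- generate_expression(gen$truth, cfg)
  enr <- gen$truth$transcripts[enriched == "fraction_a", transcript_id]
  expect_equal(length(enr), 5L)
  a <- expr$samples[fraction == "fraction_a", sample_id]
  b <- expr$samples[fraction == "fraction_b", sample_id]
  d <- rowMeans(log2(expr$values[enr, a])) -
       rowMeans(log2(expr$values[enr, b]))
  expect_lt(max(abs(d)), 1)   # only replicate noise, no planted shift
})

test_that("mean pair correlation matches the model's own expectation", {
  # independent oracle: direct Monte-Carlo of the bivariate log-normal model
  # (9 condition effects x 3 replicates, rho planted on the FPKM scale)
  oracle <- local({
    set.seed(99)
    rho <- 0.8; cond_sd <- 1; noise_sd <- 0.2
    rl <- natlnc:::latent_rho(rho, cond_sd, noise_sd)
    r <- replicate(2000, {
      ea <- rnorm(9, 0, cond_sd)
      eb <- rl * ea + sqrt(1 - rl^2) * rnorm(9, 0, cond_sd)
      x <- 2^(4 + rep(ea, each = 3) + rnorm(27, 0, noise_sd))
      y <- 2^(4 + rep(eb, each = 3) + rnorm(27, 0, noise_sd))
      cor(x, y)
    })
    mean(r)
  })
  expect_gt(oracle, 0.7)                 # the model really does sit near 0.8
  cfg <- synthetic_config(n_coding_genes = 800, n_per_lnc_class = 200,
                          chrom_length = 1e7, rho_nco = 0.8, seed = 1)
  gen <- generate_annotation(cfg)
  expr <- generate_expression(gen$truth, cfg)
  samp <- expr$samples[fraction == "total", sample_id]
  pr <- gen$truth$pairs[pair_type == "NCO"]
  r <- mapply(function(a, b) cor(expr$values[a, samp], expr$values[b, samp]),
              pr$a_feature, pr$b_feature)
  expect_equal(length(r), 200L)
  expect_lt(abs(mean(r) - oracle), 0.05) # generator agrees with the oracle
  expect_lt(abs(mean(r) - 0.8), 0.1)     # and with the nominal planted rho
})

test_that("homology generator plants qualifying decoys and failing lncRNA hits", {
  d <- default_gen()
  hits <- d$hits
  tt <- d$gen$truth$transcripts
  qual <- hits[evalue < 1e-4 & aln_len_aa >= 40 & pct_identity >= 35 &
               (query_cov_pct >= 35 | subject_cov_pct >= 35)]
  decoys <- tt[role == "decoy", transcript_id]
  expect_true(all(decoys %in% qual$query_id))
  lnc <- tt[grepl("^LNC_", transcript_id), transcript_id]
  expect_false(any(lnc %in% qual$query_id))
})

test_that("sRNA generator concentrates or spreads reads as configured", {
  d <- default_gen()
  neg <- generate_srna_counts(d$gen$truth, d$cfg, d$gen$anno,
                              case = "negative")
  expect_true(all(neg$counts$start >= neg$target_site$start &
                  neg$counts$end <= neg$target_site$end))
  pos <- generate_srna_counts(d$gen$truth, d$cfg, d$gen$anno,
                              case = "positive", spread_fraction = 0.5,
                              n_reads = 10000)
  inside <- pos$counts[start < pos$target_site$end &
                       end > pos$target_site$start, sum(count)]
  expect_equal(inside / sum(pos$counts$count), 0.5, tolerance = 0.01)
  none <- generate_srna_counts(d$gen$truth, d$cfg, d$gen$anno, n_reads = 0)
  expect_equal(nrow(none$counts), 0L)
  expect_gt(none$total_mapped, 0L)
})

test_that("fixture bundles pass the package validators and are reproducible", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- make_fixtures(d1, seed = 7, scale = "tiny")
  b2 <- make_fixtures(d2, seed = 7, scale = "tiny")
  for (f in names(b1$paths)) {
    expect_identical(unname(tools::md5sum(b1$paths[[f]])),
                     unname(tools::md5sum(b2$paths[[f]])), label = f)
  }
  anno <- read_annotation(b1$paths$annotation)
  expect_equal(n_transcripts(anno), nrow(b1$truth$transcripts))
  expr <- read_expression_table(b1$paths$expression, b1$paths$samples)
  expect_true(all(expr$values > 0))
  expect_gt(nrow(read_homology_hits(b1$paths$hits)), 0L)
})
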