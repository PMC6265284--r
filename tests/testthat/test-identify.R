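test_that("class-code filter retains u/x/i and removes everything else", {
  codes <- c("u", "x", "i", "=", "o")
  tx <- data.table::data.table(
    transcript_id = paste0("t", 1:5), gene_id = paste0("g", 1:5),
    chrom = "chr1", start = seq(0L, 40000L, 10000L),
    end = seq(500L, 40500L, 10000L), strand = "+",
    class_code = codes, biotype = "unknown")
  ex <- tx[, list(transcript_id, chrom, start, end, strand)]
  anno <- annotation_set(tx, ex)
  res <- class_code_filter(anno)
  expect_equal(n_transcripts(res$retained), 3L)
  expect_setequal(res$removed$transcript_id, c("t4", "t5"))
  # all-retained input removes nothing; empty input stays empty
  allu <- class_code_filter(res$retained)
  expect_equal(nrow(allu$removed), 0L)
  empty <- class_code_filter(subset_annotation(anno, character(0)))
  expect_equal(n_transcripts(empty$retained), 0L)
  expect_equal(nrow(empty$removed), 0L)
})

test_that("length and abundance removal thresholds are strict", {
  mk <- function(len) one_lnc(1000L, 1000L + len, "+", id = paste0("L", len))
  anno <- annotation_set(
    rbind(mk(149)$transcripts, mk(150)$transcripts, mk(2000)$transcripts),
    rbind(mk(149)$exons, mk(150)$exons, mk(2000)$exons))
  expr <- flat_expr(c("L149", "L150", "L2000"), c(5, 1.0, 0.99))
  res <- length_abundance_filter(anno, expr)
  expect_setequal(res$retained$transcripts$transcript_id, "L150")
  expect_equal(res$removed[transcript_id == "L149", reason], "short_length")
  expect_equal(res$removed[transcript_id == "L2000", reason], "low_abundance")
  # transcript missing from the matrix is removed with its own reason
  expr2 <- flat_expr(c("L149", "L150"), c(5, 2))
  res2 <- length_abundance_filter(anno, expr2)
  expect_equal(res2$removed[transcript_id == "L2000", reason],
               "absent_from_expression")
})

test_that("ORF scanner matches hand-translated and brute-force results", {
  expect_equal(scan_orfs("ATGAAATAG")$orf_max_aa, 2L)     # Met-Lys
  expect_equal(scan_orfs("CCCCCC")$orf_max_aa, 0L)
  expect_equal(scan_orfs("ATGTTTTTTTGA")$orf_max_aa, 3L)
  expect_equal(scan_orfs("ATGNNNTAG")$orf_max_aa, 2L)     # N inside is fine
  expect_equal(scan_orfs("NTGAAATAG")$orf_max_aa, 0L)     # N never matches
  expect_equal(scan_orfs("atguuuuag")$orf_max_aa, 2L)     # case and U/T
  expect_error(scan_orfs("ACGTX"), "invalid character")
  # brute-force oracle: walk every ATG, translate codon by codon
  brute <- function(s) {
    s <- gsub("U", "T", toupper(s)); best <- 0L
    for (i in seq_len(max(0L, nchar(s) - 2L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      j <- i
      while (j + 5L <= nchar(s)) {
        cod <- substr(s, j + 3L, j + 5L)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, (j + 3L - i) %/% 3L)
          break
        }
        j <- j + 3L
      }
    }
    best
  }
  set.seed(42)
  for (k in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(10:200, 1),
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    expect_equal(scan_orfs(s)$orf_max_aa, brute(s), label = s)
  }
})

test_that("homology hit criteria use inclusive aa/identity/coverage and a strict e-value", {
  hit <- function(aln, id, qcov, scov, e)
    data.table::data.table(query_id = "t1", subject_id = "p1",
                           aln_len_aa = aln, pct_identity = id,
                           query_cov_pct = qcov, subject_cov_pct = scov,
                           evalue = e)
  expect_true(homology_coding_filter("t1", hit(40, 35.0, 35.0, 0, 1e-10)))
  expect_false(homology_coding_filter("t1", hit(39, 99, 99, 99, 1e-50)))
  expect_false(homology_coding_filter("t1", hit(100, 80, 80, 80, 1e-3)))
  expect_false(homology_coding_filter("t1", hit(100, 80, 80, 80, 1e-4)))
  expect_true(homology_coding_filter("t1", hit(40, 35, 0, 35, 1e-10)))
  expect_false(homology_coding_filter("t1", hit(40, 35, 34, 34, 1e-10)))
  expect_false(homology_coding_filter("t2", hit(100, 90, 90, 90, 1e-30)))
})

test_that("built-in coding-potential scorer honors the sign contract", {
  # one long ORF spanning the whole transcript
  long_orf <- paste0("ATG", paste(rep("GCT", 300), collapse = ""), "TAA")
  expect_gt(score_coding_potential("t", long_orf), 0)
  # no ORF at all
  expect_lt(score_coding_potential("t", "CCCCCCCCCCCC"), 0)
  # sub-100-aa ORF with low coverage is always negative
  small <- paste0(paste(rep("C", 800), collapse = ""),
                  "ATG", paste(rep("GCT", 50), collapse = ""), "TAA")
  expect_lt(score_coding_potential("t", small), 0)
  # pluggable scorer is used and failures carry the transcript id
  expect_equal(score_coding_potential("t", "ACGT",
                                      scorer = function(id, s) 2.5), 2.5)
  expect_error(score_coding_potential("tx9", "ACGT",
                                      scorer = function(id, s) stop("boom")),
               "tx9")
  # sign agreement with planted truth on the default genome's decoys/lncRNAs
  d <- default_gen()
  tt <- d$gen$truth$transcripts[role %in% c("decoy", "NAT_DIVERGENT",
                                            "LINCRNA", "NAT_CONVERGENT")]
  scores <- vapply(tt$transcript_id,
                   function(id) score_coding_potential(id, d$gen$seqs[[id]]),
                   1.0)
  expect_equal(mean((scores > 0) == (tt$role == "decoy")), 1)
})

test_that("sense-overlap removal is strand-aware and intron-exempt", {
  ref <- one_gene_ref(1000L, 3000L, "+",
                      exon_breaks = list(start = c(1000L, 2200L),
                                         end = c(1800L, 3000L)))
  # 1 bp same-strand span overlap -> removed
  brush <- one_lnc(2999L, 3400L, "+", id = "Lbrush")
  # opposite-strand full containment -> retained
  anti <- one_lnc(1200L, 1700L, "-", id = "Lanti")
  # same-strand transcript fully inside the intron -> retained (no exonic
  # sense overlap; it is classified as intronic downstream)
  intronic <- one_lnc(1850L, 2100L, "+", id = "Lintron")
  # no genes on this chromosome -> retained
  faraway <- annotation_set(
    data.table::data.table(transcript_id = "Lfar", gene_id = "Lfar",
                           chrom = "chr9", start = 0L, end = 400L,
                           strand = "+", class_code = "u",
                           biotype = "unknown"),
    data.table::data.table(transcript_id = "Lfar", chrom = "chr9",
                           start = 0L, end = 400L, strand = "+"))
  anno <- annotation_set(
    rbind(brush$transcripts, anti$transcripts, intronic$transcripts,
          faraway$transcripts),
    rbind(brush$exons, anti$exons, intronic$exons, faraway$exons))
  res <- sense_overlap_filter(anno, ref)
  expect_setequal(res$removed$transcript_id, "Lbrush")
  expect_setequal(res$retained$transcripts$transcript_id,
                  c("Lanti", "Lintron", "Lfar"))
  expect_error(sense_overlap_filter(anno, one_lnc(1L, 100L, "+")),
               "biotype")
})

test_that("cascade conserves counts, is idempotent, and recovers the truth", {
  d <- default_gen()
  id <- identify_lncrnas(d$gen$anno, d$expr, d$hits, d$gen$seqs, d$ref)
  st <- id$report$stages
  expect_equal(st$n_out, st$n_in - st$n_removed)
  expect_equal(st$n_in[-1], st$n_out[-nrow(st)])
  expect_equal(st$n_in[1], n_transcripts(d$gen$anno))
  expect_equal(st$n_out[nrow(st)], n_transcripts(id$lncrnas))
  # removals table partitions the input
  expect_equal(nrow(id$report$removals) + n_transcripts(id$lncrnas),
               n_transcripts(d$gen$anno))
  # planted-truth recovery: all lncRNAs survive, every decoy removed
  truth <- d$gen$truth$transcripts
  expect_setequal(id$lncrnas$transcripts$transcript_id,
                  truth[grepl("^LNC_", transcript_id), transcript_id])
  expect_true(all(truth[role == "decoy", transcript_id] %in%
                  id$report$removals$transcript_id))
  # idempotence: running the cascade on its own output removes nothing
  again <- identify_lncrnas(id$lncrnas, d$expr, d$hits, d$gen$seqs, d$ref)
  expect_equal(sum(again$report$stages$n_removed), 0L)
  # survivors are annotated as lncRNA
  expect_true(all(id$lncrnas$transcripts$biotype == "lncRNA"))
})

test_that("relaxing length or abundance thresholds never shrinks the output", {
  d <- default_gen()
  base <- identify_lncrnas(d$gen$anno, d$expr, d$hits, d$gen$seqs, d$ref,
                           min_len = 300, min_fpkm_max = 2)
  looser <- identify_lncrnas(d$gen$anno, d$expr, d$hits, d$gen$seqs, d$ref,
                             min_len = 150, min_fpkm_max = 1)
  expect_true(all(base$lncrnas$transcripts$transcript_id %in%
                  looser$lncrnas$transcripts$transcript_id))
})

test_that("all-coding input yields an empty lncRNA set with conserved counts", {
  d <- default_gen()
  coding_ids <- d$gen$truth$transcripts[role == "coding", transcript_id]
  coding_only <- subset_annotation(d$gen$anno, coding_ids)
  id <- identify_lncrnas(coding_only, d$expr, d$hits, d$gen$seqs, d$ref)
  expect_equal(n_transcripts(id$lncrnas), 0L)
  st <- id$report$stages
  expect_equal(st$n_out, st$n_in - st$n_removed)
})

test_that("lncRNA class codes survive the cascade (class 'i' retained)", {
  toy <- read_toy()
  id <- identify_lncrnas(toy$anno, toy$expr, toy$hits, toy$seqs, toy$ref)
  expect_setequal(id$lncrnas$transcripts$transcript_id,
                  c("TX_LNC1", "TX_LNC2"))
})
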