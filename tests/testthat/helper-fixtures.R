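# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, code) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(code), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# the standard simulated study (seed 7) plus decoys and coding-coding pairs
default_gen <- function() cached("default_gen", {
  cfg <- synthetic_config(n_decoys = 10, n_cc_pairs = 5, seed = 7)
  gen <- generate_annotation(cfg)
  list(cfg = cfg, gen = gen, ref = coding_reference(gen),
       expr = generate_expression(gen$truth, cfg),
       hits = generate_homology_hits(gen$truth, cfg))
})

toy_path <- function(f) {
  p <- system.file("extdata", "toy", f, package = "natlnc")
  if (!nzchar(p)) p <- file.path("../../inst/extdata/toy", f)
  p
}

read_toy <- function() cached("toy", {
  list(anno = read_annotation(toy_path("annotation.gtf")),
       ref = read_annotation(toy_path("reference.gtf"),
                             default_biotype = "coding"),
       expr = read_expression_table(toy_path("expression.tsv"),
                                    toy_path("samples.tsv")),
       hits = read_homology_hits(toy_path("hits.tsv")),
       seqs = read_transcript_seqs(toy_path("transcripts.fa")))
})

# minimal hand-built annotation: one coding gene, configurable lncRNA
one_gene_ref <- function(gstart = 1000L, gend = 3000L, strand = "+",
                         exon_breaks = NULL) {
  if (is.null(exon_breaks)) {
    ex <- data.table::data.table(transcript_id = "G1.1", chrom = "chr1",
                                 start = gstart, end = gend, strand = strand)
  } else {
    ex <- data.table::data.table(transcript_id = "G1.1", chrom = "chr1",
                                 start = exon_breaks$start,
                                 end = exon_breaks$end, strand = strand)
  }
  annotation_set(
    data.table::data.table(transcript_id = "G1.1", gene_id = "G1",
                           chrom = "chr1", start = min(ex$start),
                           end = max(ex$end), strand = strand,
                           class_code = "=", biotype = "coding"),
    ex)
}

one_lnc <- function(start, end, strand, id = "L1", class_code = "u") {
  annotation_set(
    data.table::data.table(transcript_id = id, gene_id = id, chrom = "chr1",
                           start = start, end = end, strand = strand,
                           class_code = class_code, biotype = "unknown"),
    data.table::data.table(transcript_id = id, chrom = "chr1",
                           start = start, end = end, strand = strand))
}

# expression table with one row per feature at fixed values
flat_expr <- function(ids, values, n_samples = 4L) {
  m <- matrix(rep(values, each = n_samples), nrow = length(ids),
              byrow = TRUE,
              dimnames = list(ids, sprintf("s%d", seq_len(n_samples))))
  cond <- rep(c("a", "b"), each = 2, length.out = n_samples)
  expression_table(m, data.table::data.table(
    sample_id = colnames(m), condition = cond, timepoint = 1L,
    fraction = "total",
    replicate = as.integer(stats::ave(seq_len(n_samples), cond,
                                      FUN = seq_along))))
}
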