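#!/usr/bin/env Rscript
# Run the lncRNA selection cascade over the simulated transcriptome:
# class codes (keep u/x/i) -> length >= 150 nt and FPKM_max >= 1 ->
# remove protein-coding evidence (homology hit or positive coding-potential
# score) -> remove sense-overlapping transcripts.  Writes the filter
# accounting and the lncRNA annotation under results/identify/.

library(natlnc)

fix <- function(f) file.path("results/fixtures", f)
anno <- read_annotation(fix("annotation.gtf"))
ref <- read_annotation(fix("reference.gtf"), default_biotype = "coding")
expr <- read_expression_table(fix("expression.tsv"), fix("samples.tsv"))
hits <- read_homology_hits(fix("hits.tsv"))
seqs <- read_transcript_seqs(fix("transcripts.fa"))

id <- identify_lncrnas(anno, expr, hits, seqs, ref)

dir.create("results/identify", showWarnings = FALSE, recursive = TRUE)
write_annotation(id$lncrnas, "results/identify/lncrna.gtf")
data.table::fwrite(id$report$stages, "results/identify/filter_report.tsv",
                   sep = "\t")
data.table::fwrite(id$report$removals, "results/identify/removals.tsv",
                   sep = "\t")
data.table::fwrite(id$assessment, "results/identify/coding_assessment.tsv",
                   sep = "\t")

message("Filter cascade:")
for (i in seq_len(nrow(id$report$stages)))
  message(sprintf("  %-17s %4d in  %4d removed  %4d out",
                  id$report$stages$stage[i], id$report$stages$n_in[i],
                  id$report$stages$n_removed[i], id$report$stages$n_out[i]))
message("Identified ", n_transcripts(id$lncrnas), " lncRNAs")

truth <- data.table::fread(fix("truth.tsv"))
planted <- truth[grepl("^LNC_", transcript_id), transcript_id]
message("Planted lncRNAs recovered: ",
        sum(planted %in% id$lncrnas$transcripts$transcript_id), "/",
        length(planted))
message("Planted decoys removed: ",
        sum(truth[role == "decoy", transcript_id] %in%
            id$report$removals$transcript_id), "/",
        sum(truth$role == "decoy"))
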