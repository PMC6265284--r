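#!/usr/bin/env Rscript
# Classify each identified lncRNA against the coding annotation into
# overlapping / divergent / convergent NATs, incRNAs and lincRNAs, and
# cross-check the indexed classifier against the brute-force oracle.

library(natlnc)

lncs <- read_annotation("results/identify/lncrna.gtf")
ref <- read_annotation("results/fixtures/reference.gtf",
                       default_biotype = "coding")

cls <- classify_all(lncs, ref, window_bp = 1000)

dir.create("results/classify", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(cls$records, "results/classify/classification.tsv",
                   sep = "\t")
data.table::fwrite(
  data.table::data.table(lnc_class = names(cls$summary),
                         n = as.integer(cls$summary)),
  "results/classify/class_summary.tsv", sep = "\t")
out <- lncs
out$transcripts[, lnc_class :=
  setNames(cls$records$lnc_class, cls$records$transcript_id)[transcript_id]]
write_annotation(out, "results/classify/lncrna_classified.gtf")

message("Class summary:")
for (cl in names(cls$summary))
  message(sprintf("  %-16s %d", cl, cls$summary[[cl]]))

agree <- vapply(cls$records$transcript_id, function(tid) {
  bf <- brute_force_classify(subset_annotation(lncs, tid), ref)
  identical(bf$lnc_class, cls$records[transcript_id == tid, lnc_class])
}, logical(1))
message("Brute-force oracle agreement: ", sum(agree), "/", length(agree))

truth <- data.table::fread("results/fixtures/truth.tsv")
m <- merge(cls$records, truth, by = "transcript_id")
message("Planted-class recovery: ", sum(m$lnc_class == m$role), "/", nrow(m))
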