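#!/usr/bin/env Rscript
# Fraction-enrichment calls (P < 0.05 and fold-change >= 2 on FPKM) for the
# identified lncRNAs, differential expression between the two most distant
# conditions, and the k-means row ordering used for heatmap display.

library(natlnc)

fix <- function(f) file.path("results/fixtures", f)
expr <- read_expression_table(fix("expression.tsv"), fix("samples.tsv"))
lncs <- read_annotation("results/identify/lncrna.gtf")
ids <- intersect(rownames(expr$values), lncs$transcripts$transcript_id)
lnc_expr <- structure(list(values = expr$values[ids, , drop = FALSE],
                           samples = expr$samples),
                      class = "ExpressionTable")

dir.create("results/expression", showWarnings = FALSE, recursive = TRUE)

fe <- fraction_enrichment(lnc_expr, "fraction_a", "fraction_b",
                          alpha = 0.05, fc_min = 2)
data.table::fwrite(fe$calls, "results/expression/fraction_enrichment.tsv",
                   sep = "\t")
message("Fraction enrichment (a = poly(A)+-like, b = poly(A)--like):")
message(sprintf("  enriched_a=%d enriched_b=%d ns=%d",
                fe$summary[["enriched_a"]], fe$summary[["enriched_b"]],
                fe$summary[["ns"]]))
truth <- data.table::fread(fix("truth.tsv"))
planted <- truth[enriched == "fraction_a" & transcript_id %in% ids,
                 transcript_id]
called <- fe$calls[status == "enriched_a", feature_id]
message("  planted enriched recovered: ",
        sum(planted %in% called), "/", length(planted))

sheet <- expr$samples
ctr <- contrast(sheet[condition == "cond_01", sample_id],
                sheet[condition == "cond_09", sample_id],
                label = "cond_01_vs_cond_09")
de <- differential_call(lnc_expr, ctr)
data.table::fwrite(de, "results/expression/differential_cond01_vs_cond09.tsv",
                   sep = "\t")
message("Differential lncRNAs (cond_01 vs cond_09): ",
        sum(de$status != "ns"), "/", nrow(de))

called_any <- fe$calls[status != "ns", feature_id]
if (length(called_any) >= 6) {
  km <- kmeans_order(lnc_expr$values[called_any,
          sheet[fraction == "total", sample_id], drop = FALSE],
        k = 6, seed = 1)
  data.table::fwrite(
    data.table::data.table(feature_id = km$order,
                           cluster = as.integer(km$cluster[km$order])),
    "results/expression/heatmap_order.tsv", sep = "\t")
  message("Heatmap row order written for ", length(km$order),
          " called lncRNAs (k = 6)")
}
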