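#!/usr/bin/env Rscript
# Neighbor-pair co-expression: build CCO/CCD/CCC/NCO/NCD/NCC/LC pairs,
# correlate each pair's FPKM profiles over the condition samples, compare
# the category distributions with one-tailed Mann-Whitney tests, and
# extract the concordant overlapping-NAT set (pcc > 0.6).

library(natlnc)

fix <- function(f) file.path("results/fixtures", f)
expr <- read_expression_table(fix("expression.tsv"), fix("samples.tsv"))
ref <- read_annotation(fix("reference.gtf"), default_biotype = "coding")
lncs <- read_annotation("results/identify/lncrna.gtf")
records <- data.table::fread("results/classify/classification.tsv")

pairs <- assign_pairs(records, ref, window_bp = 1000, lncs = lncs)
recs <- pair_correlations(pairs, expr, ref, min_fpkm_max = 1,
  samples = expr$samples[fraction == "total", sample_id])

dir.create("results/coexpression", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(recs, "results/coexpression/pairs.tsv", sep = "\t")

message("Scored pairs per category (median pcc):")
summ <- recs[excluded == FALSE,
             list(n = .N, median_pcc = round(median(pcc), 3)),
             by = pair_type][order(pair_type)]
for (i in seq_len(nrow(summ)))
  message(sprintf("  %-4s n=%3d  median pcc=%6.3f", summ$pair_type[i],
                  summ$n[i], summ$median_pcc[i]))
data.table::fwrite(summ, "results/coexpression/category_summary.tsv",
                   sep = "\t")

present <- sort(unique(recs[excluded == FALSE, pair_type]))
comps <- data.table::rbindlist(lapply(present, function(a)
  data.table::rbindlist(lapply(setdiff(present, a), function(b) {
    cmp <- compare_pair_categories(recs, a, b)
    data.table::data.table(cat_a = a, cat_b = b, p_value = cmp$p_value,
                           median_a = cmp$summary$median[1],
                           median_b = cmp$summary$median[2])
  }))))
data.table::fwrite(comps, "results/coexpression/category_comparison.tsv",
                   sep = "\t")
key <- comps[cat_a == "NCO" & cat_b == "CCO"]
if (nrow(key))
  message(sprintf(
    "NCO vs CCO: median %0.3f vs %0.3f, one-tailed Mann-Whitney p = %.3g",
    key$median_a, key$median_b, key$p_value))

conc <- concordant_set(recs, pcc_min = 0.6, pair_type = "NCO")
data.table::fwrite(conc, "results/coexpression/concordant_pairs.tsv",
                   sep = "\t")
message("Concordant NCO pairs (pcc > 0.6): ", nrow(conc), "/",
        recs[pair_type == "NCO" & excluded == FALSE, .N])
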