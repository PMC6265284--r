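#!/usr/bin/env Rscript
# Build the simulated study: a synthetic genome with 50 coding genes, 10
# planted lncRNAs of each class (overlapping/divergent/convergent NATs,
# lincRNAs, incRNAs), 10 coding-potential decoys, 5 coding-coding pairs per
# geometry, and an expression design of 9 conditions x 3 replicates plus a
# two-fraction assay.  Everything downstream reads from results/fixtures/.

library(natlnc)

out <- "results/fixtures"
bundle <- make_fixtures(out, seed = 7, scale = "default")

tt <- bundle$truth$transcripts
message("Wrote synthetic input bundle to ", out)
message("  transcripts: ", nrow(tt))
message("  planted roles: ",
        paste(sprintf("%s=%d", names(table(tt$role)), table(tt$role)),
              collapse = " "))
message("  planted fraction-enriched lncRNAs: ",
        sum(tt$enriched == "fraction_a"))
message("  planted pair correlations: NCO rho=", bundle$cfg$rho_nco,
        ", others rho=", bundle$cfg$rho_other)
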