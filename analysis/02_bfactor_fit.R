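#!/usr/bin/env Rscript
# Fit the uniform spring constant by normalizing theoretical against
# experimental B-factors, and report the residue-by-residue comparison.
# Run analysis/01_simulate.R first.

library(gnmunfold)

st <- read_structure("results/synthetic_fab.pdb")
cmp <- bfactor_comparison(st)
utils::write.table(cmp$table, "results/bfactor_comparison.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Fitted spring constant gamma =", round(cmp$gamma, 3), "kBT/A^2",
    "(planted truth: 0.751)\n")
cat("Pearson correlation computed vs experimental B-factors =",
    round(cmp$correlation, 3), "\n")
cat("Per-residue table written to results/bfactor_comparison.tsv\n")
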