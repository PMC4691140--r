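#!/usr/bin/env Rscript
# Pairwise flexibility: MSFID over all non-zero modes, written as a dense
# grid for heatmap rendering, with within-domain means. Run
# analysis/01_simulate.R first.

library(gnmunfold)

st <- read_structure("results/synthetic_fab.pdb")
fab <- make_synthetic_fab(strand_len = 7L, seed = 1L)
dec <- decompose(build_kirchhoff(st))
gamma <- bfactor_comparison(st, decomp = dec)$gamma
msfid <- msfid_matrix(dec, gamma = gamma)
write_matrix_grid(msfid, "results/msfid_grid.tsv")

idx <- resolve_annotation(fab$annotation, st)
ds <- domain_statistics(mode_subset_msf(dec, gamma = gamma), msfid, idx)
utils::write.table(ds, "results/domain_statistics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(ds, digits = 4)
cat("Higher within-domain MSFID marks the more flexible domains;",
    "the loosely packed constant-like domains should lead.\n")
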