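#!/usr/bin/env Rscript
# Full analysis of a real Fab crystal structure. The McPC603 Fab entry is
# not redistributable with this repository; pass a local PDB path:
#
#   Rscript analysis/06_mcpc603.R /path/to/fab.pdb [light_chain heavy_chain]
#
# Candidate PDB entries for the phosphocholine-binding antibody McPC603
# Fab are discussed in the README.

library(gnmunfold)

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  cat("No PDB path supplied; nothing to do.\n",
      "Usage: Rscript analysis/06_mcpc603.R <fab.pdb> [L H]\n")
  quit(status = 0)
}
light <- if (length(args) >= 2L) args[2] else "L"
heavy <- if (length(args) >= 3L) args[3] else "H"

st <- read_structure(args[1], chain_filter = c(light, heavy))
ann <- read_annotation(system.file("extdata", "mcpc603_domains.txt",
                                   package = "gnmunfold"))
ann$chain <- ifelse(ann$chain == "L", light, heavy)
rep <- analyze_fab(st, annotation = ann, T0_kelvin = 300)
print(rep)
dir.create("results", showWarnings = FALSE)
write_trajectory(rep$trajectory, "results/mcpc603_unfolding.tsv")
utils::write.table(rep$domain_stats, "results/mcpc603_domain_stats.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
if (!is.null(rep$bfactors)) {
  utils::write.table(rep$bfactors$table, "results/mcpc603_bfactors.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
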