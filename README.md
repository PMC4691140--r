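# gnmunfold

Coarse-grained elastic-network analysis of protein structures, built for
the question antibody engineers keep asking: where is a Fab fragment
mobile, where is it flexible, and in what order does it fall apart when
heated?

The package implements the Gaussian network model (GNM) over C-alpha
sites and an iterative contact-breaking unfolding simulator on top of
it, together with synthetic structure generators carrying planted ground
truth so the entire pipeline is testable offline.

## The model

Residue pairs within a cutoff `r_c` (7.3 Å by default) are joined by
springs of uniform force constant γ. The Kirchhoff matrix Γ (graph
Laplacian of the contact map) determines all fluctuation statistics via
its pseudoinverse:

- cross-correlations  ⟨ΔR_i·ΔR_j⟩ = (k_BT/γ) [Γ⁻¹]_ij
- mean-square fluctuation (MSF)  ⟨(ΔR_i)²⟩ = (k_BT/γ) [Γ⁻¹]_ii
- B-factors  B_i = (8π²/3) ⟨(ΔR_i)²⟩
- mean-square fluctuation in the internal distance (MSFID)
  ⟨(ΔR_ij)²⟩ = (3k_BT/γ) ([Γ⁻¹]_ii + [Γ⁻¹]_jj − 2[Γ⁻¹]_ij)

γ is fitted by normalizing theoretical against experimental B-factors.
MSF over the six slowest modes profiles collective mobility; MSFID maps
pairwise flexibility. Unfolding is simulated by repeatedly rupturing the
breakable contact with the largest MSFID and re-solving the network,
which converts a crystal structure into an ordered rupture sequence, an
LNNC (loss number of native contacts) versus reduced-temperature curve
with cooperative jumps, and per-domain melt temperatures. See the
methods vignette (`vignettes/gnm-unfolding.Rmd`) for assumptions,
conventions and limitations.

## Worked example

A synthetic two-chain Fab-like structure (four β-sandwich domains; the
constant-like domains CL/CH deliberately packed more loosely than the
variable-like VL/VH) with pseudo-experimental B-factors planted at
γ = 0.751 kBT/Å² and 30 % noise:

```r
library(gnmunfold)

fab <- make_synthetic_fab(strand_len = 7, seed = 1)
st  <- make_pseudo_experimental_bfactors(fab$structure,
                                         true_gamma = 0.751,
                                         noise_sd_fraction = 0.3, seed = 2)
rep <- analyze_fab(st, annotation = fab$annotation,
                   snapshot_lnnc = integer(0), min_jump_size = 10)
rep
#> GNM analysis report: synthetic_fab_seed1
#>   sites: 250  contacts: 646  cutoff: 7.3 A
#>   fitted gamma: 0.7428 kBT/A^2; B-factor correlation: 0.689
#>   unfolding order: CH -> CL -> VH -> VL
#>    constant melt: 459.7 K
#>    variable melt: 625.2 K
rep$domain_stats
#>   label n_sites  mean_msf mean_msfid
#> 1    VL      57 0.9383118   2.494456
#> 2    CL      57 1.1266812   6.438852
#> 3    VH      57 0.8877355   2.417204
#> 4    CH      57 1.1504349   6.162719
```

Reading the output: the spring-constant fit recovers the planted
0.751 kBT/Å² to 1 % despite 30 % noise; the deliberately loosened
constant-like domains show the larger within-domain MSFID (flexibility)
and the larger slow-mode MSF (mobility), unfold first, and melt at a
lower reconstructed temperature (T0 = 300 K assigned to the first
rupture) than the variable-like domains — the planted stability
ordering, recovered end to end.

The numbered drivers under `analysis/` run the same chain stepwise and
write tables under `results/`: `01_simulate.R` (structures and native
contact map), `02_bfactor_fit.R` (γ and the per-residue B-factor
comparison), `03_slow_modes.R` (six-mode MSF profile),
`04_msfid.R` (flexibility grid and domain statistics),
`05_unfold.R` (rupture events, snapshots, jumps, melting summary).

## Analysing a real Fab

`analysis/06_mcpc603.R` applies the identical pipeline to a crystal
structure you supply:

```sh
Rscript analysis/06_mcpc603.R /path/to/fab.pdb L H
```

The packaged annotation (`inst/extdata/mcpc603_domains.txt`) carries the
conventional Fab domain split and the six CDR loops (L1 26–37, L2 56–61,
L3 97–102, H1 28–32, H2 50–58, H3 102–109) in author numbering. For the
phosphocholine-binding antibody McPC603, candidate PDB entries include
1MCP and 2MCP (the Fab has been deposited in several refinements); this
repository does not assert which deposition underlies any particular
published analysis, and ships no coordinates — supply whichever entry
you mean to study.

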