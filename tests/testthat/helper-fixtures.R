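# Shared fixtures: hand-written PDB text and random network generators.

# one ATOM record in fixed-column PDB format
pdb_atom_line <- function(serial, resno, chain, x, y, z, b = 0,
                          occ = 1, alt = " ", resname = "ALA",
                          icode = " ") {
  sprintf("ATOM  %5d  CA %1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, alt, resname, chain, resno, icode, x, y, z, occ, b)
}

# three-residue PDB (chains A, H, A; B-factors 10/20/30)
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    pdb_atom_line(1L, 1L, "A", 0, 0, 0, b = 10),
    pdb_atom_line(2L, 2L, "H", 3.8, 0, 0, b = 20),
    pdb_atom_line(3L, 3L, "A", 7.6, 0, 0, b = 30),
    "END"
  ), path)
  path
}

# random connected-ish point cloud structure: a jittered chain folded at
# random in space; guaranteed chain-adjacent connectivity
random_structure <- function(n, seed) {
  gnmunfold:::with_local_seed(seed, {
    step <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
    step <- step / sqrt(rowSums(step^2)) * 3.8
    xyz <- rbind(0, apply(step, 2, cumsum))
    new_cg_structure(gnmunfold:::sites_from_xyz(xyz),
                     source_label = sprintf("random_chain_seed%d", seed))
  })
}

# random contact topology on n sites: a chain backbone plus extra random
# pairs (not necessarily geometric); for spectral/graph property tests
random_topology <- function(n, seed, extra = n) {
  gnmunfold:::with_local_seed(seed, {
    backbone <- cbind(1:(n - 1), 2:n)
    pairs <- cbind(sample.int(n, extra, replace = TRUE),
                   sample.int(n, extra, replace = TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    kirchhoff_from_contacts(n, rbind(backbone, pairs))
  })
}

# random, possibly disconnected topology (no backbone)
random_sparse_topology <- function(n, seed, m = n) {
  gnmunfold:::with_local_seed(seed, {
    pairs <- cbind(sample.int(n, m, replace = TRUE),
                   sample.int(n, m, replace = TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    kirchhoff_from_contacts(n, pairs)
  })
}

# dense Moore-Penrose pseudoinverse oracle (independent of the mode path)
pinv_oracle <- function(K) MASS::ginv(K, tol = 1e-10)
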