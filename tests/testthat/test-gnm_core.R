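test_that("Kirchhoff matrices follow the contact rule with inclusive cutoff", {
  two <- new_cg_structure(data.frame(
    chain = "A", resno = 1:2, insert = "", resid = "ALA",
    x = c(0, 5), y = 0, z = 0, bfactor = NA_real_))
  k <- build_kirchhoff(two, cutoff_rc = 7.3)
  expect_equal(k$matrix, matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)

  # boundary is inclusive: exactly rc apart is a contact
  onrc <- new_cg_structure(data.frame(
    chain = "A", resno = 1:2, insert = "", resid = "ALA",
    x = c(0, 7.3), y = 0, z = 0, bfactor = NA_real_))
  expect_equal(nrow(build_kirchhoff(onrc, 7.3)$contacts), 1L)

  # three collinear sites 6 A apart: only consecutive pairs touch
  tri <- make_linear_chain(3, spacing = 6)
  k3 <- build_kirchhoff(tri, 7.3)
  expect_equal(k3$contacts, cbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(k3$matrix,
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3,
                      byrow = TRUE), ignore_attr = TRUE)

  one <- new_cg_structure(data.frame(
    chain = "A", resno = 1L, insert = "", resid = "ALA",
    x = 0, y = 0, z = 0, bfactor = NA_real_))
  expect_error(build_kirchhoff(one), "degenerate")
})

test_that("every built Kirchhoff matrix is exactly symmetric with zero row sums", {
  for (seed in 1:10) {
    st <- random_structure(25L, seed)
    K <- build_kirchhoff(st)$matrix
    expect_identical(K, t(K))
    expect_true(all(rowSums(K) == 0))
    expect_true(min(eigen(K, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-10)
  }
})

test_that("path-graph spectra match the closed form 4 sin^2(k pi / 2N)", {
  for (n in 3:50) {
    d <- decompose(build_kirchhoff(make_linear_chain(n)))
    expected <- 4 * sin((0:(n - 1)) * pi / (2 * n))^2
    expect_equal(d$values, expected, tolerance = 1e-10)
  }
})

test_that("zero-mode count equals the number of connected components", {
  two_comp <- kirchhoff_from_contacts(4L, rbind(c(1, 2), c(3, 4)))
  expect_equal(length(decompose(two_comp)$zero_modes), 2L)

  for (seed in 1:30) {
    topo <- random_sparse_topology(20L, seed, m = 14L)
    g <- igraph::graph_from_edgelist(topo$contacts, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, topo$n_sites - igraph::vcount(g)))
    expect_equal(length(decompose(topo)$zero_modes),
                 igraph::components(g)$no)
  }
})

test_that("decomposition is orthonormal and reconstructs the matrix", {
  for (seed in 1:5) {
    topo <- random_topology(20L, seed)
    d <- decompose(topo)
    U <- d$vectors
    expect_lt(max(abs(crossprod(U) - diag(topo$n_sites))), 1e-10)
    expect_lt(max(abs(U %*% diag(d$values) %*% t(U) - topo$matrix)),
              1e-8)
    # deterministic sign convention
    for (k in seq_along(d$values)) {
      lead <- which(abs(U[, k]) > 1e-8)[1]
      expect_gt(U[lead, k], 0)
    }
  }
})

test_that("fluctuation statistics match the dense pseudoinverse oracle", {
  for (seed in 1:20) {
    n <- 10L + (seed %% 21L)
    topo <- random_topology(n, seed)
    d <- decompose(topo)
    G <- pinv_oracle(topo$matrix)
    gam <- 0.751
    expect_equal(residue_msf(d, gamma = gam), diag(G) / gam,
                 tolerance = 1e-8)
    expect_equal(cross_correlation(d, gamma = gam), G / gam,
                 tolerance = 1e-8, ignore_attr = TRUE)
    dg <- diag(G)
    msfid_ref <- (3 / gam) * (outer(dg, dg, "+") - 2 * G)
    diag(msfid_ref) <- 0
    expect_equal(msfid_matrix(d, gamma = gam), msfid_ref,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("two-site network reproduces hand-computed fluctuations", {
  topo <- kirchhoff_from_contacts(2L, cbind(1L, 2L))
  d <- decompose(topo)
  expect_equal(residue_msf(d, gamma = 1), c(0.25, 0.25))
  cc <- cross_correlation(d, gamma = 1)
  expect_equal(cc[1, 2], -0.25)
  expect_equal(diag(cc), residue_msf(d))
  # 3 * (0.25 + 0.25 + 2 * 0.25) = 3
  expect_equal(msfid_matrix(d)[1, 2], 3)
  expect_equal(diag(msfid_matrix(d)), c(0, 0))
})

test_that("cross-correlations obey Cauchy-Schwarz and MSFID is a valid squared distance", {
  for (seed in c(2, 7)) {
    topo <- random_topology(18L, seed)
    d <- decompose(topo)
    cc <- cross_correlation(d)
    msf <- residue_msf(d)
    bound <- sqrt(outer(msf, msf))
    expect_true(all(abs(cc) <= bound + 1e-12))
    m <- msfid_matrix(d)
    expect_identical(m, t(m))
    expect_true(all(m >= 0))
    expect_equal(diag(m), rep(0, topo$n_sites))
    # rank order of entries does not depend on gamma
    m2 <- msfid_matrix(d, gamma = 3.7)
    ut <- upper.tri(m)
    expect_equal(rank(m[ut]), rank(m2[ut]))
  }
})

test_that("sites in different components have unbounded distance fluctuation", {
  topo <- kirchhoff_from_contacts(4L, rbind(c(1, 2), c(3, 4)))
  m <- msfid_matrix(decompose(topo))
  expect_true(is.infinite(m[1, 3]) && is.infinite(m[2, 4]))
  expect_true(is.finite(m[1, 2]) && is.finite(m[3, 4]))
})

test_that("Debye-Waller conversion is the exact 8 pi^2 / 3 scale", {
  expect_equal(theoretical_bfactors(0), 0)
  expect_equal(theoretical_bfactors(3 / (8 * pi^2)), 1.0)
  msf <- c(0.1, 0.5, 2)
  expect_equal(theoretical_bfactors(5 * msf), 5 * theoretical_bfactors(msf))
  expect_error(theoretical_bfactors(-1), "non-negative")
})

test_that("gamma fit recovers exact scales and reports scale-free correlation", {
  topo <- random_topology(30L, seed = 5)
  shape <- theoretical_bfactors(residue_msf(decompose(topo), gamma = 1))
  expect_equal(fit_gamma(shape, shape / 0.5)$gamma, 0.5)
  expect_equal(fit_gamma(shape, shape / 0.5, method = "lsq")$gamma, 0.5)
  f1 <- fit_gamma(shape, shape / 0.751)
  f2 <- fit_gamma(shape, 2 * shape / 0.751)
  expect_equal(f2$gamma, f1$gamma / 2)
  expect_equal(f1$correlation, 1.0)
  expect_error(fit_gamma(shape, -shape), "positive mean")
})

test_that("slow-mode MSF is a term-wise lower bound that saturates at all modes", {
  topo <- random_topology(25L, seed = 9)
  d <- decompose(topo)
  full <- residue_msf(d)
  n_nz <- length(d$values) - length(d$zero_modes)
  expect_equal(mode_subset_msf(d, k_slowest = n_nz), full)
  for (k in c(1L, 6L, 12L)) {
    expect_true(all(mode_subset_msf(d, k_slowest = k) <= full + 1e-12))
  }
  expect_error(mode_subset_msf(d, k_slowest = n_nz + 1L), "invalid mode")
  expect_error(residue_msf(d, mode_subset = d$zero_modes[1]),
               "zero mode")
})

test_that("fluctuation statistics are equivariant under site relabeling", {
  st <- random_structure(15L, seed = 4)
  perm <- gnmunfold:::with_local_seed(42, sample.int(15L))
  st_p <- new_cg_structure(
    transform(st$sites[perm, ], resno = 1:15),
    source_label = "permuted")
  d <- decompose(build_kirchhoff(st))
  d_p <- decompose(build_kirchhoff(st_p))
  expect_equal(residue_msf(d_p), residue_msf(d)[perm], tolerance = 1e-9)
  expect_equal(msfid_matrix(d_p), msfid_matrix(d)[perm, perm],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("residue fluctuations agree with an independent network-model implementation", {
  st <- make_beta_sandwich(strand_len = 5L, seed = 7)
  f <- tempfile(fileext = ".pdb")
  write_structure(st, f)
  ref <- suppressWarnings(
    bio3d::gnm(bio3d::read.pdb(f), cutoff = 7.3)$fluctuations)
  ours <- residue_msf(decompose(build_kirchhoff(read_structure(f))))
  ratio <- ref / ours
  expect_gt(stats::cor(ref, ours), 0.999999)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})
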