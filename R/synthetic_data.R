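# Seeded randomness without touching global RNG state: every generator
# draws from its own seed and restores .Random.seed on exit.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# data.frame of sites from a coordinate matrix
sites_from_xyz <- function(xyz, chain = "A", resno = NULL) {
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  data.frame(chain = rep(chain, length.out = n), resno = as.integer(resno),
             insert = "", resid = "ALA",
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             bfactor = NA_real_, stringsAsFactors = FALSE)
}

#' Generate a straight C-alpha chain
#'
#' Collinear sites on one chain, numbered 1..n. The Kirchhoff matrix of
#' such a chain (at a cutoff below twice the spacing) is the path-graph
#' Laplacian, whose spectrum is known in closed form -- the package's
#' analytic test bed.
#'
#' @param n Number of sites (>= 2).
#' @param spacing Distance between consecutive sites in Angstrom
#'   (default 3.8, the C-alpha virtual bond length).
#' @return A `cg_structure`.
#' @export
make_linear_chain <- function(n, spacing = 3.8) {
  if (n < 2L) stop("degenerate input: a chain needs at least 2 sites")
  if (spacing <= 0) stop("spacing must be positive")
  xyz <- cbind((seq_len(n) - 1L) * spacing, 0, 0)
  new_cg_structure(sites_from_xyz(xyz),
                   source_label = sprintf("linear_chain_n%d", n))
}

# compact globule: a chain snaking boustrophedon through a cubic lattice,
# so the chain is connected at `spacing` and laterally packed at `spacing`
snake_globule <- function(n, spacing = 3.8) {
  side <- ceiling(n^(1 / 3))
  pts <- matrix(0, n, 3L)
  k <- 1L
  dirx <- 1L
  for (iz in seq_len(side)) {
    ys <- if (iz %% 2L == 1L) seq_len(side) else rev(seq_len(side))
    for (iy in ys) {
      xs <- if (dirx == 1L) seq_len(side) else rev(seq_len(side))
      for (ix in xs) {
        if (k > n) break
        pts[k, ] <- c(ix, iy, iz)
        k <- k + 1L
      }
      dirx <- -dirx
      if (k > n) break
    }
    if (k > n) break
  }
  pts * spacing
}

# insert interpolated sites so no consecutive pair is farther than max_step
densify_path <- function(xyz, max_step = 3.8) {
  out <- xyz[1L, , drop = FALSE]
  for (k in 2L:nrow(xyz)) {
    a <- xyz[k - 1L, ]; b <- xyz[k, ]
    d <- sqrt(sum((b - a)^2))
    if (d > max_step) {
      nseg <- ceiling(d / max_step)
      for (s in seq_len(nseg - 1L)) {
        out <- rbind(out, a + (b - a) * s / nseg)
      }
    }
    out <- rbind(out, b)
  }
  out
}

# count internal contacts excluding chain-adjacent pairs
internal_nonadjacent_contacts <- function(xyz, cutoff = 7.3) {
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  sum(adj[upper.tri(adj)] &
        (abs(row(d) - col(d)) > 1L)[upper.tri(adj)])
}

#' Generate a two-domain network with a planted weak domain
#'
#' Two compact globular domains of equal size joined by a short extended
#' linker, on one chain. Domain A (the first) is weakened: its globule is
#' dilated about its centroid until only the requested fraction of its
#' internal non-adjacent contacts (at the 7.3 A rule) survives, so the
#' contact cutoff remains the single source of topology. Domain B keeps
#' its full contact density. Seeded coordinate jitter breaks the lattice
#' symmetry and makes realizations differ across seeds while remaining
#' bit-reproducible for a fixed seed.
#'
#' @param n_per_domain Sites per domain (>= 8 recommended).
#' @param weak_contact_fraction Fraction in (0, 1] of domain A's internal
#'   non-adjacent contacts to retain (1 means A and B are generated
#'   identically up to jitter).
#' @param seed Integer seed; the generator never touches global RNG state.
#' @param spacing Chain step in Angstrom.
#' @param jitter_sd Coordinate jitter standard deviation in Angstrom.
#' @return List with `structure` (a `cg_structure`), `annotation` (a
#'   `domain_annotation` labelling domains `A` and `B`), and `truth`
#'   (list: `weak_label`, `dilation`, per-domain site index vectors).
#' @export
make_two_domain_network <- function(n_per_domain, weak_contact_fraction,
                                    seed, spacing = 3.8,
                                    jitter_sd = 0.3) {
  stopifnot(n_per_domain >= 4L,
            weak_contact_fraction > 0, weak_contact_fraction <= 1)
  with_local_seed(seed, {
    base <- snake_globule(n_per_domain, spacing)
    jit <- function(x) x + matrix(stats::rnorm(length(x), 0, jitter_sd),
                                  nrow(x), 3L)
    A0 <- jit(base)
    B <- jit(base)

    dilate <- function(xyz, f) {
      ctr <- colMeans(xyz)
      sweep(sweep(xyz, 2L, ctr) * f, 2L, ctr, "+")
    }
    f_used <- 1
    A <- A0
    if (weak_contact_fraction < 1) {
      c0 <- internal_nonadjacent_contacts(A0)
      target <- round(weak_contact_fraction * c0)
      lo <- 1; hi <- 1.9   # above ~1.92 the 3.8 A backbone step exceeds 7.3
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (internal_nonadjacent_contacts(dilate(A0, mid)) > target) {
          lo <- mid
        } else hi <- mid
      }
      f_used <- hi
      A <- dilate(A0, f_used)
      # verify the chain stayed connected at the cutoff
      step_d <- sqrt(rowSums((A[-1L, , drop = FALSE] -
                                A[-nrow(A), , drop = FALSE])^2))
      if (any(step_d > 7.3)) {
        stop("generation error: weak-domain dilation disconnected the chain")
      }
    }

    # place B well away from A and bridge with an extended linker
    span <- max(stats::dist(A))
    B <- sweep(B, 2L, c(span + 14, 0, 0), "+")
    linker <- densify_path(rbind(A[nrow(A), ], B[1L, ]), max_step = spacing)
    linker <- linker[-c(1L, nrow(linker)), , drop = FALSE]
    xyz <- rbind(A, linker, B)

    idx_A <- seq_len(n_per_domain)
    idx_link <- n_per_domain + seq_len(nrow(linker))
    idx_B <- n_per_domain + nrow(linker) + seq_len(n_per_domain)
    st <- new_cg_structure(
      sites_from_xyz(xyz),
      source_label = sprintf("two_domain_n%d_f%.2f_seed%d",
                             n_per_domain, weak_contact_fraction,
                             as.integer(seed)))
    ann <- domain_annotation(
      label = c("A", "B"), chain = c("A", "A"),
      start = c(min(idx_A), min(idx_B)),
      end = c(max(idx_A), max(idx_B)))
    list(structure = st, annotation = ann,
         truth = list(weak_label = "A", dilation = f_used,
                      idx_A = idx_A, idx_B = idx_B,
                      idx_linker = idx_link))
  })
}

# one idealized beta-sandwich domain: two stacked antiparallel sheets
sandwich_xyz <- function(strand_len = 8L, n_strands = 4L, rise = 4.8,
                         strand_sep = 5.0, sheet_sep = 9.0) {
  sheet <- function(z) {
    pts <- NULL
    for (s in seq_len(n_strands)) {
      xs <- (seq_len(strand_len) - 1L) * rise
      if (s %% 2L == 0L) xs <- rev(xs)
      pts <- rbind(pts, cbind(xs, (s - 1L) * strand_sep, z))
    }
    pts
  }
  top <- sheet(0)
  bottom <- sheet(sheet_sep)
  # walk the second sheet in reverse strand order so the crossover is short
  bottom <- bottom[rev(seq_len(nrow(bottom))), , drop = FALSE]
  # bridge only the inter-sheet crossover; strand steps stay intact
  densify_path(rbind(top, bottom), max_step = 6.8)
}

#' Generate an idealized beta-sandwich domain
#'
#' Two stacked four-strand antiparallel sheets traced by a single chain,
#' with a 4.8 A per-residue rise and 5.0 A inter-strand spacing -- a
#' qualitative stand-in for an immunoglobulin-fold domain, useful as a
#' Fab-like synthetic fixture. Geometry parameters are fixture choices,
#' not measurements.
#'
#' @param strand_len Residues per strand.
#' @param n_strands Strands per sheet.
#' @param jitter_sd Seeded coordinate jitter (A); breaks the exact lattice
#'   symmetry so eigenmodes are non-degenerate.
#' @param seed Integer seed for the jitter.
#' @param dilation Scale factor about the centroid (> 1 loosens the
#'   domain's packing; used to plant stability differences).
#' @return A `cg_structure`.
#' @export
make_beta_sandwich <- function(strand_len = 8L, n_strands = 4L,
                               jitter_sd = 0.25, seed = 1L,
                               dilation = 1) {
  xyz <- sandwich_xyz(strand_len, n_strands)
  if (dilation != 1) {
    ctr <- colMeans(xyz)
    xyz <- sweep(sweep(xyz, 2L, ctr) * dilation, 2L, ctr, "+")
  }
  with_local_seed(seed, {
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sd),
                        nrow(xyz), 3L)
    new_cg_structure(sites_from_xyz(xyz),
                     source_label = sprintf("beta_sandwich_seed%d",
                                            as.integer(seed)))
  })
}

#' Generate a synthetic two-chain Fab-like structure
#'
#' Two chains (`L` and `H`), each consisting of a variable-like and a
#' constant-like beta-sandwich domain joined by an extended linker, with
#' the two chains packed side by side. The constant-like domains are
#' dilated by `loose_constant`, planting the lower packing density (and
#' hence higher flexibility) that real Fab constant domains display
#' relative to the variable domains. This is a synthetic fixture for
#' exercising the full pipeline, not a model of any real antibody.
#'
#' @param strand_len Residues per strand in each sandwich.
#' @param loose_constant Dilation factor (> 1) of the constant-like
#'   domains.
#' @param seed Integer seed for coordinate jitter.
#' @return List with `structure`, `annotation` (labels `VL`, `CL`, `VH`,
#'   `CH` and CDR-like loops `L1`..`H3` resolved on the synthetic
#'   numbering), and `truth` (domain index vectors).
#' @export
make_synthetic_fab <- function(strand_len = 7L, loose_constant = 1.12,
                               seed = 1L) {
  with_local_seed(seed, {
    jit <- function(xyz, sd = 0.25)
      xyz + matrix(stats::rnorm(length(xyz), 0, sd), nrow(xyz), 3L)
    dil <- function(xyz, f) {
      ctr <- colMeans(xyz)
      sweep(sweep(xyz, 2L, ctr) * f, 2L, ctr, "+")
    }
    dom <- sandwich_xyz(strand_len, 4L)
    build_chain <- function(x_off, y_off) {
      v <- jit(dom)
      cst <- jit(dil(dom, loose_constant))
      cst <- sweep(cst, 2L, c(max(dom[, 1L]) + 16, 0, 0), "+")
      link <- densify_path(rbind(v[nrow(v), ], cst[1L, ]), max_step = 3.8)
      link <- link[-c(1L, nrow(link)), , drop = FALSE]
      xyz <- rbind(v, link, cst)
      sweep(xyz, 2L, c(x_off, y_off, 0), "+")
    }
    Lxyz <- build_chain(0, 0)
    Hxyz <- build_chain(0, max(dom[, 2L]) + 8)
    n_dom <- nrow(dom)
    nL <- nrow(Lxyz); nH <- nrow(Hxyz)
    sites <- rbind(sites_from_xyz(Lxyz, chain = "L"),
                   sites_from_xyz(Hxyz, chain = "H"))
    st <- new_cg_structure(sites,
                           source_label = sprintf("synthetic_fab_seed%d",
                                                  as.integer(seed)))
    v_end <- n_dom
    c_start_L <- nL - n_dom + 1L
    c_start_H <- nH - n_dom + 1L
    ann <- domain_annotation(
      label = c("VL", "CL", "VH", "CH"),
      chain = c("L", "L", "H", "H"),
      start = c(1L, c_start_L, 1L, c_start_H),
      end = c(v_end, nL, v_end, nH))
    list(structure = st, annotation = ann,
         truth = list(
           idx = list(VL = seq_len(v_end),
                      CL = c_start_L:nL,
                      VH = nL + seq_len(v_end),
                      CH = nL + (c_start_H:nH)),
           loose_constant = loose_constant))
  })
}

#' Fill a structure's experimental B-factor column with noisy pseudo-data
#'
#' Computes the model B-factors of the structure at a known spring constant
#' and adds seeded zero-mean Gaussian noise with standard deviation equal
#' to `noise_sd_fraction` times the mean B-factor, planting a recoverable
#' ground truth for the spring-constant fit. Values driven negative by
#' noise are clipped at a small positive floor (1% of the mean) with a
#' message.
#'
#' @param structure A `cg_structure`.
#' @param true_gamma Planted spring constant in kBT/A^2 (> 0).
#' @param noise_sd_fraction Noise level as a fraction of the mean B-factor.
#' @param seed Integer seed.
#' @param cutoff_rc Contact cutoff used for the model B-factors.
#' @return The structure with its `bfactor` column filled.
#' @export
make_pseudo_experimental_bfactors <- function(structure, true_gamma,
                                              noise_sd_fraction = 0,
                                              seed = 1L, cutoff_rc = 7.3) {
  stopifnot(inherits(structure, "cg_structure"), true_gamma > 0,
            noise_sd_fraction >= 0)
  dec <- decompose(build_kirchhoff(structure, cutoff_rc = cutoff_rc))
  b <- theoretical_bfactors(residue_msf(dec, gamma = true_gamma))
  with_local_seed(seed, {
    noisy <- b + stats::rnorm(length(b), 0, noise_sd_fraction * mean(b))
    floor_b <- 0.01 * mean(b)
    n_clip <- sum(noisy < floor_b)
    if (n_clip > 0L) {
      message(n_clip, " pseudo-experimental B-factor(s) clipped at the ",
              "positive floor")
      noisy[noisy < floor_b] <- floor_b
    }
    structure$sites$bfactor <- noisy
    structure
  })
}
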