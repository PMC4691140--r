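#' Build the Kirchhoff (connectivity) matrix of a structure
#'
#' Two sites are in contact when their Euclidean separation is less than or
#' equal to the cutoff (the boundary is inclusive). The Kirchhoff matrix
#' Gamma is the graph Laplacian of the contact network: off-diagonal entries
#' are -1 for contacts and 0 otherwise, and each diagonal entry is the
#' contact degree of the site, so every row sums to zero.
#'
#' @param structure A `cg_structure` with at least two sites.
#' @param cutoff_rc Contact cutoff in Angstrom; 7.3 by default, the value
#'   adopted for the Fab analysis.
#' @return A `kirchhoff_topology`: list with `n_sites`, `cutoff_rc`,
#'   `contacts` (m x 2 integer matrix of 1-based pairs, i < j) and `matrix`
#'   (the n x n Kirchhoff matrix).
#' @export
build_kirchhoff <- function(structure, cutoff_rc = 7.3) {
  stopifnot(inherits(structure, "cg_structure"))
  if (nrow(structure$sites) < 2L) {
    stop("degenerate input: need at least 2 sites to build a network")
  }
  if (cutoff_rc <= 0) stop("cutoff_rc must be positive")
  d <- as.matrix(stats::dist(coords(structure)))
  adj <- d <= cutoff_rc
  diag(adj) <- FALSE
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  contacts <- cbind(as.integer(pairs[, 1L]), as.integer(pairs[, 2L]))
  contacts <- contacts[order(contacts[, 1L], contacts[, 2L]), ,
                       drop = FALSE]
  kirchhoff_from_contacts(nrow(structure$sites), contacts,
                          cutoff_rc = cutoff_rc)
}

#' Assemble a Kirchhoff topology from an explicit contact list
#'
#' @param n_sites Number of network sites.
#' @param contacts m x 2 integer matrix of 1-based site pairs (any order;
#'   normalized to i < j, sorted, de-duplicated).
#' @param cutoff_rc Cutoff recorded as metadata.
#' @return A `kirchhoff_topology`.
#' @export
kirchhoff_from_contacts <- function(n_sites, contacts,
                                    cutoff_rc = NA_real_) {
  n_sites <- as.integer(n_sites)
  contacts <- matrix(as.integer(contacts), ncol = 2L)
  if (nrow(contacts) > 0L) {
    if (any(contacts < 1L | contacts > n_sites)) {
      stop("contact index out of range")
    }
    if (any(contacts[, 1L] == contacts[, 2L])) {
      stop("self-contact (i == i) is not allowed")
    }
    flip <- contacts[, 1L] > contacts[, 2L]
    contacts[flip, ] <- contacts[flip, c(2L, 1L)]
    contacts <- unique(contacts)
    contacts <- contacts[order(contacts[, 1L], contacts[, 2L]), ,
                         drop = FALSE]
  }
  K <- matrix(0, n_sites, n_sites)
  if (nrow(contacts) > 0L) {
    K[contacts] <- -1
    K[contacts[, c(2L, 1L), drop = FALSE]] <- -1
  }
  diag(K) <- -rowSums(K)
  structure(list(n_sites = n_sites, cutoff_rc = cutoff_rc,
                 contacts = contacts, matrix = K),
            class = "kirchhoff_topology")
}

#' @export
print.kirchhoff_topology <- function(x, ...) {
  cat("Kirchhoff topology:", x$n_sites, "sites,",
      nrow(x$contacts), "contacts (cutoff",
      format(x$cutoff_rc), "A)\n")
  invisible(x)
}

#' Eigen-decompose a Kirchhoff matrix
#'
#' Full spectrum in ascending order, with a deterministic sign convention
#' (the first entry of each eigenvector whose magnitude exceeds 1e-8 is made
#' positive). Modes with eigenvalue below `zero_tolerance * lambda_max` are
#' flagged as zero modes; on a connected network there is exactly one (the
#' rigid translation), and one per connected component in general.
#'
#' @param topology A `kirchhoff_topology`.
#' @param zero_tolerance Relative threshold for flagging zero modes.
#' @return A `gnm_modes`: list with `values` (ascending eigenvalues),
#'   `vectors` (orthonormal columns), `zero_modes` (indices of flagged
#'   modes), `zero_tolerance`.
#' @export
decompose <- function(topology, zero_tolerance = 1e-9) {
  stopifnot(inherits(topology, "kirchhoff_topology"))
  e <- eigen(topology$matrix, symmetric = TRUE)
  ord <- rev(seq_along(e$values))   # eigen() returns descending
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  for (k in seq_along(values)) {
    lead <- which(abs(vectors[, k]) > 1e-8)[1L]
    if (!is.na(lead) && vectors[lead, k] < 0) {
      vectors[, k] <- -vectors[, k]
    }
  }
  lmax <- max(values, 0)
  zero <- which(values < zero_tolerance * max(lmax, .Machine$double.eps))
  structure(list(values = values, vectors = vectors,
                 zero_modes = zero, zero_tolerance = zero_tolerance),
            class = "gnm_modes")
}

#' @export
print.gnm_modes <- function(x, ...) {
  cat("GNM mode decomposition:", length(x$values), "modes,",
      length(x$zero_modes), "zero mode(s)\n")
  invisible(x)
}

# validate a requested mode subset; default = all non-zero modes
resolve_mode_subset <- function(decomp, mode_subset) {
  nz <- setdiff(seq_along(decomp$values), decomp$zero_modes)
  if (is.null(mode_subset)) return(nz)
  mode_subset <- as.integer(mode_subset)
  if (any(mode_subset %in% decomp$zero_modes)) {
    stop("invalid mode subset: contains zero mode(s) ",
         paste(intersect(mode_subset, decomp$zero_modes), collapse = ", "))
  }
  if (any(mode_subset < 1L | mode_subset > length(decomp$values))) {
    stop("invalid mode subset: index out of range")
  }
  mode_subset
}

# pseudoinverse entries over a mode subset: returns the full matrix,
# symmetrized so downstream maps are exactly symmetric
pinv_from_modes <- function(decomp, subset) {
  U <- decomp$vectors[, subset, drop = FALSE]
  G <- U %*% (t(U) / decomp$values[subset])
  (G + t(G)) / 2
}

#' Per-residue mean-square fluctuation
#'
#' `msf_i = (kBT / gamma) * sum_k u_k(i)^2 / lambda_k` over the chosen
#' modes. Temperatures enter only through kBT/gamma; the package works in
#' units where kBT = 1, so `gamma` carries units of kBT per square Angstrom.
#'
#' @param decomp A `gnm_modes`.
#' @param gamma Spring constant in kBT/A^2 (positive).
#' @param mode_subset Optional integer vector of mode indices (ascending
#'   eigenvalue order); must exclude zero modes. Default: all non-zero
#'   modes, i.e. the full pseudoinverse diagonal.
#' @return Numeric vector of per-site MSF in A^2.
#' @export
residue_msf <- function(decomp, gamma = 1, mode_subset = NULL) {
  stopifnot(inherits(decomp, "gnm_modes"))
  if (gamma <= 0) stop("gamma must be positive")
  subset <- resolve_mode_subset(decomp, mode_subset)
  U <- decomp$vectors[, subset, drop = FALSE]
  drop((U * U) %*% (1 / decomp$values[subset])) / gamma
}

#' Cross-correlation matrix of residue fluctuations
#'
#' `<dRi . dRj> = (kBT / gamma) [Gamma^-1]_ij` over the chosen modes; the
#' diagonal equals [residue_msf()].
#'
#' @inheritParams residue_msf
#' @return n x n numeric matrix in A^2.
#' @export
cross_correlation <- function(decomp, gamma = 1, mode_subset = NULL) {
  stopifnot(inherits(decomp, "gnm_modes"))
  if (gamma <= 0) stop("gamma must be positive")
  subset <- resolve_mode_subset(decomp, mode_subset)
  pinv_from_modes(decomp, subset) / gamma
}

#' Mean-square fluctuation in the internal distance (MSFID)
#'
#' `msfid(i, j) = (3 kBT / gamma) * ([G]_ii + [G]_jj - 2 [G]_ij)` with `G`
#' the pseudoinverse of the Kirchhoff matrix over the chosen modes. Large
#' values mark flexible residue pairings; the matrix is symmetric with a
#' zero diagonal. The factor 3 is the isotropic-space convention for a
#' distance fluctuation; all rank-based uses (flexibility maps, the rupture
#' order of the unfolding simulator) are invariant to it and to `gamma`.
#'
#' Pairs of sites in different connected components share no modes and their
#' distance fluctuation is unbounded; such entries are reported as `Inf`.
#'
#' @inheritParams residue_msf
#' @return n x n numeric matrix in A^2.
#' @export
msfid_matrix <- function(decomp, gamma = 1, mode_subset = NULL) {
  stopifnot(inherits(decomp, "gnm_modes"))
  if (gamma <= 0) stop("gamma must be positive")
  subset <- resolve_mode_subset(decomp, mode_subset)
  G <- pinv_from_modes(decomp, subset)
  d <- diag(G)
  M <- (3 / gamma) * (outer(d, d, "+") - 2 * G)
  M[M < 0] <- 0           # clip numerical negatives
  diag(M) <- 0
  if (length(decomp$zero_modes) > 1L) {
    comp <- component_labels_from_modes(decomp)
    M[outer(comp, comp, "!=")] <- Inf
  }
  M
}

# connected-component labels recovered from the zero-mode eigenvectors:
# each zero mode is constant on a component, so rows of the zero-mode block
# are identical within a component
component_labels_from_modes <- function(decomp) {
  Z <- decomp$vectors[, decomp$zero_modes, drop = FALSE]
  key <- apply(round(Z, 6L), 1L, paste, collapse = ",")
  match(key, unique(key))
}

#' Theoretical B-factors from mean-square fluctuations
#'
#' Debye-Waller relation: `B_i = (8 pi^2 / 3) * msf_i`.
#'
#' @param msf Numeric vector of per-site MSF in A^2 (non-negative).
#' @return Numeric vector of B-factors in A^2.
#' @export
theoretical_bfactors <- function(msf) {
  if (any(msf < 0)) stop("msf must be non-negative")
  (8 * pi^2 / 3) * msf
}

#' Fit the uniform spring constant against experimental B-factors
#'
#' The spring coefficient gamma is the only adjustable parameter of the
#' model; it is determined by normalizing the theoretical B-factors against
#' the experimental ones. Under the default `method = "mean"` the returned
#' gamma makes the mean theoretical B-factor equal the mean experimental
#' one: `gamma = mean(B at gamma = 1) / mean(B_exp)`. A least-squares
#' scaling is offered as an alternative. The Pearson correlation between
#' the two series is reported alongside; it is scale-free, so it does not
#' depend on gamma.
#'
#' @param theoretical_shape Per-site theoretical B-factors computed at
#'   gamma = 1 (A^2).
#' @param experimental Per-site experimental B-factors (A^2).
#' @param method `"mean"` (match means; default) or `"lsq"` (least-squares
#'   scale).
#' @return List with `gamma` (kBT/A^2), `correlation` (Pearson),
#'   `bfactors_fit` (theoretical B-factors at the fitted gamma), `method`.
#' @export
fit_gamma <- function(theoretical_shape, experimental,
                      method = c("mean", "lsq")) {
  method <- match.arg(method)
  stopifnot(length(theoretical_shape) == length(experimental),
            length(experimental) >= 2L)
  if (!all(is.finite(experimental)) || mean(experimental) <= 0) {
    stop("fit error: experimental B-factors must be finite with a ",
         "positive mean")
  }
  gamma <- switch(method,
    mean = mean(theoretical_shape) / mean(experimental),
    lsq  = sum(theoretical_shape^2) /
             sum(theoretical_shape * experimental)
  )
  list(gamma = gamma,
       correlation = stats::cor(theoretical_shape, experimental),
       bfactors_fit = theoretical_shape / gamma,
       method = method)
}

#' MSF restricted to the slowest modes
#'
#' Collective, large-scale motions live in the low-frequency end of the
#' spectrum; the Fab analysis uses the six slowest non-zero modes.
#'
#' @param decomp A `gnm_modes`.
#' @param gamma Spring constant in kBT/A^2.
#' @param k_slowest Number of slowest non-zero modes to keep (default 6).
#' @return Numeric vector of per-site MSF in A^2.
#' @export
mode_subset_msf <- function(decomp, gamma = 1, k_slowest = 6L) {
  nz <- setdiff(seq_along(decomp$values), decomp$zero_modes)
  if (k_slowest > length(nz)) {
    stop("invalid mode subset: requested ", k_slowest,
         " slowest modes but only ", length(nz), " non-zero modes exist")
  }
  residue_msf(decomp, gamma = gamma, mode_subset = nz[seq_len(k_slowest)])
}
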