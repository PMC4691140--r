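#' Per-residue comparison of computed and experimental B-factors
#'
#' Fits the spring constant (see [fit_gamma()]) and aligns the two series
#' residue by residue, reporting their Pearson correlation. Correlation,
#' not agreement in absolute scale, is the meaningful statistic: the
#' spring constant only sets the scale.
#'
#' @param structure A `cg_structure` whose `bfactor` column is present.
#' @param decomp Optional `gnm_modes` of the structure's network (computed
#'   at the default cutoff if missing).
#' @param cutoff_rc Cutoff used when `decomp` is not supplied.
#' @param method Passed to [fit_gamma()].
#' @return List with `table` (data.frame: `index`, `chain`, `resno`,
#'   `experimental`, `computed`), `gamma`, `correlation`, `method`.
#' @export
bfactor_comparison <- function(structure, decomp = NULL, cutoff_rc = 7.3,
                               method = "mean") {
  stopifnot(inherits(structure, "cg_structure"))
  bexp <- structure$sites$bfactor
  if (!all(is.finite(bexp))) {
    stop("experimental B-factor column is missing or incomplete")
  }
  if (is.null(decomp)) {
    decomp <- decompose(build_kirchhoff(structure, cutoff_rc = cutoff_rc))
  }
  shape <- theoretical_bfactors(residue_msf(decomp, gamma = 1))
  fit <- fit_gamma(shape, bexp, method = method)
  s <- structure$sites
  list(table = data.frame(index = seq_len(nrow(s)) - 1L, chain = s$chain,
                          resno = s$resno, experimental = bexp,
                          computed = fit$bfactors_fit),
       gamma = fit$gamma, correlation = fit$correlation,
       method = fit$method)
}

#' Domain-level mobility and flexibility statistics
#'
#' For every annotated domain: the mean slow-mode MSF of its sites
#' (mobility) and the mean within-domain MSFID over its internal site
#' pairs (flexibility). Domains that resolve to a single site have no
#' internal pairs and are excluded with a warning.
#'
#' @param msf Per-site MSF vector (typically [mode_subset_msf()]).
#' @param msfid Full MSFID matrix (typically [msfid_matrix()] over all
#'   non-zero modes).
#' @param annotation_idx Named list of site-index vectors, as from
#'   [resolve_annotation()].
#' @return data.frame: `label`, `n_sites`, `mean_msf`, `mean_msfid`.
#' @export
domain_statistics <- function(msf, msfid, annotation_idx) {
  stopifnot(is.list(annotation_idx), length(annotation_idx) > 0L)
  single <- vapply(annotation_idx, length, integer(1)) < 2L
  if (any(single)) {
    warning("domain(s) with fewer than 2 sites excluded: ",
            paste(names(annotation_idx)[single], collapse = ", "))
    annotation_idx <- annotation_idx[!single]
  }
  rows <- lapply(names(annotation_idx), function(lab) {
    idx <- annotation_idx[[lab]]
    sub <- msfid[idx, idx, drop = FALSE]
    data.frame(label = lab, n_sites = length(idx),
               mean_msf = mean(msf[idx]),
               mean_msfid = mean(sub[upper.tri(sub)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full dynamics-and-unfolding analysis of a Fab-like structure
#'
#' The complete pipeline: build the contact network at the cutoff, fit the
#' spring constant against experimental B-factors (when present), compute
#' slow-mode MSF, the full-mode MSFID map and domain statistics, simulate
#' iterative unfolding and summarize domain melting. This is the
#' program that, applied to a Fab crystal structure with its domain/CDR
#' annotation, reproduces the whole analysis chain.
#'
#' @param structure A `cg_structure`.
#' @param annotation A `domain_annotation`; defaults to the packaged Fab
#'   domain/CDR scheme (see [fab_default_annotation()]).
#' @param cutoff_rc Contact cutoff in Angstrom (default 7.3).
#' @param k_slowest Number of slowest modes for the mobility profile
#'   (default 6).
#' @param snapshot_lnnc LNNC values at which unfolding snapshots are kept.
#' @param T0_kelvin Kelvin temperature assigned to the first rupture.
#' @param min_jump_size Cooperative-jump threshold (contacts).
#' @param groups Domain groups for the melting summary; the default pairs
#'   the constant domains (CL, CH) against the variable domains (VL, VH)
#'   when those labels exist in the annotation.
#' @return An `analysis_report`: list with `structure`, `topology`,
#'   `decomposition`, `bfactors` (NULL without experimental data),
#'   `gamma`, `slow_msf`, `msfid`, `domain_stats`, `trajectory`,
#'   `melting`, `annotation_idx`, `manifest` (the numeric conventions the
#'   numbers depend on).
#' @export
analyze_fab <- function(structure, annotation = fab_default_annotation(),
                        cutoff_rc = 7.3, k_slowest = 6L,
                        snapshot_lnnc = c(600L, 990L, 1310L, 1470L),
                        T0_kelvin = 300, min_jump_size = 20L,
                        groups = NULL) {
  stopifnot(inherits(structure, "cg_structure"))
  topo <- build_kirchhoff(structure, cutoff_rc = cutoff_rc)
  dec <- decompose(topo)
  ann_idx <- resolve_annotation(annotation, structure)

  bcomp <- NULL
  gamma <- 1
  if (all(is.finite(structure$sites$bfactor))) {
    bcomp <- bfactor_comparison(structure, decomp = dec)
    gamma <- bcomp$gamma
  }

  slow_msf <- mode_subset_msf(dec, gamma = gamma, k_slowest = k_slowest)
  msfid <- msfid_matrix(dec, gamma = gamma)
  dstats <- domain_statistics(slow_msf, msfid, ann_idx)

  traj <- suppressWarnings(
    unfold(structure, topology = topo, snapshot_lnnc = snapshot_lnnc))
  if (is.null(groups)) {
    groups <- list()
    if (all(c("CL", "CH") %in% names(ann_idx))) {
      groups$constant <- c("CL", "CH")
    }
    if (all(c("VL", "VH") %in% names(ann_idx))) {
      groups$variable <- c("VL", "VH")
    }
    if (length(groups) == 0L) groups <- NULL
  }
  domain_labels <- intersect(c("VL", "CL", "VH", "CH"), names(ann_idx))
  melt_idx <- if (length(domain_labels) > 0L) ann_idx[domain_labels]
              else ann_idx
  melting <- suppressWarnings(
    melting_summary(traj, melt_idx, T0_kelvin = T0_kelvin,
                    groups = groups, min_jump_size = min_jump_size))

  out <- list(structure = structure, topology = topo,
              decomposition = dec, bfactors = bcomp, gamma = gamma,
              slow_msf = slow_msf, msfid = msfid, domain_stats = dstats,
              trajectory = traj, melting = melting,
              annotation_idx = ann_idx,
              manifest = list(cutoff_rc = cutoff_rc,
                              k_slowest = k_slowest,
                              msfid_prefactor = "3*kBT/gamma",
                              msf_prefactor = "kBT/gamma",
                              tie_break = "lexicographic smallest pair",
                              zero_tolerance = dec$zero_tolerance,
                              min_jump_size = min_jump_size,
                              T0_kelvin = T0_kelvin))
  class(out) <- "analysis_report"
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("GNM analysis report:", x$structure$source_label, "\n")
  cat("  sites:", x$topology$n_sites,
      " contacts:", nrow(x$topology$contacts),
      " cutoff:", x$manifest$cutoff_rc, "A\n")
  if (!is.null(x$bfactors)) {
    cat("  fitted gamma:", format(x$gamma, digits = 4), "kBT/A^2;",
        "B-factor correlation:",
        format(x$bfactors$correlation, digits = 3), "\n")
  }
  cat("  unfolding order:",
      paste(x$melting$unfolding_order, collapse = " -> "), "\n")
  if (!is.null(x$melting$groups)) {
    g <- x$melting$groups
    for (r in seq_len(nrow(g))) {
      cat("  ", g$label[r], "melt:",
          format(g$melt_kelvin[r], digits = 4), "K\n")
    }
  }
  invisible(x)
}

#' Write a dense matrix as a tab-separated text grid
#'
#' For heatmap rendering of MSFID or cross-correlation maps outside R.
#'
#' @param m Numeric matrix.
#' @param path Output file path.
#' @export
write_matrix_grid <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
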