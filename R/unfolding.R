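#' Contacts eligible for thermal rupture
#'
#' All native contacts except backbone-bonded pairs: sites that are
#' sequence-adjacent within one chain (consecutive sites of the same chain
#' in file order). Covalent backbone links cannot break thermally, and
#' keeping their springs in the network prevents trivial dispersal of the
#' chain, so they are never rupture candidates.
#'
#' @param topology A `kirchhoff_topology` built from `structure`.
#' @param structure The `cg_structure` the topology was built from.
#' @return m x 2 integer matrix of breakable contact pairs (1-based,
#'   i < j).
#' @export
breakable_pairs <- function(topology, structure) {
  stopifnot(inherits(topology, "kirchhoff_topology"),
            inherits(structure, "cg_structure"),
            topology$n_sites == nrow(structure$sites))
  cp <- topology$contacts
  if (nrow(cp) == 0L) return(cp)
  ch <- structure$sites$chain
  bonded <- (cp[, 2L] - cp[, 1L] == 1L) & (ch[cp[, 1L]] == ch[cp[, 2L]])
  cp[!bonded, , drop = FALSE]
}

# per-pair MSFID (3 * (Gii + Gjj - 2 Gij), kBT/gamma = 1) for the given
# pairs, straight from the non-zero modes -- avoids forming the full matrix
msfid_for_pairs <- function(decomp, pairs) {
  nz <- setdiff(seq_along(decomp$values), decomp$zero_modes)
  W <- decomp$vectors[, nz, drop = FALSE] *
    rep(1 / sqrt(decomp$values[nz]), each = nrow(decomp$vectors))
  dG <- rowSums(W * W)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  Gij <- rowSums(W[i, , drop = FALSE] * W[j, , drop = FALSE])
  3 * (dG[i] + dG[j] - 2 * Gij)
}

#' Simulate thermal unfolding by iterative contact rupture
#'
#' Starting from the native contact topology, the simulator repeatedly (i)
#' eigen-solves the current Kirchhoff matrix, (ii) computes the mean-square
#' fluctuation of the inter-residue distance (MSFID) for every live
#' breakable contact over all non-zero modes, (iii) ruptures the contact
#' with the largest MSFID (ties broken by the lexicographically smallest
#' pair), and (iv) rebuilds the network, until no breakable contact
#' remains. Re-solving after every rupture captures the nonlinear softening
#' of the network as it falls apart. Backbone-adjacent contacts (see
#' [breakable_pairs()]) are kept permanently, so chains never disperse.
#'
#' Each rupture is annotated with a reduced temperature: a contact is
#' assumed to break when its distance fluctuation reaches a fixed critical
#' value, and MSFID grows linearly with temperature, so the breaking
#' temperature of the k-th ruptured pair is inversely proportional to its
#' per-kBT fluctuation, `T_k / T0 = m_1 / m_k`, normalized so the first
#' rupture defines T0. The reported temperature is the running maximum of
#' this raw sequence: raw values below the running maximum are cooperative
#' ruptures occurring at constant temperature.
#'
#' @param structure A `cg_structure`.
#' @param topology Optional pre-built `kirchhoff_topology` (default: built
#'   from `structure` at the 7.3 A cutoff).
#' @param snapshot_lnnc Integer vector: capture the topology when the loss
#'   number of native contacts (LNNC) reaches these values. Defaults to the
#'   values used for the Fab contact-map series. Values beyond the final
#'   LNNC are dropped with a warning.
#' @param cutoff_rc Cutoff used when `topology` is not supplied.
#' @return An `unfolding_trajectory`: list with `events` (data.frame:
#'   `step`, `i`, `j`, `chain_i`, `resno_i`, `chain_j`, `resno_j`,
#'   `msfid`, `lnnc`, `t_raw`, `t_over_t0`), `initial_topology`,
#'   `snapshots` (named list of `kirchhoff_topology` at requested LNNC),
#'   `structure`.
#' @export
unfold <- function(structure, topology = NULL,
                   snapshot_lnnc = c(600L, 990L, 1310L, 1470L),
                   cutoff_rc = 7.3) {
  stopifnot(inherits(structure, "cg_structure"))
  if (is.null(topology)) {
    topology <- build_kirchhoff(structure, cutoff_rc = cutoff_rc)
  }
  initial <- topology
  brk <- breakable_pairs(topology, structure)
  n_break <- nrow(brk)
  snapshot_lnnc <- sort(unique(as.integer(snapshot_lnnc)))
  if (any(snapshot_lnnc > n_break)) {
    warning("snapshot LNNC value(s) beyond the ", n_break,
            " breakable contacts omitted: ",
            paste(snapshot_lnnc[snapshot_lnnc > n_break], collapse = ", "))
    snapshot_lnnc <- snapshot_lnnc[snapshot_lnnc <= n_break]
  }

  key <- function(p) p[, 1L] * (topology$n_sites + 1L) + p[, 2L]
  brk_keys <- key(brk)
  events <- vector("list", n_break)
  snapshots <- list()
  cur <- topology

  for (step in seq_len(n_break)) {
    live_brk <- cur$contacts[key(cur$contacts) %in% brk_keys, ,
                             drop = FALSE]
    dec <- decompose(cur)
    m <- msfid_for_pairs(dec, live_brk)
    if (any(!is.finite(m)) || any(m <= 0)) {
      stop("numerical degeneracy at unfolding step ", step,
           ": non-positive or non-finite MSFID")
    }
    mmax <- max(m)
    cand <- which(m >= mmax * (1 - 1e-9))
    pick <- cand[order(live_brk[cand, 1L], live_brk[cand, 2L])][1L]
    pij <- live_brk[pick, ]
    events[[step]] <- c(step = step, i = pij[1L], j = pij[2L],
                        msfid = m[pick])
    keep <- key(cur$contacts) != key(matrix(pij, ncol = 2L))
    cur <- kirchhoff_from_contacts(cur$n_sites,
                                   cur$contacts[keep, , drop = FALSE],
                                   cutoff_rc = cur$cutoff_rc)
    if (step %in% snapshot_lnnc) {
      snapshots[[paste0("lnnc_", step)]] <- cur
    }
  }

  ev <- as.data.frame(do.call(rbind, events))
  if (n_break == 0L) {
    ev <- data.frame(step = integer(0), i = integer(0), j = integer(0),
                     msfid = numeric(0))
  }
  s <- structure$sites
  ev$chain_i <- s$chain[ev$i]; ev$resno_i <- s$resno[ev$i]
  ev$chain_j <- s$chain[ev$j]; ev$resno_j <- s$resno[ev$j]
  ev$lnnc <- ev$step
  tt <- reduced_temperatures(ev$msfid)
  ev$t_raw <- tt$raw
  ev$t_over_t0 <- tt$reported
  ev <- ev[, c("step", "i", "j", "chain_i", "resno_i", "chain_j",
               "resno_j", "msfid", "lnnc", "t_raw", "t_over_t0")]

  out <- list(events = ev, initial_topology = initial,
              snapshots = snapshots, structure = structure)
  class(out) <- "unfolding_trajectory"
  out
}

#' @export
print.unfolding_trajectory <- function(x, ...) {
  cat("Unfolding trajectory:", nrow(x$events), "ruptures out of",
      nrow(x$initial_topology$contacts), "native contacts\n")
  if (nrow(x$events) > 0L) {
    cat("  final reduced temperature T/T0 =",
        format(max(x$events$t_over_t0), digits = 4), "\n")
  }
  invisible(x)
}

#' Reduced rupture temperatures from an MSFID sequence
#'
#' Maps the MSFID of each ruptured pair (per unit kBT/gamma) to a reduced
#' temperature `T_k / T0 = m_1 / m_k` and monotonizes the sequence with a
#' running maximum, so that cooperative cascades (raw temperature below the
#' running maximum) read as ruptures at constant temperature.
#'
#' @param msfid_sequence Numeric vector: the MSFID at which each successive
#'   pair ruptured, or an `unfolding_trajectory`.
#' @return List with `raw` and `reported` (non-decreasing, starts at 1)
#'   per-event reduced temperatures.
#' @export
reduced_temperatures <- function(msfid_sequence) {
  if (inherits(msfid_sequence, "unfolding_trajectory")) {
    msfid_sequence <- msfid_sequence$events$msfid
  }
  if (length(msfid_sequence) == 0L) {
    return(list(raw = numeric(0), reported = numeric(0)))
  }
  if (any(!is.finite(msfid_sequence)) || any(msfid_sequence <= 0)) {
    bad <- which(!is.finite(msfid_sequence) | msfid_sequence <= 0)[1L]
    stop("numerical degeneracy at step ", bad,
         ": zero or non-finite MSFID")
  }
  raw <- msfid_sequence[1L] / msfid_sequence
  list(raw = raw, reported = cummax(raw))
}

#' Detect cooperative jumps in the LNNC-temperature curve
#'
#' A jump is a maximal run of at least `min_jump_size` consecutive rupture
#' events sharing one reported (running-maximum) temperature: many contacts
#' breaking at a single temperature is the signature of a cooperative
#' transition of a substructure.
#'
#' @param trajectory An `unfolding_trajectory`.
#' @param min_jump_size Minimum number of events in a run for it to count
#'   as a jump (default 20, a domain-scale run on a Fab-sized protein).
#' @return data.frame with one row per jump: `t_over_t0`, `lnnc_before`
#'   (LNNC just before the jump), `lnnc_after`, `size`.
#' @export
detect_jumps <- function(trajectory, min_jump_size = 20L) {
  stopifnot(inherits(trajectory, "unfolding_trajectory"))
  tt <- trajectory$events$t_over_t0
  empty <- data.frame(t_over_t0 = numeric(0), lnnc_before = integer(0),
                      lnnc_after = integer(0), size = integer(0))
  if (length(tt) == 0L) return(empty)
  r <- rle(tt)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  big <- which(r$lengths >= min_jump_size)
  if (length(big) == 0L) return(empty)
  data.frame(t_over_t0 = r$values[big],
             lnnc_before = starts[big] - 1L,
             lnnc_after = ends[big],
             size = r$lengths[big])
}

#' Domain-level melting summary of an unfolding trajectory
#'
#' Attributes every breakable native contact of the initial topology to a
#' domain (both endpoints inside one labelled domain), to the inter-domain
#' category, or to the unannotated remainder. Each domain is assigned the
#' reduced temperature of the cooperative jump that ruptures the majority
#' (plurality) of its internal contacts, converted to Kelvin via
#' `T0_kelvin`; if no jump ruptures any of them, the reported temperature
#' at the domain's median rupture step is used instead. The unfolding
#' order sorts domains by the median rupture step of their internal
#' contacts. Optional `groups` aggregate domains (e.g. the constant
#' regions CL + CH vs the variable regions VL + VH) and are summarized the
#' same way over the union of their internal contacts.
#'
#' @param trajectory An `unfolding_trajectory`.
#' @param annotation_idx Named list mapping domain labels to site indices,
#'   as returned by [resolve_annotation()].
#' @param T0_kelvin Temperature, in Kelvin, assigned to the first rupture
#'   (default 300, room temperature).
#' @param groups Optional named list mapping group labels to character
#'   vectors of domain labels.
#' @param min_jump_size Passed to [detect_jumps()].
#' @return A `melting_summary`: list with `domains` (data.frame: `label`,
#'   `n_internal`, `median_step`, `jump_t_over_t0`, `melt_kelvin`),
#'   `groups` (same shape), `unfolding_order` (labels, earliest first),
#'   `jumps`, `rupture_steps` (list of per-domain internal rupture steps),
#'   `T0_kelvin`.
#' @export
melting_summary <- function(trajectory, annotation_idx, T0_kelvin = 300,
                            groups = NULL, min_jump_size = 20L) {
  stopifnot(inherits(trajectory, "unfolding_trajectory"))
  ev <- trajectory$events
  jumps <- detect_jumps(trajectory, min_jump_size = min_jump_size)

  member_steps <- function(idx) {
    ev$step[ev$i %in% idx & ev$j %in% idx]
  }
  summarize <- function(steps) {
    med <- stats::median(steps)
    jt <- NA_real_
    if (nrow(jumps) > 0L) {
      counts <- vapply(seq_len(nrow(jumps)), function(k) {
        sum(steps > jumps$lnnc_before[k] & steps <= jumps$lnnc_after[k])
      }, numeric(1))
      if (max(counts) > 0) jt <- jumps$t_over_t0[which.max(counts)]
    }
    if (is.na(jt)) {
      jt <- ev$t_over_t0[ev$step == round(med)][1L]
      if (is.na(jt)) jt <- stats::approx(ev$step, ev$t_over_t0, med)$y
    }
    c(median_step = med, jump_t = jt)
  }

  steps_by_label <- lapply(annotation_idx, member_steps)
  empty <- vapply(steps_by_label, length, integer(1)) == 0L
  if (any(empty)) {
    warning("domain(s) with no internal breakable contacts excluded: ",
            paste(names(steps_by_label)[empty], collapse = ", "))
    steps_by_label <- steps_by_label[!empty]
  }
  if (length(steps_by_label) == 0L) {
    stop("no domain has internal breakable contacts")
  }

  dom <- t(vapply(steps_by_label, summarize, numeric(2)))
  domains <- data.frame(
    label = names(steps_by_label),
    n_internal = vapply(steps_by_label, length, integer(1)),
    median_step = dom[, "median_step"],
    jump_t_over_t0 = dom[, "jump_t"],
    melt_kelvin = T0_kelvin * dom[, "jump_t"],
    row.names = NULL, stringsAsFactors = FALSE
  )

  grp_tab <- NULL
  if (!is.null(groups)) {
    gsteps <- lapply(groups, function(labs) {
      labs <- intersect(labs, names(steps_by_label))
      sort(unlist(steps_by_label[labs], use.names = FALSE))
    })
    gsteps <- gsteps[vapply(gsteps, length, integer(1)) > 0L]
    if (length(gsteps) > 0L) {
      g <- t(vapply(gsteps, summarize, numeric(2)))
      grp_tab <- data.frame(
        label = names(gsteps),
        n_internal = vapply(gsteps, length, integer(1)),
        median_step = g[, "median_step"],
        jump_t_over_t0 = g[, "jump_t"],
        melt_kelvin = T0_kelvin * g[, "jump_t"],
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
  }

  structure(list(
    domains = domains,
    groups = grp_tab,
    unfolding_order = domains$label[order(domains$median_step)],
    jumps = jumps,
    rupture_steps = steps_by_label,
    T0_kelvin = T0_kelvin
  ), class = "melting_summary")
}

#' @export
print.melting_summary <- function(x, ...) {
  cat("Melting summary (T0 =", x$T0_kelvin, "K)\n")
  cat("  unfolding order:", paste(x$unfolding_order, collapse = " -> "),
      "\n")
  print(x$domains, digits = 4)
  if (!is.null(x$groups)) {
    cat("  groups:\n")
    print(x$groups, digits = 4)
  }
  invisible(x)
}

#' Write an unfolding trajectory as a tab-separated event table
#'
#' Columns: step, chain_i, resnum_i, chain_j, resnum_j, msfid, lnnc,
#' T_over_T0.
#'
#' @param trajectory An `unfolding_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory <- function(trajectory, path) {
  ev <- trajectory$events
  out <- data.frame(step = ev$step, chain_i = ev$chain_i,
                    resnum_i = ev$resno_i, chain_j = ev$chain_j,
                    resnum_j = ev$resno_j, msfid = ev$msfid,
                    lnnc = ev$lnnc, T_over_T0 = ev$t_over_t0)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
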