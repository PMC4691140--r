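#' Read a coarse-grained (C-alpha) structure from a PDB file
#'
#' Reduces a PDB file to one site per residue, located at the residue's
#' C-alpha atom, in order of appearance. The B-factor column of the C-alpha
#' record is kept as the experimental B-factor of the site. HETATM records
#' are ignored. When a C-alpha carries alternate locations, the altloc with
#' the highest occupancy is kept; ties are broken by altloc identifier order
#' so the result is deterministic. Residues without a C-alpha atom are
#' skipped with a warning.
#'
#' @param path Path to a PDB file.
#' @param chain_filter Optional character vector of chain identifiers; when
#'   given, only sites on these chains are kept.
#' @param model_index For multi-model files, which model to use (default 1,
#'   the convention for crystal structures).
#' @return An object of class `cg_structure`: a list with `sites` (a
#'   data.frame with columns `chain`, `resno`, `insert`, `resid`, `x`, `y`,
#'   `z`, `bfactor`) and `source_label`.
#' @export
read_structure <- function(path, chain_filter = NULL, model_index = 1L) {
  if (!file.exists(path)) {
    stop("cannot read structure: file does not exist: ", path)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  atom <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models) {
    stop("model_index ", model_index, " out of range: file has ",
         n_models, " model(s)")
  }
  if (model_index > 1L) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    atom$x <- xyz[, 1L]; atom$y <- xyz[, 2L]; atom$z <- xyz[, 3L]
  }

  ca <- atom[atom$type == "ATOM" & atom$elety == "CA", , drop = FALSE]
  if (!is.null(chain_filter)) {
    ca <- ca[ca$chain %in% chain_filter, , drop = FALSE]
  }
  if (nrow(ca) == 0L) {
    stop("empty structure: no C-alpha atoms",
         if (!is.null(chain_filter)) " after chain filtering" else "")
  }

  ins <- ca$insert
  ins[is.na(ins)] <- ""
  alt <- ca$alt
  alt[is.na(alt)] <- ""
  occ <- ca$o
  occ[is.na(occ)] <- 1

  key <- paste(ca$chain, ca$resno, ins, sep = "\r")
  # altloc policy: highest occupancy first, then altloc identifier order;
  # stable within the file's own ordering of residues
  pick <- vapply(split(seq_len(nrow(ca)), factor(key, levels = unique(key))),
                 function(idx) {
                   if (length(idx) == 1L) return(idx)
                   o <- order(-occ[idx], alt[idx])
                   idx[o[1L]]
                 }, integer(1))
  ca <- ca[pick, , drop = FALSE]
  ins <- ins[pick]

  bad <- !is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z)
  if (any(bad)) stop("non-finite coordinates for ", sum(bad), " site(s)")

  sites <- data.frame(
    chain   = as.character(ca$chain),
    resno   = as.integer(ca$resno),
    insert  = ins,
    resid   = as.character(ca$resid),
    x = ca$x, y = ca$y, z = ca$z,
    bfactor = as.numeric(ca$b),
    stringsAsFactors = FALSE
  )
  rownames(sites) <- NULL

  n_res <- length(unique(paste(atom$chain[atom$type == "ATOM"],
                               atom$resno[atom$type == "ATOM"],
                               atom$insert[atom$type == "ATOM"])))
  n_kept <- nrow(sites)
  if (!is.null(chain_filter)) {
    flt <- atom$type == "ATOM" & atom$chain %in% chain_filter
    n_res <- length(unique(paste(atom$chain[flt], atom$resno[flt],
                                 atom$insert[flt])))
  }
  if (n_kept < n_res) {
    warning(n_res - n_kept, " residue(s) without a C-alpha atom skipped")
  }

  new_cg_structure(sites, source_label = basename(path))
}

#' Construct a coarse-grained structure from site data
#'
#' Low-level constructor used by [read_structure()] and the synthetic
#' generators. Validates the structure invariants: finite coordinates and
#' unique (chain, residue number, insertion code) identities.
#'
#' @param sites data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `x`, `y`, `z`, `bfactor` (`bfactor` may be `NA`).
#' @param source_label Free-text provenance label.
#' @return A `cg_structure` object.
#' @export
new_cg_structure <- function(sites, source_label = "in-memory") {
  stopifnot(is.data.frame(sites),
            all(c("chain", "resno", "insert", "x", "y", "z") %in%
                  names(sites)))
  if (is.null(sites$resid)) sites$resid <- "ALA"
  if (is.null(sites$bfactor)) sites$bfactor <- NA_real_
  if (!all(is.finite(sites$x) & is.finite(sites$y) & is.finite(sites$z))) {
    stop("all site coordinates must be finite")
  }
  id <- paste(sites$chain, sites$resno, sites$insert, sep = "\r")
  if (anyDuplicated(id)) {
    stop("duplicate site identity (chain, resno, insert) in structure")
  }
  structure(list(sites = sites, source_label = source_label),
            class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("Coarse-grained structure:", x$source_label, "\n")
  cat("  ", nrow(x$sites), "C-alpha sites on chain(s):",
      paste(unique(x$sites$chain), collapse = ", "), "\n")
  if (any(is.finite(x$sites$bfactor))) {
    cat("  experimental B-factors present (mean ",
        format(mean(x$sites$bfactor, na.rm = TRUE), digits = 4), " A^2)\n",
        sep = "")
  }
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param structure A `cg_structure`.
#' @return n x 3 numeric matrix of site coordinates in Angstrom.
#' @export
coords <- function(structure) {
  stopifnot(inherits(structure, "cg_structure"))
  as.matrix(structure$sites[, c("x", "y", "z")])
}

#' Write a coarse-grained structure as a C-alpha-only PDB file
#'
#' Emits one ATOM record per site so generated fixtures can be inspected in
#' any structure viewer and re-read with [read_structure()].
#'
#' @param structure A `cg_structure`.
#' @param path Output file path.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "cg_structure"))
  s <- structure$sites
  b <- s$bfactor
  b[!is.finite(b)] <- 0
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(s[, c("x", "y", "z")]))),
    resno = s$resno, chain = s$chain, resid = s$resid,
    insert = ifelse(s$insert == "", NA, s$insert),
    elety = rep("CA", nrow(s)), b = b, o = rep(1, nrow(s))
  )
  invisible(path)
}

#' Write a contact map to a tab-separated file
#'
#' One row per contact: the 0-based site indices `i`, `j` with `i < j`,
#' sorted lexicographically. Round-trips losslessly through
#' [read_contact_map()]. This is the plain-text form of the native contact
#' maps drawn during the unfolding analysis.
#'
#' @param topology A `kirchhoff_topology` (see [build_kirchhoff()]).
#' @param path Output file path.
#' @export
write_contact_map <- function(topology, path) {
  stopifnot(inherits(topology, "kirchhoff_topology"))
  cp <- topology$contacts
  if (nrow(cp) > 0L) {
    cp <- cp[order(cp[, 1L], cp[, 2L]), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("i\tj", con)
  if (nrow(cp) > 0L) {
    writeLines(paste(cp[, 1L] - 1L, cp[, 2L] - 1L, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#'
#' @param path File path.
#' @param n_sites Number of sites of the network the map belongs to.
#' @param cutoff_rc Cutoff recorded on the returned topology (metadata only).
#' @return A `kirchhoff_topology`.
#' @export
read_contact_map <- function(path, n_sites, cutoff_rc = NA_real_) {
  tab <- utils::read.delim(path, header = TRUE,
                           colClasses = c("integer", "integer"))
  pairs <- cbind(tab$i + 1L, tab$j + 1L)
  kirchhoff_from_contacts(n_sites, pairs, cutoff_rc = cutoff_rc)
}

#' Domain and CDR annotation as named residue ranges
#'
#' @param label Character vector of range labels.
#' @param chain Character vector of chain identifiers.
#' @param start,end Integer vectors, inclusive author-numbering bounds.
#' @return A `domain_annotation` data.frame.
#' @export
domain_annotation <- function(label, chain, start, end) {
  ann <- data.frame(label = as.character(label), chain = as.character(chain),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  stopifnot(all(ann$start <= ann$end))
  class(ann) <- c("domain_annotation", "data.frame")
  ann
}

#' Read an annotation file (label, chain, start, end per line)
#'
#' Lines starting with `#` are comments; fields are whitespace-separated.
#'
#' @param path Path to the annotation file.
#' @return A `domain_annotation`.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("label", "chain", "start", "end"),
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  domain_annotation(tab$label, tab$chain, tab$start, tab$end)
}

#' Default Fab domain and CDR annotation (McPC603 numbering)
#'
#' The four immunoglobulin domains (VL, CL on the light chain; VH, CH on the
#' heavy chain) and the six complementarity-determining regions in author
#' numbering: L1 26-37, L2 56-61, L3 97-102 on the light chain and H1 28-32,
#' H2 50-58, H3 102-109 on the heavy chain. Domain boundaries follow the
#' conventional immunoglobulin-fold split of a Fab: the variable domain is
#' the first ~110-120 residues of each chain, the constant domain the rest.
#'
#' @param light_chain,heavy_chain Chain identifiers in the structure file.
#' @param vl_end,vh_end Last residue of the variable domain on each chain.
#' @param cl_end,ch_end Last residue of the constant domain on each chain.
#' @return A `domain_annotation`.
#' @export
fab_default_annotation <- function(light_chain = "L", heavy_chain = "H",
                                   vl_end = 113L, cl_end = 220L,
                                   vh_end = 122L, ch_end = 222L) {
  domain_annotation(
    label = c("VL", "CL", "VH", "CH",
              "L1", "L2", "L3", "H1", "H2", "H3"),
    chain = c(light_chain, light_chain, heavy_chain, heavy_chain,
              light_chain, light_chain, light_chain,
              heavy_chain, heavy_chain, heavy_chain),
    start = c(1L, vl_end + 1L, 1L, vh_end + 1L,
              26L, 56L, 97L, 28L, 50L, 102L),
    end   = c(vl_end, cl_end, vh_end, ch_end,
              37L, 61L, 102L, 32L, 58L, 109L)
  )
}

#' Resolve an annotation against a structure
#'
#' Maps every labelled range to the (1-based) site indices whose chain
#' matches and whose author residue number lies within the inclusive range.
#' Insertion-coded residues at an in-range numeric position are included,
#' following antibody numbering conventions.
#'
#' @param annotation A `domain_annotation`.
#' @param structure A `cg_structure`.
#' @return Named list mapping each label to an increasing integer vector of
#'   site indices.
#' @export
resolve_annotation <- function(annotation, structure) {
  stopifnot(inherits(annotation, "domain_annotation"),
            inherits(structure, "cg_structure"))
  s <- structure$sites
  out <- list()
  for (lab in unique(annotation$label)) {
    rows <- annotation[annotation$label == lab, , drop = FALSE]
    idx <- integer(0)
    for (r in seq_len(nrow(rows))) {
      hit <- which(s$chain == rows$chain[r] &
                     s$resno >= rows$start[r] & s$resno <= rows$end[r])
      idx <- c(idx, hit)
    }
    idx <- sort(unique(idx))
    if (length(idx) == 0L) {
      stop("annotation range '", lab, "' resolves to zero sites")
    }
    out[[lab]] <- idx
  }
  out
}

#' Write a per-residue table of values as tab-separated text
#'
#' Columns: 0-based site index, chain, residue number, value.
#'
#' @param structure A `cg_structure`.
#' @param values Numeric vector, one per site.
#' @param path Output file path.
#' @param value_name Column name for the value.
#' @export
write_residue_table <- function(structure, values, path,
                                value_name = "value") {
  s <- structure$sites
  stopifnot(length(values) == nrow(s))
  tab <- data.frame(index = seq_len(nrow(s)) - 1L, chain = s$chain,
                    resno = s$resno, value = values)
  names(tab)[4L] <- value_name
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
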