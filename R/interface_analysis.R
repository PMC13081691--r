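#' Interface residues between two chains
#'
#' A residue pair is a contact when its minimum heavy-atom distance is at or
#' below `config$interface_contact_cutoff` (5.0 Angstrom default, the
#' PISA-like definition used for residue-sharing analyses; pDockQ uses its
#' own Cbeta 8 Angstrom contacts). Output ordering is deterministic
#' (ascending residue index in A, then B).
#'
#' @param model a [complex_model()] (or `scored_complex`).
#' @param chain_a,chain_b chain ids.
#' @param config a [scoring_config()].
#' @return object of class `interface_set`: `residues` (named list of the
#'   two chains' interface residue indices) and `contacts`
#'   (data.frame `res_a`, `res_b`, `dist`).
#' @export
find_interface <- function(model, chain_a, chain_b,
                           config = scoring_config()) {
  if (inherits(model, "scored_complex")) model <- model$model
  ca <- get_chain(model, chain_a); cb <- get_chain(model, chain_b)
  xa <- chain_coords(ca); xb <- chain_coords(cb)
  D <- cross_dist(xa$xyz, xb$xyz)
  Dres <- residue_min_dist(D, xa$res_index, xb$res_index)
  ua <- unique(xa$res_index); ub <- unique(xb$res_index)
  hit <- which(Dres <= config$interface_contact_cutoff, arr.ind = TRUE)
  contacts <- data.frame(res_a = ua[hit[, 1]], res_b = ub[hit[, 2]],
                         dist = Dres[hit])
  contacts <- contacts[order(contacts$res_a, contacts$res_b), , drop = FALSE]
  rownames(contacts) <- NULL
  res <- list(sort(unique(contacts$res_a)), sort(unique(contacts$res_b)))
  names(res) <- c(chain_a, chain_b)
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 residues = res, contacts = contacts),
            class = "interface_set")
}

#' @export
print.interface_set <- function(x, ...) {
  cat(sprintf("<interface_set> %s-%s: %d contacts (%d + %d residues)\n",
              x$chain_a, x$chain_b, nrow(x$contacts),
              length(x$residues[[1]]), length(x$residues[[2]])))
  invisible(x)
}

#' Trim a paired model to annotated domains
#'
#' Removes residues outside the annotated ranges from the targeted chains and
#' slices the PAE matrix (and any bundle pLDDT) to the surviving residues in
#' their original order, so all bundle invariants still hold. Chains without
#' an annotation are kept full length. Residues keep their original author
#' numbering. Used e.g. to restrict lipid-transfer proteins to their
#' lipid-binding (ORD) domain before interface clustering.
#'
#' @param pair a `scored_complex` from [attach_confidence()] (a bare
#'   [complex_model()] is also accepted and trimmed without a bundle).
#' @param annotations data.frame with columns `protein_id` (chain id),
#'   `domain`, `start`, `end` (1-based inclusive); multiple rows per chain
#'   are unioned.
#' @return the trimmed object, same class as the input.
#' @export
trim_to_domain <- function(pair, annotations) {
  is_pair <- inherits(pair, "scored_complex")
  model <- if (is_pair) pair$model else pair
  keep_global <- logical(0)
  for (cid in names(model$chains)) {
    ch <- model$chains[[cid]]
    ann <- annotations[annotations$protein_id == cid, , drop = FALSE]
    if (nrow(ann)) {
      if (any(ann$start < 1 | ann$end < ann$start))
        stop("trim_to_domain: invalid range for chain ", cid)
      if (any(ann$end > max(ch$residues$index)))
        stop("trim_to_domain: range beyond chain ", cid, " length (",
             max(ch$residues$index), ")")
      keep <- rep(FALSE, nrow(ch$residues))
      for (k in seq_len(nrow(ann)))
        keep <- keep | (ch$residues$index >= ann$start[k] &
                        ch$residues$index <= ann$end[k])
      if (!any(keep)) stop("trim_to_domain: chain ", cid, " trimmed to nothing")
      kept_idx <- ch$residues$index[keep]
      ch$residues <- ch$residues[keep, , drop = FALSE]
      ch$atoms <- ch$atoms[ch$atoms$res_index %in% kept_idx, , drop = FALSE]
      ch$sequence <- paste(aa_three_to_one(ch$residues$name), collapse = "")
      model$chains[[cid]] <- ch
      keep_global <- c(keep_global, keep)
    } else {
      keep_global <- c(keep_global, rep(TRUE, nrow(ch$residues)))
    }
  }
  model <- validate_complex_model(model)
  if (!is_pair) return(model)
  b <- pair$bundle
  sel <- which(keep_global)
  bundle <- confidence_bundle(b$pae[sel, sel, drop = FALSE],
                              ptm = b$ptm, iptm = b$iptm,
                              plddt = if (!is.null(b$plddt)) b$plddt[sel] else NULL,
                              residue_chain = if (!is.null(b$residue_chain))
                                b$residue_chain[sel, , drop = FALSE] else NULL,
                              chain_pair_iptm = b$chain_pair_iptm)
  attach_confidence(model, bundle)
}

#' Fraction of interface residues shared between two models
#'
#' Compares the interface residue sets of two models of (possibly
#' homologous) complexes. Residues of the first interface are carried into
#' the second model's numbering through `mapping` (identity when `NULL`),
#' then two fractions are reported: the symmetric Jaccard index
#' (intersection / union) and the directional fraction
#' (intersection / size of the first interface), the reading behind
#' "shared interacting residues" statements.
#'
#' @param iface_1,iface_2 `interface_set` objects from [find_interface()].
#' @param mapping optional `residue_mapping` from [map_chains()] translating
#'   model-1 residues to model-2 residues.
#' @return list with `jaccard`, `directional`, and the mapped sets.
#' @export
shared_interface_fraction <- function(iface_1, iface_2, mapping = NULL) {
  tag <- function(iface) {
    unlist(lapply(names(iface$residues), function(cid)
      if (length(iface$residues[[cid]]))
        paste0(cid, ":", iface$residues[[cid]]) else character(0)),
      use.names = FALSE)
  }
  s1 <- tag(iface_1)
  if (!is.null(mapping)) s1 <- map_residue_tags(s1, mapping)
  s2 <- tag(iface_2)
  if (!length(s1) && !length(s2)) {
    warning("both interfaces empty; shared fraction defined as 1")
    return(list(jaccard = 1, directional = 1, set_1 = s1, set_2 = s2))
  }
  inter <- length(intersect(s1, s2))
  list(jaccard = inter / length(union(s1, s2)),
       directional = if (length(s1)) inter / length(s1) else 0,
       set_1 = s1, set_2 = s2)
}

# translate "chain:res" tags through a residue_mapping (model A -> model B);
# unmapped residues are dropped
map_residue_tags <- function(tags, mapping) {
  out <- character(0)
  for (p in mapping$pairs) {
    pref <- paste0(p$chain_a, ":")
    mine <- tags[startsWith(tags, pref)]
    if (!length(mine)) next
    res <- as.integer(sub(pref, "", mine))
    hit <- match(res, p$map$res_a)
    ok <- !is.na(hit)
    out <- c(out, paste0(p$chain_b, ":", p$map$res_b[hit[ok]]))
  }
  out
}

#' Membrane frame
#'
#' Positions of the two leaflet planes of an externally oriented membrane
#' (normal along z, as produced by membrane-positioning tools).
#'
#' @param z_upper,z_lower z coordinates (Angstrom) of the upper and lower
#'   leaflet planes; `z_upper > z_lower`.
#' @return object of class `membrane_frame`.
#' @export
membrane_frame <- function(z_upper, z_lower) {
  if (!is.finite(z_upper) || !is.finite(z_lower) || z_upper <= z_lower)
    stop("membrane_frame: z_upper must exceed z_lower")
  structure(list(z_upper = z_upper, z_lower = z_lower),
            class = "membrane_frame")
}

#' Flag membrane-proximal residues
#'
#' A residue is flagged when any of its atoms lies within
#' `config$membrane_proximity_cutoff` (3.5 Angstrom default) of the upper
#' leaflet plane, i.e. `|z - z_upper| <= cutoff`. The model must already be
#' oriented with the membrane normal along z. Proximity to the lower leaflet
#' is included with `both_leaflets = TRUE`.
#'
#' @param model a [complex_model()].
#' @param frame a [membrane_frame()].
#' @param config a [scoring_config()].
#' @param both_leaflets also test the lower leaflet plane.
#' @return data.frame `chain_id`, `index` of flagged residues.
#' @export
membrane_proximal_residues <- function(model, frame,
                                       config = scoring_config(),
                                       both_leaflets = FALSE) {
  if (inherits(model, "scored_complex")) model <- model$model
  stopifnot(inherits(frame, "membrane_frame"))
  cutoff <- config$membrane_proximity_cutoff
  out <- lapply(model$chains, function(ch) {
    near <- abs(ch$atoms$z - frame$z_upper) <= cutoff
    if (both_leaflets)
      near <- near | abs(ch$atoms$z - frame$z_lower) <= cutoff
    idx <- sort(unique(ch$atoms$res_index[near]))
    if (length(idx)) data.frame(chain_id = ch$chain_id, index = idx,
                                stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(chain_id = character(0), index = integer(0))
  rownames(out) <- NULL
  out
}

#' Export flagged residues as a PyMOL selection string
#'
#' @param flagged data.frame from [membrane_proximal_residues()].
#' @param name selection name.
#' @return single selection command string.
#' @export
pymol_selection <- function(flagged, name = "membrane_proximal") {
  if (!nrow(flagged)) return(sprintf("select %s, none", name))
  parts <- vapply(split(flagged$index, flagged$chain_id), function(i)
    paste0("resi ", paste(i, collapse = "+")), character(1))
  body <- paste(sprintf("(chain %s and %s)", names(parts), parts),
                collapse = " or ")
  sprintf("select %s, %s", name, body)
}
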