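#' Scoring configuration
#'
#' Bundles every tunable cutoff and classification band used across the
#' pipeline. Defaults follow the protocol the package implements: PAE and
#' inter-residue distance cutoffs of 15 Angstrom for ipSAE, a permissive
#' weighted ipTM+pTM threshold of 0.40, pDockQ acceptability at 0.23, and an
#' interface-lDDT network threshold of 0.80.
#'
#' @param pae_cutoff PAE cutoff (Angstrom) for ipSAE-style scores. Pairs with
#'   `PAE < pae_cutoff` (strict) count as aligned-error-supported.
#' @param dist_cutoff inter-residue distance cutoff (Angstrom) companion to
#'   `pae_cutoff`; kept for parity with the reference scoring script.
#' @param weighted_weights weights `(w_iptm, w_ptm)` of the combined
#'   confidence score, default `c(0.8, 0.2)`.
#' @param weighted_permissive permissive retention threshold on the weighted
#'   score (records with weighted score at or below it are excluded).
#' @param weighted_bands two increasing breakpoints splitting the weighted
#'   score into permissive-pass / intermediate / high bands.
#' @param iptm_bands two increasing breakpoints for raw ipTM confidence bands.
#' @param ipsae_false_max ipSAE values below this are labelled false-like.
#' @param ipsae_true_min ipSAE values above this are labelled true-like.
#' @param pdockq_bands three increasing breakpoints: acceptable / medium /
#'   high accuracy.
#' @param actifptm_bands three increasing breakpoints for the masked
#'   interface pTM labels.
#' @param lddt_edge_threshold minimum interface lDDT for a network edge.
#' @param lddt_inclusion_radius reference-distance inclusion radius (Angstrom)
#'   for interface lDDT atom pairs.
#' @param lddt_thresholds preservation tolerances (Angstrom) averaged by lDDT.
#' @param interface_contact_cutoff heavy-atom distance (Angstrom) defining an
#'   interface contact for residue-sharing analyses (PISA-like).
#' @param cb_contact_cutoff Cbeta-Cbeta contact distance (Angstrom) used by
#'   pDockQ and by the masked interface pTM interface definition.
#' @param membrane_proximity_cutoff distance (Angstrom) to the membrane plane
#'   below which a residue is flagged membrane-proximal.
#'
#' @return an object of class `scoring_config` (a validated named list).
#' @export
#' @examples
#' cfg <- scoring_config()
#' cfg$pae_cutoff
scoring_config <- function(pae_cutoff = 15,
                           dist_cutoff = 15,
                           weighted_weights = c(0.8, 0.2),
                           weighted_permissive = 0.40,
                           weighted_bands = c(0.60, 0.80),
                           iptm_bands = c(0.60, 0.75),
                           ipsae_false_max = 0.20,
                           ipsae_true_min = 0.40,
                           pdockq_bands = c(0.23, 0.49, 0.80),
                           actifptm_bands = c(0.60, 0.70, 0.80),
                           lddt_edge_threshold = 0.80,
                           lddt_inclusion_radius = 15,
                           lddt_thresholds = c(0.5, 1, 2, 4),
                           interface_contact_cutoff = 5.0,
                           cb_contact_cutoff = 8.0,
                           membrane_proximity_cutoff = 3.5) {
  cfg <- list(
    pae_cutoff = pae_cutoff, dist_cutoff = dist_cutoff,
    weighted_weights = weighted_weights,
    weighted_permissive = weighted_permissive,
    weighted_bands = weighted_bands, iptm_bands = iptm_bands,
    ipsae_false_max = ipsae_false_max, ipsae_true_min = ipsae_true_min,
    pdockq_bands = pdockq_bands, actifptm_bands = actifptm_bands,
    lddt_edge_threshold = lddt_edge_threshold,
    lddt_inclusion_radius = lddt_inclusion_radius,
    lddt_thresholds = lddt_thresholds,
    interface_contact_cutoff = interface_contact_cutoff,
    cb_contact_cutoff = cb_contact_cutoff,
    membrane_proximity_cutoff = membrane_proximity_cutoff
  )
  validate_scoring_config(cfg)
}

validate_scoring_config <- function(cfg) {
  cuts <- c("pae_cutoff", "dist_cutoff", "lddt_edge_threshold",
            "lddt_inclusion_radius", "interface_contact_cutoff",
            "cb_contact_cutoff", "membrane_proximity_cutoff",
            "weighted_permissive", "ipsae_false_max", "ipsae_true_min")
  for (k in cuts) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("scoring_config: `", k, "` must be a single positive number")
  }
  for (k in c("weighted_bands", "iptm_bands", "pdockq_bands",
              "actifptm_bands", "lddt_thresholds")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(diff(v) <= 0))
      stop("scoring_config: `", k, "` must be strictly increasing")
  }
  w <- cfg$weighted_weights
  if (length(w) != 2L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("scoring_config: `weighted_weights` must be two non-negative weights summing to 1")
  structure(cfg, class = "scoring_config")
}

#' Read or write a scoring configuration as YAML
#'
#' Flat YAML keys mirror the `scoring_config()` argument names. Unknown keys
#' are rejected with a message naming them; omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @param cfg a `scoring_config` object.
#' @return `read_config()` returns a `scoring_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(scoring_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(scoring_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scoring_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("<scoring_config>\n")
  for (k in names(x))
    cat(sprintf("  %-26s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}
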