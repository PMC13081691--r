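#' Weighted ipTM+pTM confidence score
#'
#' The screen's headline ranking score, `0.8 * ipTM + 0.2 * pTM` by default.
#'
#' @param iptm,ptm predictor summary scores in `[0, 1]`.
#' @param weights the two weights, summing to 1.
#' @return the weighted score in `[0, 1]`.
#' @export
#' @examples
#' weighted_score(0.85, 0.60) # 0.80
weighted_score <- function(iptm, ptm, weights = c(0.8, 0.2)) {
  if (any(!is.finite(c(iptm, ptm))) || any(c(iptm, ptm) < 0 | c(iptm, ptm) > 1))
    stop("weighted_score: iptm and ptm must lie in [0, 1]")
  weights[1] * iptm + weights[2] * ptm
}

#' TM-score normalization distance d0
#'
#' `d0(n) = 1.24 * (n - 15)^(1/3) - 1.8`, clamped below at 1.0 (the raw
#' expression is negative or undefined for small n). Monotone non-decreasing.
#'
#' @param n positive integer count (vectorized).
#' @return d0 in Angstrom.
#' @export
d0_of <- function(n) {
  if (any(n < 1)) stop("d0_of: n must be >= 1")
  v <- n - 15
  raw <- 1.24 * sign(v) * abs(v)^(1/3) - 1.8
  pmax(raw, 1.0)
}

# TM-style kernel
tm_kernel <- function(pae, d0) 1 / (1 + (pae / d0)^2)

# one direction of the ipSAE family from the source->target PAE block.
# P: rows = aligned residues of the source chain, cols = scored residues of
# the target chain. Returns the three variant scores plus bookkeeping.
ipsae_directional <- function(P, len_a, len_b, pae_cutoff) {
  M <- P < pae_cutoff                      # strict: ties at the cutoff excluded
  nS <- rowSums(M)
  act <- nS > 0
  n_dom <- sum(act) + sum(colSums(M) > 0)
  if (!any(act))
    return(list(ipsae = 0, d0chn = 0, d0dom = 0, n_dom = 0L))
  score_with_d0 <- function(d0) {
    K <- tm_kernel(P[act, , drop = FALSE], d0) * M[act, , drop = FALSE]
    max(rowSums(K) / nS[act])
  }
  # per-residue d0 from |S_i| (row-wise d0 vector recycles down columns)
  d0i <- d0_of(nS[act])
  Ki <- (1 / (1 + (P[act, , drop = FALSE] / d0i)^2)) * M[act, , drop = FALSE]
  list(ipsae = max(rowSums(Ki) / nS[act]),
       d0chn = score_with_d0(d0_of(len_a + len_b)),
       d0dom = score_with_d0(d0_of(n_dom)),
       n_dom = n_dom)
}

#' ipSAE interface score family from a raw PAE matrix
#'
#' Low-level entry point used by [ipsae()] and handy for scoring confidence
#' output without coordinates. For direction A->B, each residue i of chain A
#' collects the interchain pairs with `PAE(i, j) < pae_cutoff`; its score is
#' the mean TM-kernel `1 / (1 + (PAE / d0)^2)` over those pairs, and the
#' direction score is the best residue. The three variants differ only in
#' the count fed to [d0_of()]: the per-residue pair count (`ipsae`), the sum
#' of the two chain lengths (`d0chn`), or the number of residues of either
#' chain with any interchain PAE under the cutoff (`d0dom`). Directions with
#' no qualifying pair score exactly 0.
#'
#' @param pae full PAE matrix (rows: aligned residue, columns: scored).
#' @param idx_a,idx_b row/column indices of the two chains within `pae`.
#' @param pae_cutoff PAE cutoff in Angstrom (strict inequality).
#' @return list with components `ipsae`, `ipsae_d0chn`, `ipsae_d0dom`, each a
#'   named triple `(a_to_b, b_to_a, max)`, plus `n_dom` per direction.
#' @export
ipsae_from_pae <- function(pae, idx_a, idx_b, pae_cutoff = 15) {
  ab <- ipsae_directional(pae[idx_a, idx_b, drop = FALSE],
                          length(idx_a), length(idx_b), pae_cutoff)
  ba <- ipsae_directional(pae[idx_b, idx_a, drop = FALSE],
                          length(idx_b), length(idx_a), pae_cutoff)
  triple <- function(k) {
    v <- c(a_to_b = ab[[k]], b_to_a = ba[[k]])
    c(v, max = max(v))
  }
  list(ipsae = triple("ipsae"),
       ipsae_d0chn = triple("d0chn"),
       ipsae_d0dom = triple("d0dom"),
       n_dom = c(a_to_b = ab$n_dom, b_to_a = ba$n_dom))
}

#' ipSAE interface scores for a chain pair
#'
#' @param pair a `scored_complex` from [attach_confidence()].
#' @param chain_a,chain_b chain ids.
#' @param config a [scoring_config()].
#' @return see [ipsae_from_pae()].
#' @export
ipsae <- function(pair, chain_a, chain_b, config = scoring_config()) {
  stopifnot(inherits(pair, "scored_complex"))
  ipsae_from_pae(pair$bundle$pae,
                 global_indices(pair, chain_a), global_indices(pair, chain_b),
                 pae_cutoff = config$pae_cutoff)
}

#' pDockQ sigmoid
#'
#' `0.724 / (1 + exp(-0.052 * (x - 152.611))) + 0.018` with
#' `x = mean interface pLDDT * ln(number of contacts)`; the published
#' single-interface constants. Bounded in `(0.018, 0.742)`.
#'
#' @param x the pLDDT-log-contacts product.
#' @return pDockQ value (vectorized).
#' @export
pdockq_from_x <- function(x) 0.724 / (1 + exp(-0.052 * (x - 152.611))) + 0.018

#' pDockQ docking-quality estimate for a chain pair
#'
#' Contacts are interchain residue pairs whose Cbeta atoms (Calpha for
#' glycine) lie within `config$cb_contact_cutoff` (8 Angstrom). With zero
#' contacts the score is the floor 0.018.
#'
#' @inheritParams ipsae
#' @return a list with `pdockq`, `n_contacts` and `mean_plddt`.
#' @export
pdockq <- function(pair, chain_a, chain_b, config = scoring_config()) {
  model <- if (inherits(pair, "scored_complex")) pair$model else pair
  ca <- get_chain(model, chain_a); cb <- get_chain(model, chain_b)
  ra <- residue_rep_coords(ca); rb <- residue_rep_coords(cb)
  if (!nrow(ra$xyz) || !nrow(rb$xyz))
    stop("pdockq: missing CB/CA coordinates in chain ", chain_a, " or ", chain_b)
  D <- cross_dist(ra$xyz, rb$xyz)
  hit <- D <= config$cb_contact_cutoff
  n <- sum(hit)
  if (n == 0)
    return(list(pdockq = 0.018, n_contacts = 0L, mean_plddt = NA_real_))
  res_a <- ra$res_index[rowSums(hit) > 0]
  res_b <- rb$res_index[colSums(hit) > 0]
  pl <- c(ca$residues$plddt[ca$residues$index %in% res_a],
          cb$residues$plddt[cb$residues$index %in% res_b])
  x <- mean(pl) * log(n)
  list(pdockq = pdockq_from_x(x), n_contacts = as.integer(n),
       mean_plddt = mean(pl))
}

#' Interface-masked pTM (coordinate-contact approximation of actifpTM)
#'
#' An ipTM-style score restricted to the residues actually at the interface:
#' the interface set I collects residues of either chain with any interchain
#' heavy-atom distance within `config$cb_contact_cutoff`; the score is the
#' best per-residue mean of the TM kernel over interchain pairs inside I,
#' with `d0 = d0_of(|I|)`, maximized over both directions. Returns 0 when I
#' is empty. This is a coordinate-contact approximation of actifpTM, not the
#' distogram-weighted original (predictors do not expose distograms); it is
#' labelled `masked_iptm(actifpTM-approx)` in outputs.
#'
#' @inheritParams ipsae
#' @return a list with `masked_iptm` and the interface sizes per chain.
#' @export
masked_interface_ptm <- function(pair, chain_a, chain_b,
                                 config = scoring_config()) {
  stopifnot(inherits(pair, "scored_complex"))
  model <- pair$model
  ca <- get_chain(model, chain_a); cb <- get_chain(model, chain_b)
  xa <- chain_coords(ca); xb <- chain_coords(cb)
  D <- cross_dist(xa$xyz, xb$xyz)
  Dres <- residue_min_dist(D, xa$res_index, xb$res_index)
  in_a <- unique(xa$res_index)[apply(Dres <= config$cb_contact_cutoff, 1, any)]
  in_b <- unique(xb$res_index)[apply(Dres <= config$cb_contact_cutoff, 2, any)]
  if (!length(in_a) || !length(in_b))
    return(list(masked_iptm = 0, n_interface_a = 0L, n_interface_b = 0L))
  ga <- global_indices(pair, chain_a)[match(in_a, ca$residues$index)]
  gb <- global_indices(pair, chain_b)[match(in_b, cb$residues$index)]
  d0 <- d0_of(length(in_a) + length(in_b))
  pae <- pair$bundle$pae
  s_ab <- max(rowMeans(tm_kernel(pae[ga, gb, drop = FALSE], d0)))
  s_ba <- max(rowMeans(tm_kernel(pae[gb, ga, drop = FALSE], d0)))
  list(masked_iptm = max(s_ab, s_ba),
       n_interface_a = length(in_a), n_interface_b = length(in_b))
}

#' Full confidence-metric family for one chain pair
#'
#' Computes the weighted ipTM+pTM score (from the bundle's summaries),
#' the three ipSAE variants in both directions, pDockQ, the masked interface
#' pTM, the interface residue count at the PISA-like 5 Angstrom heavy-atom
#' cutoff, and the categorical band labels.
#'
#' @inheritParams ipsae
#' @return an object of class `chain_pair_scores`.
#' @export
chain_pair_scores <- function(pair, chain_a, chain_b,
                              config = scoring_config()) {
  stopifnot(inherits(pair, "scored_complex"))
  ips <- ipsae(pair, chain_a, chain_b, config)
  pq <- pdockq(pair, chain_a, chain_b, config)
  mi <- masked_interface_ptm(pair, chain_a, chain_b, config)
  iface <- find_interface(pair$model, chain_a, chain_b, config)
  w <- if (is.na(pair$bundle$iptm) || is.na(pair$bundle$ptm)) NA_real_
       else weighted_score(pair$bundle$iptm, pair$bundle$ptm,
                           config$weighted_weights)
  scores <- structure(list(
    chain_a = chain_a, chain_b = chain_b,
    iptm = pair$bundle$iptm, ptm = pair$bundle$ptm, weighted = w,
    ipsae = ips$ipsae, ipsae_d0chn = ips$ipsae_d0chn,
    ipsae_d0dom = ips$ipsae_d0dom,
    pdockq = pq$pdockq, n_contacts = pq$n_contacts,
    masked_iptm = mi$masked_iptm,
    n_interface_residues = length(iface$residues[[1]]) +
      length(iface$residues[[2]])
  ), class = "chain_pair_scores")
  scores$labels <- classify_scores(scores, config)
  scores
}

#' Classify scores into the documented confidence bands
#'
#' Bands: weighted ipTM+pTM `>0.80` high, `(0.60, 0.80]` intermediate,
#' `(0.40, 0.60]` permissive-pass, `<=0.40` fail; ipSAE (and its d0dom
#' variant) `<0.20` false-like, `>0.40` true-like, otherwise indeterminate;
#' pDockQ `<0.23` fail, `[0.23, 0.49)` acceptable, `[0.49, 0.80)` medium,
#' `>=0.80` high; masked interface pTM `>0.70` reliable, `[0.60, 0.70]`
#' intermediate, `<0.60` low.
#'
#' @param scores a `chain_pair_scores` object (or a list with the same
#'   numeric fields).
#' @param config a [scoring_config()].
#' @return named character vector of band labels.
#' @export
classify_scores <- function(scores, config = scoring_config()) {
  wb <- config$weighted_bands; perm <- config$weighted_permissive
  lab_weighted <- function(x) {
    if (is.na(x)) NA_character_
    else if (x > wb[2]) "high"
    else if (x > wb[1]) "intermediate"
    else if (x > perm) "permissive-pass"
    else "fail"
  }
  lab_ipsae <- function(x) {
    if (x < config$ipsae_false_max) "false-like"
    else if (x > config$ipsae_true_min) "true-like"
    else "indeterminate"
  }
  pb <- config$pdockq_bands
  lab_pdockq <- function(x) {
    if (x < pb[1]) "fail"
    else if (x < pb[2]) "acceptable"
    else if (x < pb[3]) "medium"
    else "high"
  }
  ab <- config$actifptm_bands
  lab_masked <- function(x) {
    if (x > ab[2]) "reliable" else if (x >= ab[1]) "intermediate" else "low"
  }
  c(weighted = lab_weighted(scores$weighted),
    ipsae = lab_ipsae(scores$ipsae[["max"]]),
    ipsae_d0dom = lab_ipsae(scores$ipsae_d0dom[["max"]]),
    pdockq = lab_pdockq(scores$pdockq),
    `masked_iptm(actifpTM-approx)` = lab_masked(scores$masked_iptm))
}

#' @export
print.chain_pair_scores <- function(x, ...) {
  cat(sprintf("<chain_pair_scores> %s-%s\n", x$chain_a, x$chain_b))
  cat(sprintf("  weighted ipTM+pTM : %s (%s)\n", format(round(x$weighted, 3)),
              x$labels[["weighted"]]))
  cat(sprintf("  ipSAE             : %.3f (d0chn %.3f, d0dom %.3f [%s])\n",
              x$ipsae[["max"]], x$ipsae_d0chn[["max"]],
              x$ipsae_d0dom[["max"]], x$labels[["ipsae_d0dom"]]))
  cat(sprintf("  pDockQ            : %.3f (%s, %d contacts)\n",
              x$pdockq, x$labels[["pdockq"]], x$n_contacts))
  cat(sprintf("  masked ipTM       : %.3f (%s)\n", x$masked_iptm,
              x$labels[["masked_iptm(actifpTM-approx)"]]))
  invisible(x)
}
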