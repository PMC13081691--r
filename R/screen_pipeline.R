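#' Run the bait-candidate triage screen
#'
#' Scores every manifest row with the full confidence-metric family and
#' applies the documented filters in order: (1) weighted ipTM+pTM must exceed
#' the permissive threshold (0.40), (2) pDockQ must reach 0.23. ipSAE bands
#' are recorded but never exclude on their own. A row that fails a filter
#' carries the first failing filter as its exclusion reason. Unreadable rows
#' are logged, recorded as failed and the screen continues (one bad model
#' never aborts a screen).
#'
#' @param manifest data.frame with columns `model_path`, `confidence_path`,
#'   `bait`, `candidate`, `method`, optional `model_id` and `replicate`
#'   (path to a manifest TSV is also accepted).
#' @param config a [scoring_config()].
#' @param localization optional annotation data.frame (`protein_id`,
#'   `compartment`) for [localization_compatibility()].
#' @param membrane optional [membrane_frame()]; with `tm_ranges` enables the
#'   membrane-plausibility flag.
#' @param tm_ranges optional data.frame (`protein_id`, `start`, `end`) of
#'   transmembrane segments, `protein_id` naming the model chain; an
#'   interface that engages a TM segment while a membrane frame is supplied
#'   is flagged implausible (never auto-excluded).
#' @return a `screen_table` data.frame (one row per manifest row) with a
#'   `provenance` attribute (config snapshot and timestamp).
#' @export
run_screen <- function(manifest, config = scoring_config(),
                       localization = NULL, membrane = NULL,
                       tm_ranges = NULL) {
  if (is.character(manifest)) manifest <- read.delim(manifest, sep = "\t",
                                                     stringsAsFactors = FALSE)
  need <- c("model_path", "confidence_path", "bait", "candidate", "method")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (is.null(manifest$replicate)) manifest$replicate <- 1L
  if (is.null(manifest$model_id))
    manifest$model_id <- tools::file_path_sans_ext(basename(manifest$model_path))
  key <- with(manifest, paste(bait, candidate, method, replicate))
  if (anyDuplicated(key))
    stop("manifest rows not unique over (bait, candidate, method, replicate)")

  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    rows[[i]] <- tryCatch(
      screen_one(m, config, localization, membrane, tm_ranges),
      error = function(e) {
        message("screen: row ", i, " (", m$model_id, ") failed: ",
                conditionMessage(e))
        failed_record(m, conditionMessage(e))
      })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(config = unclass(config),
                                  timestamp = format(Sys.time(), tz = "UTC"),
                                  n_rows = nrow(manifest))
  class(out) <- c("screen_table", "data.frame")
  out
}

screen_one <- function(m, config, localization, membrane, tm_ranges) {
  model <- read_structure(m$model_path, model_id = m$model_id,
                          source_method = if (m$method %in% c("af2m", "af3", "apd2"))
                            m$method else "synthetic")
  if (length(model$chains) < 2)
    stop("model has fewer than two chains")
  bundle <- read_confidence(m$confidence_path)
  pair <- attach_confidence(model, bundle)
  cids <- names(model$chains)[1:2]
  sc <- chain_pair_scores(pair, cids[1], cids[2], config)

  # documented filter order: weighted permissive, then pDockQ
  if (is.na(sc$weighted)) {
    decision <- "indeterminate"; reason <- "missing ptm/iptm"
  } else if (sc$weighted <= config$weighted_permissive) {
    decision <- "exclude"
    reason <- sprintf("weighted <= %.2f", config$weighted_permissive)
  } else if (sc$pdockq < config$pdockq_bands[1]) {
    decision <- "exclude"
    reason <- sprintf("pDockQ < %.2f", config$pdockq_bands[1])
  } else {
    decision <- "retain"; reason <- ""
  }

  loc <- if (is.null(localization)) "unknown"
         else localization_compatibility(c(m$bait, m$candidate), localization)
  memb <- membrane_plausibility(pair, cids, membrane, tm_ranges, config)

  data.frame(
    bait = m$bait, candidate = m$candidate, method = m$method,
    model_id = m$model_id, replicate = m$replicate,
    chain_a = cids[1], chain_b = cids[2],
    iptm = sc$iptm, ptm = sc$ptm, weighted = sc$weighted,
    ipsae_ab = sc$ipsae[["a_to_b"]], ipsae_ba = sc$ipsae[["b_to_a"]],
    ipsae = sc$ipsae[["max"]],
    ipsae_d0chn_ab = sc$ipsae_d0chn[["a_to_b"]],
    ipsae_d0chn_ba = sc$ipsae_d0chn[["b_to_a"]],
    ipsae_d0chn = sc$ipsae_d0chn[["max"]],
    ipsae_d0dom_ab = sc$ipsae_d0dom[["a_to_b"]],
    ipsae_d0dom_ba = sc$ipsae_d0dom[["b_to_a"]],
    ipsae_d0dom = sc$ipsae_d0dom[["max"]],
    pdockq = sc$pdockq, masked_iptm = sc$masked_iptm,
    n_interface_residues = sc$n_interface_residues,
    weighted_label = sc$labels[["weighted"]],
    ipsae_label = sc$labels[["ipsae"]],
    ipsae_d0dom_label = sc$labels[["ipsae_d0dom"]],
    pdockq_label = sc$labels[["pdockq"]],
    masked_iptm_label = sc$labels[["masked_iptm(actifpTM-approx)"]],
    cluster_id = NA_character_,
    localization_compatible = loc, membrane_plausible = memb,
    decision = decision, exclusion_reason = reason, status = "ok",
    stringsAsFactors = FALSE)
}

failed_record <- function(m, msg) {
  data.frame(
    bait = m$bait, candidate = m$candidate, method = m$method,
    model_id = m$model_id %||% NA_character_,
    replicate = m$replicate %||% 1L,
    chain_a = NA_character_, chain_b = NA_character_,
    iptm = NA_real_, ptm = NA_real_, weighted = NA_real_,
    ipsae_ab = NA_real_, ipsae_ba = NA_real_, ipsae = NA_real_,
    ipsae_d0chn_ab = NA_real_, ipsae_d0chn_ba = NA_real_,
    ipsae_d0chn = NA_real_,
    ipsae_d0dom_ab = NA_real_, ipsae_d0dom_ba = NA_real_,
    ipsae_d0dom = NA_real_,
    pdockq = NA_real_, masked_iptm = NA_real_,
    n_interface_residues = NA_integer_,
    weighted_label = NA_character_, ipsae_label = NA_character_,
    ipsae_d0dom_label = NA_character_, pdockq_label = NA_character_,
    masked_iptm_label = NA_character_,
    cluster_id = NA_character_,
    localization_compatible = "unknown", membrane_plausible = "unknown",
    decision = "indeterminate", exclusion_reason = msg, status = "failed",
    stringsAsFactors = FALSE)
}

# tri-state membrane-plausibility flag: "no" when the scored interface
# engages an annotated transmembrane segment while a membrane frame is given
membrane_plausibility <- function(pair, cids, membrane, tm_ranges, config) {
  if (is.null(membrane) || is.null(tm_ranges)) return("unknown")
  iface <- find_interface(pair$model, cids[1], cids[2], config)
  for (cid in cids) {
    tm <- tm_ranges[tm_ranges$protein_id == cid, , drop = FALSE]
    if (!nrow(tm)) next
    for (k in seq_len(nrow(tm))) {
      hit <- iface$residues[[cid]] >= tm$start[k] &
             iface$residues[[cid]] <= tm$end[k]
      if (any(hit)) return("no")
    }
  }
  "yes"
}

#' Subcellular-localization compatibility of a protein pair
#'
#' Two proteins are compatible ("yes") when their annotated compartment sets
#' intersect, or when both expose a cytosol-facing surface according to the
#' documented compatibility table (e.g. the cytosolic face of the ER can meet
#' cytosolic proteins, while the ER lumen is topologically isolated from the
#' cytosol). "unknown" when either protein has no annotation.
#'
#' @param pair character vector of the two protein ids.
#' @param annotations data.frame (`protein_id`, `compartment`); one row per
#'   protein-compartment assignment. Recognized compartments:
#'   `cytosol`, `ER`, `ER_lumen`, `PM`, `golgi`, `golgi_lumen`,
#'   `mitochondria_outer`, `mitochondria_matrix`, `endosome`, `nucleus`,
#'   `extracellular`.
#' @return `"yes"`, `"no"` or `"unknown"`.
#' @export
localization_compatibility <- function(pair, annotations) {
  stopifnot(length(pair) == 2)
  sets <- lapply(pair, function(p)
    annotations$compartment[annotations$protein_id == p])
  if (!length(sets[[1]]) || !length(sets[[2]])) return("unknown")
  if (length(intersect(sets[[1]], sets[[2]]))) return("yes")
  # compartments whose resident (or surface-exposed) proteins face the cytosol
  cyto_facing <- c("cytosol", "ER", "PM", "golgi", "mitochondria_outer",
                   "endosome")
  if (any(sets[[1]] %in% cyto_facing) && any(sets[[2]] %in% cyto_facing))
    return("yes")
  "no"
}

#' Assign network cluster ids to a screen table
#'
#' @param table a `screen_table`.
#' @param net a clustered `interaction_network` (see [cluster_network()]).
#' @return the table with `cluster_id` filled from the network membership.
#' @export
assign_clusters <- function(table, net) {
  if (is.null(net$membership)) net <- cluster_network(net)
  hit <- match(table$model_id, names(net$membership))
  table$cluster_id <- ifelse(is.na(hit), NA_character_,
                             net$membership[hit])
  table
}

#' Cross-method consensus report
#'
#' A bait-candidate pair is consensus-supported when retained models of that
#' pair from at least two distinct prediction methods fall in the same
#' network cluster; pairs are tiered by the number of methods that agree
#' (three > two > one). For each pair the best retained scores are reported.
#' Five-replicate predictions enter as separate rows; the best-by-weighted
#' replicate represents the pair within each method.
#'
#' @param table a `screen_table` from [run_screen()].
#' @param net an `interaction_network` over the same model set.
#' @return data.frame `bait`, `candidate`, `tier`, `n_methods_clustered`,
#'   `cluster_id`, `best_weighted`, `best_pdockq`, `methods`, sorted by tier.
#' @export
consensus_report <- function(table, net) {
  net <- if (is.null(net$membership)) cluster_network(net) else net
  table <- assign_clusters(table, net)
  kept <- table[table$decision == "retain", , drop = FALSE]
  pairs <- unique(kept[, c("bait", "candidate")])
  if (!nrow(pairs))
    return(data.frame(bait = character(0), candidate = character(0),
                      tier = character(0), n_methods_clustered = integer(0),
                      cluster_id = character(0), best_weighted = numeric(0),
                      best_pdockq = numeric(0), methods = character(0)))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    sub <- kept[kept$bait == pairs$bait[k] &
                kept$candidate == pairs$candidate[k], , drop = FALSE]
    by_cluster <- split(sub$method, sub$cluster_id)
    n_meth <- if (length(by_cluster))
      max(vapply(by_cluster, function(v) length(unique(v)), integer(1))) else 0L
    best_cluster <- if (length(by_cluster))
      names(by_cluster)[which.max(vapply(by_cluster, function(v)
        length(unique(v)), integer(1)))] else NA_character_
    tier <- c("single-method", "two-method",
              "three-method")[max(min(n_meth, 3L), 1L)]
    data.frame(bait = pairs$bait[k], candidate = pairs$candidate[k],
               tier = tier, n_methods_clustered = n_meth,
               cluster_id = best_cluster,
               best_weighted = max(sub$weighted),
               best_pdockq = max(sub$pdockq),
               methods = paste(sort(unique(sub$method)), collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_methods_clustered, -out$best_weighted), , drop = FALSE]
}

#' Write a consensus report as Markdown
#'
#' @param report data.frame from [consensus_report()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_report_md <- function(report, path) {
  lines <- c("# Consensus-supported interaction pairs", "",
             "| bait | candidate | tier | methods | best weighted | best pDockQ |",
             "|---|---|---|---|---|---|")
  for (k in seq_len(nrow(report)))
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %.3f | %.3f |",
                              report$bait[k], report$candidate[k],
                              report$tier[k], report$methods[k],
                              report$best_weighted[k], report$best_pdockq[k]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein localization annotation table
#'
#' TSV with columns `protein_id`, `compartment` (one row per assignment).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_localization <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("protein_id", "compartment") %in% names(df)))
    stop("localization table must have columns protein_id, compartment")
  df
}
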