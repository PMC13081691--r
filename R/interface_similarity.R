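# backbone + CB atom set used for interface lDDT
.lddt_atoms <- c("N", "CA", "C", "O", "CB")

get_blosum62 <- function() {
  if (is.null(.ppitriage_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ppitriage_env$BLOSUM62 <- e$BLOSUM62
  }
  .ppitriage_env$BLOSUM62
}

#' Map residues between two models by sequence alignment
#'
#' Chains are paired greedily by best global-alignment score (identical
#' sequences pair first); each paired chain couple is aligned globally
#' (BLOSUM62, gap open 11, extend 1) and only aligned (non-gap) positions
#' enter the mapping. Percent identity is identical positions over alignment
#' length (including gaps) times 100. Identical sequences yield the identity
#' mapping without invoking the aligner.
#'
#' @param model_a,model_b [complex_model()] objects.
#' @return object of class `residue_mapping`: `pairs`, a list of
#'   `(chain_a, chain_b, map = data.frame(res_a, res_b), pid)`.
#' @export
map_chains <- function(model_a, model_b) {
  if (inherits(model_a, "scored_complex")) model_a <- model_a$model
  if (inherits(model_b, "scored_complex")) model_b <- model_b$model
  ca <- names(model_a$chains); cb <- names(model_b$chains)
  sa <- vapply(model_a$chains, `[[`, character(1), "sequence")
  sb <- vapply(model_b$chains, `[[`, character(1), "sequence")
  # pairing score matrix; identical sequences get an unbeatable score
  S <- matrix(NA_real_, length(ca), length(cb), dimnames = list(ca, cb))
  aligns <- list()
  for (i in seq_along(ca)) for (j in seq_along(cb)) {
    if (sa[i] == sb[j]) {
      S[i, j] <- 1e9 + nchar(sa[i])
    } else {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(sa[i]), Biostrings::AAString(sb[j]),
        type = "global", substitutionMatrix = get_blosum62(),
        gapOpening = 11, gapExtension = 1)
      S[i, j] <- Biostrings::score(pa)
      aligns[[paste(i, j)]] <- pa
    }
  }
  pairs <- list()
  Sw <- S
  for (k in seq_len(min(length(ca), length(cb)))) {
    best <- which(Sw == max(Sw, na.rm = TRUE), arr.ind = TRUE)[1, ]
    i <- best[1]; j <- best[2]
    if (!is.finite(Sw[i, j])) break
    if (Sw[i, j] <= 0 && sa[i] != sb[j])
      warning("map_chains: chain pair ", ca[i], "-", cb[j],
              " aligned with non-positive score; mapping may be unreliable")
    pairs[[length(pairs) + 1L]] <-
      chain_pair_mapping(model_a$chains[[i]], model_b$chains[[j]],
                         aligns[[paste(i, j)]])
    Sw[i, ] <- -Inf; Sw[, j] <- -Inf
  }
  if (!length(pairs))
    stop("map_chains: no chain pairing could be aligned")
  structure(list(pairs = pairs,
                 model_a = model_a$model_id, model_b = model_b$model_id),
            class = "residue_mapping")
}

# residue-level correspondence for one paired chain couple
chain_pair_mapping <- function(chain_a, chain_b, alignment = NULL) {
  if (is.null(alignment)) {            # identical sequences: identity mapping
    stopifnot(chain_a$sequence == chain_b$sequence)
    map <- data.frame(res_a = chain_a$residues$index,
                      res_b = chain_b$residues$index)
    pid <- 100
  } else {
    p <- strsplit(as.character(Biostrings::pattern(alignment)), "")[[1]]
    s <- strsplit(as.character(Biostrings::subject(alignment)), "")[[1]]
    ai <- cumsum(p != "-"); bi <- cumsum(s != "-")
    both <- p != "-" & s != "-"
    map <- data.frame(res_a = chain_a$residues$index[ai[both]],
                      res_b = chain_b$residues$index[bi[both]])
    pid <- 100 * sum(both & p == s) / length(p)
  }
  list(chain_a = chain_a$chain_id, chain_b = chain_b$chain_id,
       map = map, pid = pid)
}

reverse_mapping <- function(mapping) {
  pairs <- lapply(mapping$pairs, function(p)
    list(chain_a = p$chain_b, chain_b = p$chain_a,
         map = data.frame(res_a = p$map$res_b, res_b = p$map$res_a),
         pid = p$pid))
  structure(list(pairs = pairs, model_a = mapping$model_b,
                 model_b = mapping$model_a),
            class = "residue_mapping")
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat(sprintf("<residue_mapping> %s -> %s\n", x$model_a, x$model_b))
  for (p in x$pairs)
    cat(sprintf("  %s-%s: %d aligned positions, %.1f%% identity\n",
                p$chain_a, p$chain_b, nrow(p$map), p$pid))
  invisible(x)
}

# one direction of the interface lDDT: ref is the reference model
lddt_directional <- function(ref, target, mapping, config) {
  radius <- config$lddt_inclusion_radius
  thr <- config$lddt_thresholds
  # per reference chain: backbone+CB coords and the mapped target coords
  chains <- list()
  for (p in mapping$pairs) {
    ch_r <- get_chain(ref, p$chain_a)
    ch_t <- get_chain(target, p$chain_b)
    cr <- chain_coords(ch_r, .lddt_atoms)
    key_t <- paste(ch_t$atoms$res_index, ch_t$atoms$atom_name)
    mapped_res <- p$map$res_b[match(cr$res_index, p$map$res_a)]
    hit <- match(paste(mapped_res, cr$atom_name), key_t)
    txyz <- cbind(ch_t$atoms$x, ch_t$atoms$y, ch_t$atoms$z)[hit, , drop = FALSE]
    chains[[p$chain_a]] <- list(ref = cr$xyz, tgt = txyz)
  }
  if (length(chains) < 2)
    stop("interface_lddt: fewer than two mapped chains")
  n_total <- 0L; n_mapped <- 0L
  preserved <- numeric(length(thr))
  cids <- names(chains)
  for (i in seq_len(length(cids) - 1)) for (j in seq(i + 1, length(cids))) {
    A <- chains[[cids[i]]]; B <- chains[[cids[j]]]
    Dref <- cross_dist(A$ref, B$ref)
    sel <- which(Dref < radius, arr.ind = TRUE)
    if (!nrow(sel)) next
    n_total <- n_total + nrow(sel)
    ta <- A$tgt[sel[, 1], , drop = FALSE]
    tb <- B$tgt[sel[, 2], , drop = FALSE]
    ok <- stats::complete.cases(ta) & stats::complete.cases(tb)
    if (!any(ok)) next
    n_mapped <- n_mapped + sum(ok)
    dd <- abs(sqrt(rowSums((ta[ok, , drop = FALSE] -
                            tb[ok, , drop = FALSE])^2)) - Dref[sel][ok])
    preserved <- preserved + vapply(thr, function(t) sum(dd < t), numeric(1))
  }
  if (n_total == 0L || n_mapped == 0L)     # this direction is undefined
    return(list(lddt = NA_real_, n_total = n_total, n_mapped = n_mapped))
  list(lddt = mean(preserved / n_mapped), n_total = n_total,
       n_mapped = n_mapped)
}

#' Superposition-free interface lDDT between two models
#'
#' Measures how closely the interacting residues of two complexes align
#' without any superposition. With model A as reference, every interchain
#' backbone/CB atom pair within the inclusion radius (15 Angstrom) is mapped
#' into model B (via `mapping`); the fraction whose distance is preserved
#' within each tolerance in `config$lddt_thresholds` (0.5, 1, 2, 4 Angstrom)
#' is averaged over tolerances. The returned score is the mean of the two
#' directions, making the edge undirected. Pairs with unmapped atoms are
#' skipped and reported through `coverage`. A direction whose reference has
#' no qualifying interchain pairs is undefined and omitted from the mean;
#' when both directions are undefined the comparison is an error (distinct
#' from a score of 0).
#'
#' @param model_a,model_b [complex_model()] objects with at least 2 chains.
#' @param mapping a `residue_mapping` from [map_chains()]; computed when
#'   `NULL`.
#' @param config a [scoring_config()].
#' @return object of class `similarity_edge` with `interface_lddt`,
#'   per-direction scores, `n_mapped_interface_pairs` and `coverage`.
#' @export
interface_lddt <- function(model_a, model_b, mapping = NULL,
                           config = scoring_config()) {
  if (inherits(model_a, "scored_complex")) model_a <- model_a$model
  if (inherits(model_b, "scored_complex")) model_b <- model_b$model
  if (length(model_a$chains) < 2 || length(model_b$chains) < 2)
    stop("interface_lddt: both models need at least two chains")
  if (is.null(mapping)) mapping <- map_chains(model_a, model_b)
  ab <- lddt_directional(model_a, model_b, mapping, config)
  ba <- lddt_directional(model_b, model_a, reverse_mapping(mapping), config)
  if (is.na(ab$lddt) && is.na(ba$lddt))
    stop("interface_lddt: no mapped interchain atom pairs within ",
         config$lddt_inclusion_radius, " Angstrom in either reference ",
         "(undefined interface)")
  structure(list(model_a = model_a$model_id, model_b = model_b$model_id,
                 interface_lddt = mean(c(ab$lddt, ba$lddt), na.rm = TRUE),
                 lddt_ab = ab$lddt, lddt_ba = ba$lddt,
                 n_mapped_interface_pairs = ab$n_mapped + ba$n_mapped,
                 coverage = (ab$n_mapped + ba$n_mapped) /
                   (ab$n_total + ba$n_total)),
            class = "similarity_edge")
}

#' @export
print.similarity_edge <- function(x, ...) {
  cat(sprintf("<similarity_edge> %s -- %s: interface lDDT %.3f (%d pairs, coverage %.2f)\n",
              x$model_a, x$model_b, x$interface_lddt,
              x$n_mapped_interface_pairs, x$coverage))
  invisible(x)
}

#' Compare two models end to end
#'
#' Convenience wrapper: [map_chains()] then [interface_lddt()].
#'
#' @inheritParams interface_lddt
#' @return a `similarity_edge`.
#' @export
compare_models <- function(model_a, model_b, config = scoring_config()) {
  interface_lddt(model_a, model_b, mapping = NULL, config = config)
}

#' All-against-all similarity edges for a set of models
#'
#' @param models list of [complex_model()] objects.
#' @param config a [scoring_config()].
#' @return data.frame `model_a`, `model_b`, `interface_lddt`, `n_pairs`.
#' @export
similarity_edges <- function(models, config = scoring_config()) {
  n <- length(models)
  rows <- list()
  for (i in seq_len(max(n - 1, 0))) for (j in seq(i + 1, n)) {
    e <- compare_models(models[[i]], models[[j]], config)
    rows[[length(rows) + 1L]] <-
      data.frame(model_a = e$model_a, model_b = e$model_b,
                 interface_lddt = e$interface_lddt,
                 n_pairs = e$n_mapped_interface_pairs,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(model_a = character(0), model_b = character(0),
                      interface_lddt = numeric(0), n_pairs = integer(0)))
  do.call(rbind, rows)
}

#' Build a thresholded interface-similarity network
#'
#' Edges with `interface_lddt >= threshold` (0.80 by default, the level used
#' to call significant structural convergence) are retained; nodes are kept
#' even when isolated.
#'
#' @param edges data.frame (`model_a`, `model_b`, `interface_lddt`,
#'   optionally `n_pairs`) or a list of `similarity_edge` objects.
#' @param nodes optional data.frame of node metadata; first column the model
#'   id, extra columns (e.g. `weighted`, `method`) become vertex attributes.
#' @param threshold minimum interface lDDT for an edge.
#' @return object of class `interaction_network` wrapping an igraph graph.
#' @export
build_network <- function(edges, nodes = NULL,
                          threshold = scoring_config()$lddt_edge_threshold) {
  if (is.list(edges) && !is.data.frame(edges) && length(edges) &&
      inherits(edges[[1]], "similarity_edge")) {
    edges <- do.call(rbind, lapply(edges, function(e)
      data.frame(model_a = e$model_a, model_b = e$model_b,
                 interface_lddt = e$interface_lddt,
                 n_pairs = e$n_mapped_interface_pairs,
                 stringsAsFactors = FALSE)))
  }
  if (is.null(edges) || !is.data.frame(edges))
    edges <- data.frame(model_a = character(0), model_b = character(0),
                        interface_lddt = numeric(0))
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$model_a, edges$model_b)))
    nodes <- data.frame(model_id = ids, stringsAsFactors = FALSE)
  }
  names(nodes)[1] <- "model_id"
  kept <- edges[edges$interface_lddt >= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(kept, directed = FALSE, vertices = nodes)
  structure(list(graph = g, threshold = threshold, edges = edges,
                 nodes = nodes, clusters = NULL),
            class = "interaction_network")
}

#' Cluster a similarity network into connected components
#'
#' Connected components of the thresholded graph, the minimal deterministic
#' reading of "clusters of complexes with similar interfaces". Clusters are
#' ordered by their smallest member id; a greedy alternative is not needed
#' for triage and is intentionally not the default.
#'
#' @param net an `interaction_network` from [build_network()].
#' @return the network with `clusters` (list of member-id vectors) and
#'   `membership` (named cluster label per model) filled in.
#' @export
cluster_network <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  comp <- igraph::components(net$graph)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, character(1), 1))]
  names(members) <- paste0("C", seq_along(members))
  membership <- setNames(rep(names(members), lengths(members)),
                         unlist(members, use.names = FALSE))
  net$clusters <- members
  net$membership <- membership
  net
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges at lDDT >= %.2f\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  if (!is.null(x$clusters))
    cat("  clusters:", paste(sprintf("%s(%d)", names(x$clusters),
                                     lengths(x$clusters)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a similarity edge list as TSV
#'
#' @param edges data.frame from [similarity_edges()].
#' @param path TSV path.
#' @return `path` invisibly.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
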