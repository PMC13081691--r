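#' Read a predicted structure into a complex model
#'
#' Parses a PDB or mmCIF file (via bio3d) into a [complex_model()]. Only
#' protein `ATOM` records are kept; per-residue pLDDT is taken from the
#' B-factor column (the AlphaFold convention) unless a confidence file later
#' supplies explicit values. Common modified residues (MSE, SEP, ...) are
#' mapped to their parent amino acid; other non-standard residues are dropped
#' with a warning.
#'
#' @param path path to the structure file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @param model_id identifier; defaults to the file name without extension.
#' @param source_method provenance tag, see [complex_model()].
#' @return a [complex_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model_id = NULL,
                           source_method = "synthetic") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  known <- atoms$resid %in% c(names(.aa3to1), names(.aa_nonstandard))
  if (any(!known)) {
    warning("dropping ", sum(!known), " atoms of non-standard residues: ",
            paste(unique(atoms$resid[!known]), collapse = ", "))
    atoms <- atoms[known, , drop = FALSE]
  }
  if (!nrow(atoms))
    stop("no protein residues in ", path, " (empty model)")
  if (is.null(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  chains <- lapply(split(atoms, factor(atoms$chain, levels = unique(atoms$chain))),
                   function(a) {
    first <- !duplicated(a$resno)
    residues <- data.frame(index = a$resno[first],
                           name = a$resid[first],
                           plddt = a$b[first],
                           stringsAsFactors = FALSE)
    new_chain(a$chain[1],
              residues = residues,
              atoms = data.frame(res_index = a$resno, atom_name = a$elety,
                                 x = a$x, y = a$y, z = a$z,
                                 stringsAsFactors = FALSE))
  })
  complex_model(model_id, chains, source_method = source_method)
}

#' Write a complex model as a PDB file
#'
#' Per-residue pLDDT is stored in the B-factor column. Coordinates keep PDB
#' precision (three decimals), so a write/read round trip agrees to 1e-3
#' Angstrom.
#'
#' @param model a [complex_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  rows <- do.call(rbind, lapply(model$chains, function(ch) {
    pl <- setNames(ch$residues$plddt, ch$residues$index)
    data.frame(chain = ch$chain_id, resno = ch$atoms$res_index,
               resid = ch$residues$name[match(ch$atoms$res_index, ch$residues$index)],
               elety = ch$atoms$atom_name,
               x = ch$atoms$x, y = ch$atoms$y, z = ch$atoms$z,
               b = unname(pl[as.character(ch$atoms$res_index)]),
               stringsAsFactors = FALSE)
  }))
  xyz <- as.numeric(t(as.matrix(rows[, c("x", "y", "z")])))
  n <- nrow(rows)
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = rows$resno, resid = rows$resid,
                   eleno = seq_len(n), elety = rows$elety,
                   chain = rows$chain, o = rep(1.0, n), b = rows$b)
  invisible(path)
}

#' Read a confidence JSON file
#'
#' Supports the two common dialects. `colabfold` (AlphaFold2-Multimer /
#' ColabFold style): residue-level PAE under `pae` or
#' `predicted_aligned_error`, optional `plddt`, `ptm`, `iptm`. `af3_server`
#' (AlphaFold3 server style): token-level `pae` plus `token_chain_ids` and
#' `token_res_ids` (and optionally `token_is_protein`); the token matrix is
#' reduced to residue level by keeping exactly one protein token per
#' (chain, residue) and discarding non-protein tokens, so the resulting
#' matrix is square over protein residues only.
#'
#' @param path JSON file path.
#' @param dialect `"colabfold"`, `"af3_server"` or `"auto"` (detected from
#'   the keys present).
#' @return a [confidence_bundle()]; `ptm`/`iptm` are `NA` when absent.
#' @export
read_confidence <- function(path, dialect = c("auto", "colabfold", "af3_server")) {
  dialect <- match.arg(dialect)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  # some tools wrap the record in a length-1 array
  if (is.data.frame(js)) js <- as.list(js[1, , drop = FALSE])
  if (dialect == "auto") {
    dialect <- if (!is.null(js$token_chain_ids)) "af3_server" else "colabfold"
  }
  if (dialect == "colabfold") {
    pae <- js$pae %||% js$predicted_aligned_error
    if (is.null(pae))
      stop("confidence dialect error: no `pae`/`predicted_aligned_error` key in ", path)
    pae <- as_pae_matrix(pae)
    confidence_bundle(pae,
                      ptm = as_scalar_or_na(js$ptm),
                      iptm = as_scalar_or_na(js$iptm),
                      plddt = if (!is.null(js$plddt)) as.numeric(js$plddt) else NULL)
  } else {
    if (is.null(js$pae))
      stop("confidence dialect error: no `pae` key in ", path)
    if (is.null(js$token_chain_ids) || is.null(js$token_res_ids))
      stop("confidence dialect error: af3_server dialect needs ",
           "`token_chain_ids` and `token_res_ids`")
    pae <- as_pae_matrix(js$pae)
    tch <- as.character(js$token_chain_ids)
    tres <- as.integer(js$token_res_ids)
    if (length(tch) != nrow(pae) || length(tres) != nrow(pae))
      stop("confidence consistency error: token metadata does not match PAE size")
    is_prot <- if (!is.null(js$token_is_protein)) as.logical(js$token_is_protein)
               else rep(TRUE, nrow(pae))
    key <- paste(tch, tres)
    keep <- is_prot & !duplicated(key) & !(key %in% key[!is_prot])
    if (!any(keep)) stop("confidence consistency error: no protein tokens left")
    pae <- pae[keep, keep, drop = FALSE]
    rc <- data.frame(chain_id = tch[keep], index = tres[keep],
                     stringsAsFactors = FALSE)
    plddt <- if (!is.null(js$token_plddts)) as.numeric(js$token_plddts)[keep] else NULL
    cpi <- if (!is.null(js$chain_pair_iptm)) as.matrix(js$chain_pair_iptm) else NULL
    confidence_bundle(pae, ptm = as_scalar_or_na(js$ptm),
                      iptm = as_scalar_or_na(js$iptm),
                      plddt = plddt, residue_chain = rc, chain_pair_iptm = cpi)
  }
}

as_pae_matrix <- function(pae) {
  if (is.list(pae) && !is.data.frame(pae)) pae <- do.call(rbind, pae)
  pae <- as.matrix(pae)
  storage.mode(pae) <- "double"
  if (nrow(pae) != ncol(pae))
    stop("confidence consistency error: PAE matrix not square (",
         nrow(pae), " x ", ncol(pae), ")")
  pae
}

as_scalar_or_na <- function(x) {
  if (is.null(x) || !length(x)) NA_real_ else as.numeric(x[[1]])
}

#' Write a confidence bundle as ColabFold-dialect JSON
#'
#' @param bundle a [confidence_bundle()].
#' @param path output JSON path.
#' @param digits number of significant digits for PAE entries.
#' @return `path` invisibly.
#' @export
write_confidence <- function(bundle, path, digits = 4) {
  obj <- list(pae = round(bundle$pae, digits))
  if (!is.null(bundle$plddt)) obj$plddt <- round(bundle$plddt, 2)
  if (!is.na(bundle$ptm)) obj$ptm <- bundle$ptm
  if (!is.na(bundle$iptm)) obj$iptm <- bundle$iptm
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

# documented column order of the screen score table
screen_table_columns <- function() {
  c("bait", "candidate", "method", "model_id", "replicate",
    "chain_a", "chain_b", "iptm", "ptm", "weighted",
    "ipsae_ab", "ipsae_ba", "ipsae",
    "ipsae_d0chn_ab", "ipsae_d0chn_ba", "ipsae_d0chn",
    "ipsae_d0dom_ab", "ipsae_d0dom_ba", "ipsae_d0dom",
    "pdockq", "masked_iptm", "n_interface_residues",
    "weighted_label", "ipsae_label", "ipsae_d0dom_label",
    "pdockq_label", "masked_iptm_label",
    "cluster_id", "localization_compatible", "membrane_plausible",
    "decision", "exclusion_reason", "status")
}

#' Write / read a screen score table as TSV
#'
#' Fixed, documented column order (see `ppitriage:::screen_table_columns()`);
#' UTF-8, tab-delimited, one header line. The round trip is lossless for all
#' fields.
#'
#' @param records a `screen_table` data.frame as returned by [run_screen()].
#' @param path TSV path.
#' @return `write_score_table()` returns `path` invisibly;
#'   `read_score_table()` returns the `screen_table` data.frame.
#' @export
write_score_table <- function(records, path) {
  if (!nrow(records)) stop("write_score_table: empty table")
  cols <- intersect(screen_table_columns(), names(records))
  out <- records[, c(cols, setdiff(names(records), cols)), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE)
  class(df) <- c("screen_table", "data.frame")
  df
}

#' Write / read an interaction network as GraphML
#'
#' Nodes carry `model_id` (vertex name), the weighted confidence score and
#' the prediction method; edges carry `interface_lddt` (and `n_pairs` when
#' available).
#'
#' @param net an `interaction_network` from [build_network()], or an igraph.
#' @param path GraphML file path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns an igraph graph.
#' @export
write_network <- function(net, path) {
  g <- if (inherits(net, "interaction_network")) net$graph else net
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read a domain annotation table
#'
#' TSV with columns `protein_id`, `domain`, `start`, `end` (1-based,
#' inclusive), e.g. the ORD-domain ranges used to trim lipid-transfer
#' proteins before interface clustering.
#'
#' @param path TSV path.
#' @return data.frame of annotations.
#' @export
read_domain_annotations <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "domain", "start", "end")
  if (!all(need %in% names(df)))
    stop("domain annotation table must have columns: ",
         paste(need, collapse = ", "))
  if (any(df$start < 1 | df$end < df$start))
    stop("invalid domain range(s): start must be >= 1 and end >= start")
  df
}
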