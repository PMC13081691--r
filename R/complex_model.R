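#' Complex model container
#'
#' In-memory representation of one predicted complex: an ordered list of
#' chains, each carrying its one-letter sequence, a residue table (index,
#' three-letter name, per-residue pLDDT on 0-100) and an atom table with
#' Cartesian coordinates in Angstrom.
#'
#' @param model_id character identifier of the model.
#' @param chains named or unnamed list of chains as built by [new_chain()];
#'   order is preserved and defines the global residue indexing.
#' @param source_method one of `"af2m"`, `"af3"`, `"apd2"`, `"synthetic"`.
#' @return an object of class `complex_model`.
#' @export
complex_model <- function(model_id, chains, source_method = "synthetic") {
  source_method <- match.arg(source_method, c("af2m", "af3", "apd2", "synthetic"))
  if (!length(chains)) stop("complex_model: at least one chain required")
  names(chains) <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(names(chains))) stop("complex_model: duplicated chain ids")
  m <- structure(list(model_id = model_id, source_method = source_method,
                      chains = chains),
                 class = "complex_model")
  validate_complex_model(m)
}

#' Build one chain of a complex model
#'
#' @param chain_id single-character (or short) chain identifier.
#' @param residues data.frame with columns `index` (positive, strictly
#'   increasing author numbering), `name` (three-letter residue code) and
#'   `plddt` (0-100).
#' @param atoms data.frame with columns `res_index` (matching
#'   `residues$index`), `atom_name`, `x`, `y`, `z`.
#' @return a list of class `model_chain` with a derived one-letter `sequence`.
#' @export
new_chain <- function(chain_id, residues, atoms) {
  residues <- as.data.frame(residues)
  atoms <- as.data.frame(atoms)
  seq1 <- paste(aa_three_to_one(residues$name), collapse = "")
  structure(list(chain_id = chain_id, sequence = seq1,
                 residues = residues, atoms = atoms),
            class = "model_chain")
}

# three-letter -> one-letter for the 20 standard residues (X otherwise)
.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.aa1to3 <- setNames(names(.aa3to1), unname(.aa3to1))
# common nonstandard residues mapped to their parent
.aa_nonstandard <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
                     SEP = "SER", TPO = "THR", PTR = "TYR", MLY = "LYS",
                     CSO = "CYS", KCX = "LYS")

aa_three_to_one <- function(x) {
  x <- toupper(x)
  x[x %in% names(.aa_nonstandard)] <- .aa_nonstandard[x[x %in% names(.aa_nonstandard)]]
  out <- .aa3to1[x]
  out[is.na(out)] <- "X"
  unname(out)
}

validate_complex_model <- function(m) {
  for (ch in m$chains) {
    r <- ch$residues
    if (!nrow(r)) stop("complex_model: chain ", ch$chain_id, " has no residues")
    if (any(diff(r$index) <= 0))
      stop("complex_model: residue indices not strictly increasing in chain ",
           ch$chain_id)
    if (any(!is.finite(r$plddt)) || any(r$plddt < 0 | r$plddt > 100))
      stop("complex_model: pLDDT outside [0, 100] in chain ", ch$chain_id)
    a <- ch$atoms
    if (any(!is.finite(a$x)) || any(!is.finite(a$y)) || any(!is.finite(a$z)))
      stop("complex_model: non-finite coordinates in chain ", ch$chain_id)
    if (!all(a$res_index %in% r$index))
      stop("complex_model: atoms referencing unknown residues in chain ", ch$chain_id)
    if (nchar(ch$sequence) != nrow(r))
      stop("complex_model: sequence length mismatch in chain ", ch$chain_id)
  }
  m
}

#' @export
print.complex_model <- function(x, ...) {
  cat("<complex_model>", x$model_id, sprintf("(%s)", x$source_method), "\n")
  for (ch in x$chains)
    cat(sprintf("  chain %s: %d residues, %d atoms\n",
                ch$chain_id, nrow(ch$residues), nrow(ch$atoms)))
  invisible(x)
}

#' Chain ids and residue counts of a complex model
#'
#' @param model a `complex_model`.
#' @return `chain_ids()`: character vector; `n_residues()`: named integer
#'   vector of per-chain residue counts.
#' @export
chain_ids <- function(model) names(model$chains)

#' @rdname chain_ids
#' @export
n_residues <- function(model) {
  vapply(model$chains, function(ch) nrow(ch$residues), integer(1))
}

get_chain <- function(model, chain_id) {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stop("chain not found: ", chain_id)
  ch
}

# n x 3 coordinate matrix of a chain's atoms (optionally a subset of names)
chain_coords <- function(ch, atom_names = NULL) {
  a <- ch$atoms
  if (!is.null(atom_names)) a <- a[a$atom_name %in% atom_names, , drop = FALSE]
  list(xyz = cbind(a$x, a$y, a$z), res_index = a$res_index,
       atom_name = a$atom_name)
}

# representative coordinate per residue: CB, falling back to CA
residue_rep_coords <- function(ch) {
  a <- ch$atoms
  keep <- a[a$atom_name %in% c("CA", "CB"), , drop = FALSE]
  out <- lapply(split(keep, factor(keep$res_index, levels = ch$residues$index)),
                function(d) {
                  if (!nrow(d)) return(c(NA_real_, NA_real_, NA_real_))
                  d <- if ("CB" %in% d$atom_name) d[d$atom_name == "CB", ][1, ]
                       else d[d$atom_name == "CA", ][1, ]
                  c(d$x, d$y, d$z)
                })
  xyz <- do.call(rbind, out)
  ok <- stats::complete.cases(xyz)
  list(xyz = xyz[ok, , drop = FALSE], res_index = ch$residues$index[ok])
}

#' Confidence bundle container
#'
#' Holds the predicted aligned error (PAE) matrix and summary confidence of
#' one model: `pae` is an N x N matrix in Angstrom over all residues (rows:
#' aligned residue i, columns: scored residue j; generally asymmetric),
#' `ptm`/`iptm` are in `[0, 1]` (NA when the source file lacks them).
#'
#' @param pae square numeric matrix, entries in `[0, 35]` Angstrom.
#' @param ptm,iptm predicted TM-score summaries, or `NA` when missing.
#' @param plddt optional per-residue pLDDT vector of length `nrow(pae)`;
#'   takes precedence over structure B-factors when attached to a model.
#' @param residue_chain optional data.frame (`chain_id`, `index`) mapping PAE
#'   rows to chains, in PAE row order.
#' @param chain_pair_iptm optional chain-by-chain ipTM matrix.
#' @return an object of class `confidence_bundle`.
#' @export
confidence_bundle <- function(pae, ptm = NA_real_, iptm = NA_real_,
                              plddt = NULL, residue_chain = NULL,
                              chain_pair_iptm = NULL) {
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae)) stop("confidence_bundle: PAE must be square")
  if (any(!is.finite(pae)) || any(pae < 0))
    stop("confidence_bundle: PAE entries must be finite and non-negative")
  if (any(pae > 35))
    stop("confidence_bundle: PAE entries above 35 Angstrom look corrupt ",
         "(unit error?)")
  for (v in list(ptm = ptm, iptm = iptm)) {
    if (!is.na(v) && (v < 0 || v > 1))
      stop("confidence_bundle: ptm/iptm must lie in [0, 1]")
  }
  if (!is.null(plddt) && length(plddt) != nrow(pae))
    stop("confidence_bundle: plddt length does not match PAE dimension")
  if (!is.null(residue_chain) && nrow(residue_chain) != nrow(pae))
    stop("confidence_bundle: residue_chain does not match PAE dimension")
  structure(list(pae = unname(pae), ptm = ptm, iptm = iptm, plddt = plddt,
                 residue_chain = residue_chain,
                 chain_pair_iptm = chain_pair_iptm),
            class = "confidence_bundle")
}

#' @export
print.confidence_bundle <- function(x, ...) {
  cat(sprintf("<confidence_bundle> %d residues, ptm=%s iptm=%s\n",
              nrow(x$pae), format(x$ptm), format(x$iptm)))
  invisible(x)
}

#' Pair a complex model with its confidence bundle
#'
#' Fixes the global residue indexing (model chain order, contiguous) shared
#' by all downstream metrics. If the bundle carries its own chain order and
#' it differs from the model's, the PAE matrix (and per-residue pLDDT) is
#' permuted to model order. Per-residue pLDDT from the confidence file, when
#' present, overrides values read from structure B-factors.
#'
#' @param model a [complex_model()].
#' @param bundle a [confidence_bundle()] over the same residues.
#' @return an object of class `scored_complex` with elements `model`,
#'   `bundle` and `index` (data.frame `global`, `chain_id`, `index`).
#' @export
attach_confidence <- function(model, bundle) {
  stopifnot(inherits(model, "complex_model"), inherits(bundle, "confidence_bundle"))
  nres <- n_residues(model)
  N <- sum(nres)
  if (nrow(bundle$pae) != N)
    stop(sprintf("attach_confidence: residue count mismatch (model %d, confidence %d)",
                 N, nrow(bundle$pae)))
  index <- data.frame(
    global = seq_len(N),
    chain_id = rep(names(nres), nres),
    index = unlist(lapply(model$chains, function(ch) ch$residues$index),
                   use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (!is.null(bundle$residue_chain)) {
    rc <- bundle$residue_chain
    if (!setequal(unique(rc$chain_id), names(nres)))
      stop("attach_confidence: confidence chain ids do not match the model")
    perm <- order(match(rc$chain_id, names(nres)), rc$index)
    if (!identical(rc$chain_id[perm], index$chain_id))
      stop("attach_confidence: per-chain residue counts disagree with the model")
    if (!all(perm == seq_len(N))) {
      bundle$pae <- bundle$pae[perm, perm, drop = FALSE]
      if (!is.null(bundle$plddt)) bundle$plddt <- bundle$plddt[perm]
      bundle$residue_chain <- rc[perm, , drop = FALSE]
    }
  }
  if (!is.null(bundle$plddt)) {
    off <- 0L
    for (cid in names(model$chains)) {
      k <- nres[[cid]]
      model$chains[[cid]]$residues$plddt <- bundle$plddt[off + seq_len(k)]
      off <- off + k
    }
    validate_complex_model(model)
  }
  structure(list(model = model, bundle = bundle, index = index),
            class = "scored_complex")
}

#' @export
print.scored_complex <- function(x, ...) {
  cat("<scored_complex>", x$model$model_id, "\n")
  print(x$model)
  print(x$bundle)
  invisible(x)
}

# global PAE row indices of one chain
global_indices <- function(pair, chain_id) {
  g <- pair$index$global[pair$index$chain_id == chain_id]
  if (!length(g)) stop("chain not found: ", chain_id)
  g
}
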