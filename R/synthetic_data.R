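# idealized alpha-helix geometry: cylindrical coordinates per backbone atom
# (radius, phase offset in degrees, z offset), rise 1.5 A, twist 100 deg/res
.helix_geom <- data.frame(
  atom_name = c("N", "CA", "C", "O", "CB"),
  r = c(1.46, 2.30, 1.65, 2.00, 3.30),
  dphi = c(-26, 0, 22, 25, -6),
  dz = c(-0.95, 0, 1.05, 2.20, -0.10),
  stringsAsFactors = FALSE
)

rot_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

transform_coords <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, t, "+")
}

transform_chain <- function(ch, R = diag(3), t = c(0, 0, 0)) {
  xyz <- transform_coords(cbind(ch$atoms$x, ch$atoms$y, ch$atoms$z), R, t)
  ch$atoms$x <- xyz[, 1]; ch$atoms$y <- xyz[, 2]; ch$atoms$z <- xyz[, 3]
  ch
}

chain_xyz <- function(ch) cbind(ch$atoms$x, ch$atoms$y, ch$atoms$z)

min_chain_dist <- function(cha, chb) min(cross_dist(chain_xyz(cha), chain_xyz(chb)))

# build one idealized helical chain along +z starting at the origin
build_helix_chain <- function(chain_id, sequence) {
  n <- nchar(sequence)
  aa1 <- strsplit(sequence, "")[[1]]
  aa3 <- unname(.aa1to3[aa1])
  rows <- lapply(seq_len(n), function(k) {
    g <- if (aa1[k] == "G") .helix_geom[.helix_geom$atom_name != "CB", ]
         else .helix_geom
    phi <- ((k - 1) * 100 + g$dphi) * pi / 180
    data.frame(res_index = k, atom_name = g$atom_name,
               x = g$r * cos(phi), y = g$r * sin(phi),
               z = (k - 1) * 1.5 + g$dz, stringsAsFactors = FALSE)
  })
  new_chain(chain_id,
            residues = data.frame(index = seq_len(n), name = aa3,
                                  plddt = 90, stringsAsFactors = FALSE),
            atoms = do.call(rbind, rows))
}

random_sequence <- function(n) {
  paste(sample(names(.aa1to3), n, replace = TRUE), collapse = "")
}

#' Specification of a synthetic predicted complex
#'
#' Declares the study conditions a generated model emulates: chain lengths,
#' docking pose, closest-approach gap, the intra-/inter-chain PAE levels with
#' their noise, and the pLDDT level. `pae_inter_base` controls the true-like
#' versus false-like character of the pair: low values mean the predictor
#' "trusts" the interface. `ptm`/`iptm`, when left `NULL`, follow a
#' documented monotone (non-physical, fixture-convention) map of
#' `pae_inter_base`: `iptm = clip(1.1 exp(-pae_inter_base / 8), 0, 0.95)` and
#' `ptm = clip(0.55 + 0.40 exp(-pae_inter_base / 8), 0, 0.97)`, each with a
#' small seeded jitter.
#'
#' @param seed integer RNG seed; the same spec always generates identical
#'   output.
#' @param chain_lengths residue counts of the chains (2-4 chains).
#' @param pose optional list (per non-reference chain) of
#'   `list(rotation = degrees about z-azimuth placement, translation = xyz)`
#'   overriding the default docking.
#' @param interface_gap closest heavy-atom approach between docked chains
#'   (Angstrom).
#' @param pae_intra_base,pae_inter_base baseline PAE (Angstrom) within and
#'   between chains.
#' @param pae_noise_sd,plddt_noise_sd Gaussian noise levels.
#' @param plddt_base baseline per-residue pLDDT.
#' @param ptm,iptm explicit summary scores; `NULL` uses the monotone map.
#' @param label `"true-like"`/`"false-like"`; derived from `pae_inter_base`
#'   (<= 10 is true-like) when `NULL`.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, chain_lengths = c(400, 300), pose = NULL,
                           interface_gap = 4.5, pae_intra_base = 2,
                           pae_inter_base = 4, pae_noise_sd = 1,
                           plddt_base = 90, plddt_noise_sd = 4,
                           ptm = NULL, iptm = NULL, label = NULL) {
  if (interface_gap <= 0) stop("synthetic_spec: interface_gap must be positive")
  if (any(c(pae_intra_base, pae_inter_base, pae_noise_sd, plddt_noise_sd) < 0))
    stop("synthetic_spec: base and noise levels must be non-negative")
  if (length(chain_lengths) < 2 || length(chain_lengths) > 4)
    stop("synthetic_spec: 2-4 chains supported")
  if (is.null(label))
    label <- if (pae_inter_base <= 10) "true-like" else "false-like"
  structure(list(seed = seed, chain_lengths = chain_lengths, pose = pose,
                 interface_gap = interface_gap,
                 pae_intra_base = pae_intra_base,
                 pae_inter_base = pae_inter_base,
                 pae_noise_sd = pae_noise_sd, plddt_base = plddt_base,
                 plddt_noise_sd = plddt_noise_sd,
                 ptm = ptm, iptm = iptm, label = label),
            class = "synthetic_spec")
}

iptm_map <- function(pae_inter_base) {
  min(max(1.1 * exp(-pae_inter_base / 8), 0), 0.95)
}
ptm_map <- function(pae_inter_base) {
  min(max(0.55 + 0.40 * exp(-pae_inter_base / 8), 0), 0.97)
}

# place chain `ch` docked against reference atoms at the given azimuth so the
# closest approach is ~gap (3 corrective iterations)
dock_chain <- function(ch, ref, gap, azimuth_deg = 0) {
  ctr_ref <- colMeans(chain_xyz(ref))
  ch <- transform_chain(ch, rot_axis(c(1, 0, 0), 180))     # antiparallel
  ch <- transform_chain(ch, t = ctr_ref - colMeans(chain_xyz(ch)))
  u <- c(cos(azimuth_deg * pi / 180), sin(azimuth_deg * pi / 180), 0)
  D <- gap + 12
  ch2 <- transform_chain(ch, t = D * u)
  for (k in 1:3) {
    m <- min_chain_dist(ref, ch2)
    D <- D + (gap - m)
    ch2 <- transform_chain(ch, t = D * u)
  }
  ch2
}

#' Generate a synthetic predicted complex with matching confidence
#'
#' Builds each chain as an idealized alpha helix (rise 1.5 Angstrom, 100
#' degree twist, Calpha radius 2.3 Angstrom; N/CA/C/O/CB atoms), docks the
#' non-reference chains at the requested closest approach, and fabricates a
#' consistent confidence bundle: PAE at `pae_intra_base` within chains and
#' `pae_inter_base` between chains plus independent Gaussian noise on (i, j)
#' and (j, i) (no symmetrization, matching real predictor output), clipped
#' to [0, 35]; pLDDT around `plddt_base`; pTM/ipTM from the spec (see
#' [synthetic_spec()]). Fully deterministic under the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @param model_id identifier of the generated model.
#' @return list with `model` ([complex_model()]), `bundle`
#'   ([confidence_bundle()]), `pair` (the attached handle) and `label`.
#' @export
make_dimer <- function(spec, model_id = sprintf("synth_seed%d", spec$seed)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    L <- spec$chain_lengths
    ids <- LETTERS[seq_along(L)]
    chains <- lapply(seq_along(L), function(k)
      build_helix_chain(ids[k], random_sequence(L[k])))
    for (k in seq_along(L)[-1]) {
      pose <- if (!is.null(spec$pose)) spec$pose[[k - 1]] else NULL
      if (is.null(pose)) {
        chains[[k]] <- dock_chain(chains[[k]], chains[[1]],
                                  gap = spec$interface_gap,
                                  azimuth_deg = (k - 2) * 120)
      } else {
        R <- rot_axis(c(0, 0, 1), pose$rotation %||% 0)
        chains[[k]] <- transform_chain(chains[[k]], R,
                                       pose$translation %||% c(0, 0, 0))
      }
    }
    N <- sum(L)
    inter <- matrix(spec$pae_inter_base, N, N)
    off <- c(0, cumsum(L))
    for (k in seq_along(L)) {
      idx <- (off[k] + 1):off[k + 1]
      inter[idx, idx] <- spec$pae_intra_base
    }
    pae <- inter + matrix(rnorm(N * N, sd = spec$pae_noise_sd), N, N)
    diag(pae) <- pmin(diag(pae), 0.5)
    pae <- pmin(pmax(pae, 0), 35)
    plddt <- pmin(pmax(spec$plddt_base + rnorm(N, sd = spec$plddt_noise_sd),
                       0), 100)
    iptm <- spec$iptm %||% min(max(iptm_map(spec$pae_inter_base) +
                                     runif(1, -0.02, 0.02), 0), 1)
    ptm <- spec$ptm %||% min(max(ptm_map(spec$pae_inter_base) +
                                   runif(1, -0.02, 0.02), 0), 1)
    off2 <- 0L
    for (k in seq_along(L)) {
      chains[[k]]$residues$plddt <- plddt[off2 + seq_len(L[k])]
      off2 <- off2 + L[k]
    }
    model <- complex_model(model_id, chains, source_method = "synthetic")
    bundle <- confidence_bundle(pae, ptm = ptm, iptm = iptm, plddt = plddt)
    list(model = model, bundle = bundle,
         pair = attach_confidence(model, bundle), label = spec$label)
  })
}

#' Apply a random rigid perturbation to one chain
#'
#' Translates the chain by `translation` Angstrom along a random direction
#' and rotates it by `rotation` degrees about a random axis through its
#' centroid. Zero magnitudes return the model unchanged. Drives
#' pose-family generation for cluster-recovery experiments.
#'
#' @param model a [complex_model()].
#' @param translation translation magnitude, Angstrom.
#' @param rotation rotation magnitude, degrees.
#' @param seed RNG seed.
#' @param chain chain id to perturb (default: the last chain).
#' @param model_id id of the perturbed model.
#' @return the perturbed [complex_model()].
#' @export
perturb_pose <- function(model, translation = 0, rotation = 0, seed = 1,
                         chain = NULL, model_id = NULL) {
  if (length(model$chains) < 2) stop("perturb_pose: need at least two chains")
  if (is.null(chain)) chain <- names(model$chains)[length(model$chains)]
  if (!is.null(model_id)) model$model_id <- model_id
  if (translation == 0 && rotation == 0) return(model)
  with_seed(seed, {
    ch <- get_chain(model, chain)
    ctr <- colMeans(chain_xyz(ch))
    axis <- rnorm(3); u <- rnorm(3); u <- u / sqrt(sum(u^2))
    R <- if (rotation != 0) rot_axis(axis, rotation) else diag(3)
    ch <- transform_chain(ch, t = -ctr)
    ch <- transform_chain(ch, R, ctr + translation * u)
    model$chains[[chain]] <- ch
    validate_complex_model(model)
  })
}

#' Write a labelled synthetic screen fixture to disk
#'
#' Emulates, at desk scale, the output of an all-against-all prediction
#' screen: for each bait-candidate pair one dimer model (PDB) and one
#' ColabFold-dialect confidence JSON, plus a manifest TSV and a ground-truth
#' label TSV. True-like pairs draw `pae_inter_base` in [2, 6] Angstrom with
#' ipTM in (0.62, 0.92); false-like pairs draw `pae_inter_base` in [20, 30]
#' with ipTM in (0.05, 0.28), so the documented screen filters separate the
#' two classes by construction.
#'
#' @param n_pairs number of bait-candidate pairs (>= 2).
#' @param frac_true fraction of true-like pairs.
#' @param seed RNG seed.
#' @param outdir output directory (created if needed).
#' @param chain_lengths per-chain residue counts of each dimer.
#' @param methods prediction-method tags cycled over the pairs.
#' @return list with `manifest` and `labels` data.frames (also written as
#'   `manifest.tsv` / `labels.tsv` in `outdir`).
#' @export
make_screen_fixture <- function(n_pairs = 24, frac_true = 0.5, seed = 1,
                                outdir = tempfile("screen_fixture_"),
                                chain_lengths = c(120, 100),
                                methods = "af2m") {
  if (n_pairs < 2) stop("make_screen_fixture: n_pairs must be >= 2")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("make_screen_fixture: cannot create ", outdir)
  n_true <- round(n_pairs * frac_true)
  with_seed(seed, {
    lab <- sample(rep(c("true-like", "false-like"),
                      c(n_true, n_pairs - n_true)))
    pair_seeds <- sample.int(.Machine$integer.max - 1, n_pairs)
    rows <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      truthy <- lab[i] == "true-like"
      spec <- synthetic_spec(
        seed = pair_seeds[i], chain_lengths = chain_lengths,
        pae_inter_base = if (truthy) runif(1, 2, 6) else runif(1, 20, 30),
        iptm = if (truthy) runif(1, 0.62, 0.92) else runif(1, 0.05, 0.28),
        ptm = if (truthy) runif(1, 0.60, 0.90) else runif(1, 0.30, 0.60),
        label = lab[i])
      mid <- sprintf("pair%02d", i)
      dm <- make_dimer(spec, model_id = mid)
      model_path <- file.path(outdir, paste0(mid, ".pdb"))
      conf_path <- file.path(outdir, paste0(mid, ".json"))
      write_structure(dm$model, model_path)
      write_confidence(dm$bundle, conf_path)
      rows[[i]] <- data.frame(
        model_id = mid, model_path = model_path, confidence_path = conf_path,
        bait = sprintf("bait%02d", i), candidate = sprintf("cand%02d", i),
        method = methods[(i - 1) %% length(methods) + 1], replicate = 1L,
        stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    labels <- data.frame(bait = manifest$bait, candidate = manifest$candidate,
                         label = lab, stringsAsFactors = FALSE)
    write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(labels, file.path(outdir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(manifest = manifest, labels = labels, outdir = outdir)
  })
}
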