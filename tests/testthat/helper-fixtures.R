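# shared fixture builders (all generated in code at test time)

# small docked dimer with attached confidence
small_dimer <- function(seed = 3, lens = c(30, 25), inter = 4,
                        noise = 1, ...) {
  make_dimer(synthetic_spec(seed = seed, chain_lengths = lens,
                            pae_inter_base = inter, pae_noise_sd = noise, ...))
}

# random PAE fixture over two chains (no coordinates needed)
random_pae_fixture <- function(seed) {
  set.seed(seed)
  la <- sample(3:40, 1); lb <- sample(3:40, 1)
  n <- la + lb
  pae <- matrix(runif(n * n, 0, 30), n, n)
  diag(pae) <- 0
  list(pae = pae, idx_a = seq_len(la), idx_b = la + seq_len(lb),
       la = la, lb = lb)
}

# rigid-body transform of a whole model
transform_model <- function(model, axis = c(1, 2, 3), deg = 30,
                            shift = c(5, -3, 9), model_id = NULL) {
  R <- ppitriage:::rot_axis(axis, deg)
  for (cid in names(model$chains))
    model$chains[[cid]] <- ppitriage:::transform_chain(model$chains[[cid]], R, shift)
  if (!is.null(model_id)) model$model_id <- model_id
  model
}

# three azimuthal pose groups of n_per perturbed copies each
make_pose_groups <- function(seed, n_groups = 3, n_per = 5,
                             lens = c(30, 25)) {
  base <- make_dimer(synthetic_spec(seed = 11, chain_lengths = lens,
                                    pae_noise_sd = 0))$model
  models <- list()
  ppitriage:::with_seed(seed, {
    pseeds <- sample.int(1e6, n_groups * n_per)
    k <- 0
    for (g in seq_len(n_groups)) {
      gm <- base
      gm$chains$B <- ppitriage:::transform_chain(
        gm$chains$B, ppitriage:::rot_axis(c(0, 0, 1), (g - 1) * 120))
      for (r in seq_len(n_per)) {
        k <- k + 1
        models[[k]] <- perturb_pose(gm, translation = runif(1, 0.05, 0.4),
                                    rotation = runif(1, 0.2, 1),
                                    seed = pseeds[k],
                                    model_id = sprintf("g%d_m%d", g, r))
      }
    }
  })
  models
}

# minimal two-chain model with one CA atom per residue at given positions
point_model <- function(xa, xb, model_id = "pts") {
  mk <- function(cid, X) {
    n <- nrow(X)
    new_chain(cid,
              residues = data.frame(index = seq_len(n), name = "GLY",
                                    plddt = 90),
              atoms = data.frame(res_index = seq_len(n), atom_name = "CA",
                                 x = X[, 1], y = X[, 2], z = X[, 3]))
  }
  complex_model(model_id, list(mk("A", xa), mk("B", xb)))
}
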