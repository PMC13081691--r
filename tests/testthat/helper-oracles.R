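# Independent brute-force oracles. These deliberately share no code with the
# package: plain double loops and direct formula transcriptions.

oracle_d0 <- function(n) {
  if (n >= 15) max(1.0, 1.24 * (n - 15)^(1/3) - 1.8) else 1.0
}

# one direction of the ipSAE family by explicit loops.
# P: source-by-target PAE block (rows aligned residue of the source chain).
oracle_ipsae_dir <- function(P, len_a, len_b, cutoff) {
  any_row <- apply(P, 1, function(r) any(r < cutoff))
  any_col <- apply(P, 2, function(cc) any(cc < cutoff))
  n_dom <- sum(any_row) + sum(any_col)
  best <- c(ipsae = 0, d0chn = 0, d0dom = 0)
  for (i in seq_len(nrow(P))) {
    S <- which(P[i, ] < cutoff)
    if (!length(S)) next
    for (variant in names(best)) {
      d0 <- switch(variant,
                   ipsae = oracle_d0(length(S)),
                   d0chn = oracle_d0(len_a + len_b),
                   d0dom = oracle_d0(n_dom))
      acc <- 0
      for (j in S) acc <- acc + 1 / (1 + (P[i, j] / d0)^2)
      best[variant] <- max(best[variant], acc / length(S))
    }
  }
  best
}

oracle_ipsae <- function(pae, idx_a, idx_b, cutoff = 15) {
  ab <- oracle_ipsae_dir(pae[idx_a, idx_b, drop = FALSE],
                         length(idx_a), length(idx_b), cutoff)
  ba <- oracle_ipsae_dir(pae[idx_b, idx_a, drop = FALSE],
                         length(idx_b), length(idx_a), cutoff)
  list(ab = ab, ba = ba, max = pmax(ab, ba))
}

# flat atom table of a model chain
atom_table <- function(model, chain_id, atoms = NULL) {
  a <- model$chains[[chain_id]]$atoms
  if (!is.null(atoms)) a <- a[a$atom_name %in% atoms, , drop = FALSE]
  a
}

# brute-force residue-pair contact list at a heavy-atom cutoff
oracle_contacts <- function(model, ca, cb, cutoff) {
  A <- atom_table(model, ca); B <- atom_table(model, cb)
  out <- NULL
  for (ra in unique(A$res_index)) for (rb in unique(B$res_index)) {
    aa <- A[A$res_index == ra, ]; bb <- B[B$res_index == rb, ]
    dmin <- Inf
    for (i in seq_len(nrow(aa))) for (j in seq_len(nrow(bb)))
      dmin <- min(dmin, sqrt(sum((c(aa$x[i], aa$y[i], aa$z[i]) -
                                  c(bb$x[j], bb$y[j], bb$z[j]))^2)))
    if (dmin <= cutoff)
      out <- rbind(out, data.frame(res_a = ra, res_b = rb, dist = dmin))
  }
  out
}

# brute-force symmetrized interface lDDT for two-chain models related by the
# identity residue mapping (same sequences, same numbering)
oracle_lddt_dir <- function(ref, tgt, radius = 15, thr = c(0.5, 1, 2, 4)) {
  cids <- names(ref$chains)
  A <- atom_table(ref, cids[1], c("N", "CA", "C", "O", "CB"))
  B <- atom_table(ref, cids[2], c("N", "CA", "C", "O", "CB"))
  At <- atom_table(tgt, cids[1]); Bt <- atom_table(tgt, cids[2])
  n_mapped <- 0; hits <- numeric(length(thr))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    dA <- sqrt(sum((c(A$x[i], A$y[i], A$z[i]) - c(B$x[j], B$y[j], B$z[j]))^2))
    if (dA >= radius) next
    ti <- which(At$res_index == A$res_index[i] & At$atom_name == A$atom_name[i])
    tj <- which(Bt$res_index == B$res_index[j] & Bt$atom_name == B$atom_name[j])
    if (!length(ti) || !length(tj)) next
    n_mapped <- n_mapped + 1
    dB <- sqrt(sum((c(At$x[ti], At$y[ti], At$z[ti]) -
                    c(Bt$x[tj], Bt$y[tj], Bt$z[tj]))^2))
    hits <- hits + as.numeric(abs(dA - dB) < thr)
  }
  mean(hits / n_mapped)
}

oracle_lddt <- function(ma, mb) {
  mean(c(oracle_lddt_dir(ma, mb), oracle_lddt_dir(mb, ma)))
}

# brute-force masked interface pTM (interface by heavy-atom <= cutoff)
oracle_masked_ptm <- function(model, pae, ca, cb, cutoff = 8) {
  A <- atom_table(model, ca); B <- atom_table(model, cb)
  la <- model$chains[[ca]]$residues$index
  lb <- model$chains[[cb]]$residues$index
  in_a <- c(); in_b <- c()
  for (ra in la) for (rb in lb) {
    aa <- A[A$res_index == ra, ]; bb <- B[B$res_index == rb, ]
    D <- outer(seq_len(nrow(aa)), seq_len(nrow(bb)), Vectorize(function(i, j)
      sqrt(sum((c(aa$x[i], aa$y[i], aa$z[i]) - c(bb$x[j], bb$y[j], bb$z[j]))^2))))
    if (min(D) <= cutoff) { in_a <- union(in_a, ra); in_b <- union(in_b, rb) }
  }
  if (!length(in_a) || !length(in_b)) return(0)
  ga <- match(in_a, la); gb <- length(la) + match(in_b, lb)
  d0 <- oracle_d0(length(in_a) + length(in_b))
  best <- 0
  for (i in ga) best <- max(best, mean(1 / (1 + (pae[i, gb] / d0)^2)))
  for (j in gb) best <- max(best, mean(1 / (1 + (pae[j, ga] / d0)^2)))
  best
}

# Eisenberg moment via complex arithmetic (independent of the package's
# trigonometric form)
oracle_moment <- function(h, delta = 100) {
  z <- sum(h * exp(1i * (seq_along(h) - 1) * delta * pi / 180))
  Mod(z) / length(h)
}

# connected components by naive label propagation
oracle_components <- function(nodes, edges) {
  lab <- setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$model_a[k]; b <- edges$model_b[k]
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) { lab[a] <- m; lab[b] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  unname(split(nodes, lab[nodes]))
}
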