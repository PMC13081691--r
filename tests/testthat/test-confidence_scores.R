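test_that("weighted score is the stated linear combination and rejects bad input", {
  expect_equal(weighted_score(1, 1), 1)
  expect_equal(weighted_score(0, 0), 0)
  expect_equal(weighted_score(0.85, 0.60), 0.8 * 0.85 + 0.2 * 0.60)
  # exact linearity: w(a,b) + w(c,d) = w(a+c, b+d) for in-range sums
  set.seed(42)
  for (k in 1:20) {
    a <- runif(1, 0, 0.5); b <- runif(1, 0, 0.5)
    c_ <- runif(1, 0, 0.5); d <- runif(1, 0, 0.5)
    expect_equal(weighted_score(a, b) + weighted_score(c_, d),
                 weighted_score(a + c_, b + d))
  }
  expect_error(weighted_score(1.2, 0.5), "\\[0, 1\\]")
  expect_error(weighted_score(0.5, -0.1), "\\[0, 1\\]")
})

test_that("d0 follows the clamped TM-score form and is monotone", {
  expect_equal(d0_of(19), 1.0)                       # raw value clamped
  expect_equal(d0_of(1000), 1.24 * 985^(1/3) - 1.8)  # closed form
  expect_error(d0_of(0), ">= 1")
  v <- d0_of(1:500)
  expect_true(all(diff(v) >= 0))
})

test_that("ipSAE matches the brute-force double-loop oracle on a hand fixture", {
  # 3x3 interchain PAE, LA = LB = 3
  P <- matrix(c(2, 20, 20, 20, 4, 20, 20, 20, 6), 3, 3, byrow = TRUE)
  pae <- matrix(30, 6, 6)
  pae[1:3, 4:6] <- P
  pae[4:6, 1:3] <- t(P)
  got <- ipsae_from_pae(pae, 1:3, 4:6, pae_cutoff = 15)
  exp <- oracle_ipsae(pae, 1:3, 4:6, cutoff = 15)
  for (v in c("ipsae", "ipsae_d0chn", "ipsae_d0dom")) {
    ov <- sub("ipsae_?", "", v); ov <- if (ov == "") "ipsae" else ov
    expect_equal(got[[v]][["a_to_b"]], unname(exp$ab[[ov]]), tolerance = 1e-12)
    expect_equal(got[[v]][["b_to_a"]], unname(exp$ba[[ov]]), tolerance = 1e-12)
    expect_equal(got[[v]][["max"]],
                 max(got[[v]][["a_to_b"]], got[[v]][["b_to_a"]]))
  }
})

test_that("ipSAE returns exactly 0 when no interchain PAE beats the cutoff", {
  fx <- random_pae_fixture(5)
  pae <- fx$pae
  pae[fx$idx_a, fx$idx_b] <- 15   # ties at the cutoff are excluded (strict <)
  pae[fx$idx_b, fx$idx_a] <- 22
  got <- ipsae_from_pae(pae, fx$idx_a, fx$idx_b, pae_cutoff = 15)
  expect_identical(got$ipsae[["max"]], 0)
  expect_identical(got$ipsae_d0chn[["max"]], 0)
  expect_identical(got$ipsae_d0dom[["max"]], 0)
})

test_that("ipSAE is 1 when every interchain PAE is 0", {
  pae <- matrix(0, 8, 8)
  got <- ipsae_from_pae(pae, 1:4, 5:8)
  expect_equal(got$ipsae[["max"]], 1)
  expect_equal(got$ipsae_d0chn[["max"]], 1)
  expect_equal(got$ipsae_d0dom[["max"]], 1)
})

test_that("adding a constant to all interchain PAE never increases any ipSAE variant", {
  for (seed in 1:5) {
    fx <- random_pae_fixture(seed)
    base <- ipsae_from_pae(fx$pae, fx$idx_a, fx$idx_b)
    for (eps in c(0.5, 2, 5)) {
      pae2 <- fx$pae
      pae2[fx$idx_a, fx$idx_b] <- pmin(pae2[fx$idx_a, fx$idx_b] + eps, 35)
      pae2[fx$idx_b, fx$idx_a] <- pmin(pae2[fx$idx_b, fx$idx_a] + eps, 35)
      bumped <- ipsae_from_pae(pae2, fx$idx_a, fx$idx_b)
      for (v in c("ipsae", "ipsae_d0chn", "ipsae_d0dom"))
        expect_lte(bumped[[v]][["max"]], base[[v]][["max"]] + 1e-12)
    }
  }
})

test_that("pDockQ has the documented floor, midpoint and asymptote", {
  expect_equal(pdockq_from_x(152.611), 0.724 / 2 + 0.018, tolerance = 1e-9)
  expect_lt(pdockq_from_x(600), 0.742)
  expect_gt(pdockq_from_x(600), 0.742 - 1e-6)
  x <- seq(0, 400, by = 5)
  expect_true(all(diff(pdockq_from_x(x)) > 0))
  # zero contacts on separated chains -> floor
  dm <- small_dimer(seed = 8, lens = c(12, 10))
  far <- dm$model
  far$chains$B <- ppitriage:::transform_chain(far$chains$B, t = c(100, 0, 0))
  expect_equal(pdockq(far, "A", "B")$pdockq, 0.018)
})

test_that("pDockQ on a docked dimer uses mean interface pLDDT times log contacts", {
  dm <- small_dimer(seed = 8, lens = c(12, 10))
  got <- pdockq(dm$pair, "A", "B")
  expect_gt(got$n_contacts, 0)
  x <- got$mean_plddt * log(got$n_contacts)
  expect_equal(got$pdockq, 0.724 / (1 + exp(-0.052 * (x - 152.611))) + 0.018)
})

test_that("masked interface pTM matches the brute-force oracle and edge cases", {
  dm <- small_dimer(seed = 13, lens = c(6, 6))
  got <- masked_interface_ptm(dm$pair, "A", "B")
  expect_equal(got$masked_iptm,
               oracle_masked_ptm(dm$model, dm$pair$bundle$pae, "A", "B"),
               tolerance = 1e-12)
  # empty interface -> 0
  far <- dm$model
  far$chains$B <- ppitriage:::transform_chain(far$chains$B, t = c(100, 0, 0))
  pf <- attach_confidence(far, dm$bundle)
  expect_identical(masked_interface_ptm(pf, "A", "B")$masked_iptm, 0)
  # PAE uniformly 0 over a non-empty interface -> 1
  zero <- attach_confidence(dm$model,
                            confidence_bundle(matrix(0, 12, 12),
                                              ptm = 0.8, iptm = 0.8))
  expect_equal(masked_interface_ptm(zero, "A", "B")$masked_iptm, 1)
})

test_that("scores are invariant under rigid motion and PAE-consistent reindexing", {
  dm <- small_dimer(seed = 21, lens = c(10, 9))
  moved <- transform_model(dm$model)
  pm <- attach_confidence(moved, dm$bundle)
  expect_equal(pdockq(pm, "A", "B")$pdockq, pdockq(dm$pair, "A", "B")$pdockq)
  expect_equal(masked_interface_ptm(pm, "A", "B")$masked_iptm,
               masked_interface_ptm(dm$pair, "A", "B")$masked_iptm)
  # bundle stored in B-then-A order with permuted PAE: attach restores it
  n <- sum(n_residues(dm$model))
  perm <- c(11:19, 1:10)   # B first, then A
  rc <- data.frame(chain_id = rep(c("B", "A"), c(9, 10)),
                   index = c(1:9, 1:10))
  swapped <- confidence_bundle(dm$bundle$pae[perm, perm],
                               ptm = dm$bundle$ptm, iptm = dm$bundle$iptm,
                               residue_chain = rc)
  ps <- attach_confidence(dm$model, swapped)
  expect_equal(ipsae(ps, "A", "B"), ipsae(dm$pair, "A", "B"))
})

test_that("band classification follows the documented thresholds", {
  cfg <- scoring_config()
  mk <- function(w, ip, ipd, pq, mi)
    list(weighted = w, ipsae = c(max = ip), ipsae_d0dom = c(max = ipd),
         pdockq = pq, masked_iptm = mi)
  lab <- classify_scores(mk(0.85, 0.5, 0.15, 0.50, 0.75), cfg)
  expect_equal(unname(lab[["weighted"]]), "high")
  expect_equal(unname(lab[["ipsae"]]), "true-like")
  expect_equal(unname(lab[["ipsae_d0dom"]]), "false-like")
  expect_equal(unname(lab[["pdockq"]]), "medium")
  expect_equal(unname(lab[["masked_iptm(actifpTM-approx)"]]), "reliable")
  lab2 <- classify_scores(mk(0.35, 0.3, 0.3, 0.20, 0.60), cfg)
  expect_equal(unname(lab2[["weighted"]]), "fail")
  expect_equal(unname(lab2[["ipsae"]]), "indeterminate")
  expect_equal(unname(lab2[["pdockq"]]), "fail")
  expect_equal(unname(lab2[["masked_iptm(actifpTM-approx)"]]), "intermediate")
  lab3 <- classify_scores(mk(0.55, 0.1, 0.5, 0.30, 0.2), cfg)
  expect_equal(unname(lab3[["weighted"]]), "permissive-pass")
  expect_equal(unname(lab3[["pdockq"]]), "acceptable")
  expect_equal(unname(lab3[["masked_iptm(actifpTM-approx)"]]), "low")
})
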