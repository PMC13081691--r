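test_that("the screen applies the documented filters with the right reasons", {
  out <- withr::local_tempdir()
  fx <- make_screen_fixture(8, 0.5, seed = 11, outdir = out,
                            chain_lengths = c(30, 25))
  tab <- run_screen(fx$manifest)
  expect_s3_class(tab, "screen_table")
  expect_equal(nrow(tab), 8)
  truthy <- fx$labels$label == "true-like"
  expect_identical(tab$decision[truthy], rep("retain", sum(truthy)))
  expect_identical(tab$decision[!truthy], rep("exclude", sum(!truthy)))
  expect_identical(unique(tab$exclusion_reason[!truthy]), "weighted <= 0.40")
  # retained records honor the invariant: weighted above permissive AND
  # pDockQ at least acceptable
  kept <- tab[tab$decision == "retain", ]
  expect_true(all(kept$weighted > 0.40 & kept$pdockq >= 0.23))
  expect_true(all(tab$exclusion_reason[tab$decision == "exclude"] != ""))
})

test_that("pDockQ filter catches well-ranked models with bad interfaces", {
  out <- withr::local_tempdir()
  # docked geometry but confident summaries with terrible local accuracy:
  # force a low-contact, low-pLDDT interface so pDockQ drops below 0.23
  dm <- make_dimer(synthetic_spec(seed = 2, chain_lengths = c(12, 10),
                                  interface_gap = 7.5, pae_inter_base = 5,
                                  plddt_base = 30, plddt_noise_sd = 0,
                                  iptm = 0.8, ptm = 0.7),
                   model_id = "lowq")
  write_structure(dm$model, file.path(out, "lowq.pdb"))
  write_confidence(dm$bundle, file.path(out, "lowq.json"))
  manifest <- data.frame(model_id = "lowq",
                         model_path = file.path(out, "lowq.pdb"),
                         confidence_path = file.path(out, "lowq.json"),
                         bait = "b", candidate = "c", method = "af2m",
                         replicate = 1L)
  tab <- run_screen(manifest)
  expect_lt(tab$pdockq, 0.23)
  expect_identical(tab$decision, "exclude")
  expect_identical(tab$exclusion_reason, "pDockQ < 0.23")
})

test_that("a broken manifest row is recorded as failed without aborting the screen", {
  out <- withr::local_tempdir()
  fx <- make_screen_fixture(3, 1, seed = 5, outdir = out,
                            chain_lengths = c(25, 20))
  manifest <- fx$manifest
  manifest$model_path[2] <- file.path(out, "missing.pdb")
  expect_message(tab <- run_screen(manifest), "failed")
  expect_identical(tab$status, c("ok", "failed", "ok"))
  expect_identical(tab$decision[2], "indeterminate")
  expect_identical(tab$decision[c(1, 3)], c("retain", "retain"))
})

test_that("screening is deterministic for a fixed manifest", {
  out <- withr::local_tempdir()
  fx <- make_screen_fixture(4, 0.5, seed = 9, outdir = out,
                            chain_lengths = c(25, 20))
  t1 <- run_screen(fx$manifest)
  t2 <- run_screen(fx$manifest)
  attr(t1, "provenance") <- attr(t2, "provenance") <- NULL
  expect_identical(t1, t2)
})

test_that("localization compatibility implements the topology rules", {
  ann <- data.frame(
    protein_id = c("sac1", "orp11", "lumP", "unkP", "secA"),
    compartment = c("ER", "cytosol", "ER_lumen", "cytosol", "extracellular"))
  expect_identical(localization_compatibility(c("sac1", "orp11"), ann), "yes")
  expect_identical(localization_compatibility(c("lumP", "orp11"), ann), "no")
  expect_identical(localization_compatibility(c("sac1", "absent"), ann),
                   "unknown")
  expect_identical(localization_compatibility(c("secA", "orp11"), ann), "no")
  # shared compartment always compatible
  ann2 <- rbind(ann, data.frame(protein_id = "lumP2",
                                compartment = "ER_lumen"))
  expect_identical(localization_compatibility(c("lumP", "lumP2"), ann2), "yes")
})

test_that("membrane plausibility flags TM-engaged interfaces", {
  dm <- small_dimer(seed = 3, lens = c(20, 18))
  iface <- find_interface(dm$model, "A", "B")
  tm_hit <- data.frame(protein_id = "A", start = min(iface$residues$A),
                       end = min(iface$residues$A))
  tm_miss <- data.frame(protein_id = "A", start = 1000, end = 1001)
  frame <- membrane_frame(50, 10)
  expect_identical(
    ppitriage:::membrane_plausibility(dm$pair, c("A", "B"), frame, tm_hit,
                                      scoring_config()), "no")
  expect_identical(
    ppitriage:::membrane_plausibility(dm$pair, c("A", "B"), frame, tm_miss,
                                      scoring_config()), "yes")
  expect_identical(
    ppitriage:::membrane_plausibility(dm$pair, c("A", "B"), NULL, tm_hit,
                                      scoring_config()), "unknown")
})

test_that("consensus tiers require retained models of >= 2 methods in one cluster", {
  tab <- data.frame(
    bait = "sac1", candidate = c("orp11", "orp11", "orp11", "orp3"),
    method = c("af2m", "af3", "apd2", "af2m"),
    model_id = c("m1", "m2", "m3", "m4"), replicate = 1L,
    weighted = c(0.8, 0.75, 0.7, 0.6), pdockq = c(0.4, 0.45, 0.3, 0.3),
    decision = c("retain", "retain", "retain", "retain"),
    cluster_id = NA_character_, stringsAsFactors = FALSE)
  class(tab) <- c("screen_table", "data.frame")
  edges <- data.frame(model_a = c("m1", "m2"), model_b = c("m2", "m3"),
                      interface_lddt = c(0.9, 0.85))
  net <- cluster_network(build_network(
    edges, nodes = data.frame(model_id = paste0("m", 1:4)), threshold = 0.8))
  rep <- consensus_report(tab, net)
  top <- rep[rep$candidate == "orp11", ]
  expect_identical(top$tier, "three-method")
  expect_equal(top$n_methods_clustered, 3L)
  expect_equal(top$best_weighted, 0.8)
  lone <- rep[rep$candidate == "orp3", ]
  expect_identical(lone$tier, "single-method")
  # models of the same pair in different clusters are not consensus
  edges2 <- data.frame(model_a = "m1", model_b = "m4",
                       interface_lddt = 0.9)
  net2 <- cluster_network(build_network(
    edges2, nodes = data.frame(model_id = paste0("m", 1:4)), threshold = 0.8))
  rep2 <- consensus_report(tab, net2)
  expect_equal(rep2$n_methods_clustered[rep2$candidate == "orp11"], 1L)
  # empty network: every pair at single-method tier
  net3 <- cluster_network(build_network(
    edges2[0, ], nodes = data.frame(model_id = paste0("m", 1:4))))
  rep3 <- consensus_report(tab, net3)
  expect_true(all(rep3$tier == "single-method"))
})
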