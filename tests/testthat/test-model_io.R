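test_that("structure write/read round-trips coordinates and pLDDT at PDB precision", {
  dm <- small_dimer(seed = 5, lens = c(12, 10))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(dm$model, f)
  m2 <- read_structure(f)
  expect_identical(chain_ids(m2), chain_ids(dm$model))
  expect_identical(unname(n_residues(m2)), unname(n_residues(dm$model)))
  for (cid in chain_ids(m2)) {
    a1 <- dm$model$chains[[cid]]$atoms; a2 <- m2$chains[[cid]]$atoms
    expect_equal(cbind(a2$x, a2$y, a2$z), cbind(a1$x, a1$y, a1$z),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(m2$chains[[cid]]$residues$plddt,
                 round(dm$model$chains[[cid]]$residues$plddt, 2))
    expect_identical(m2$chains[[cid]]$sequence, dm$model$chains[[cid]]$sequence)
  }
})

test_that("B-factor column becomes per-residue pLDDT", {
  dm <- small_dimer(seed = 6, lens = c(8, 8))
  for (cid in chain_ids(dm$model))
    dm$model$chains[[cid]]$residues$plddt <- 90.0
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(dm$model, f)
  m2 <- read_structure(f)
  expect_true(all(unlist(lapply(m2$chains, function(ch) ch$residues$plddt)) == 90))
})

test_that("a structure without protein residues is an empty-model error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00",
    "END"), f)
  expect_error(read_structure(f), "empty model|no protein")
})

test_that("colabfold confidence JSON maps directly to the bundle", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pae = matrix(c(0, 5, 6, 0), 2, 2, byrow = TRUE),
                            ptm = 0.5, iptm = 0.4, plddt = c(80, 85)),
                       f, auto_unbox = TRUE, matrix = "rowmajor")
  b <- read_confidence(f)
  expect_equal(dim(b$pae), c(2L, 2L))
  expect_equal(b$pae[1, 2], 5)
  expect_equal(b$pae[2, 1], 6)
  expect_equal(b$ptm, 0.5)
  expect_equal(b$plddt, c(80, 85))
})

test_that("AF3-server token PAE reduces to protein residues only", {
  # 3 protein residues with a ligand token interleaved: hand-enumerated indices
  pae <- matrix(c(0, 1, 2, 3,
                  4, 0, 5, 6,
                  7, 8, 0, 9,
                  1, 2, 3, 0), 4, 4, byrow = TRUE)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pae = pae,
                            token_chain_ids = c("A", "A", "L", "B"),
                            token_res_ids = c(1, 2, 1, 1),
                            token_is_protein = c(TRUE, TRUE, FALSE, TRUE),
                            ptm = 0.8, iptm = 0.7),
                       f, auto_unbox = TRUE, matrix = "rowmajor")
  b <- read_confidence(f)
  expect_equal(nrow(b$pae), 3L)
  expect_equal(b$pae[1, 3], 3)  # A1 -> B1 skips the ligand row/col
  expect_equal(b$pae[2, 3], 6)
  expect_equal(b$residue_chain$chain_id, c("A", "A", "B"))
})

test_that("the two dialects encode identical content identically", {
  pae <- matrix(runif(25, 0, 20), 5, 5); diag(pae) <- 0
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pae = pae, ptm = 0.6, iptm = 0.5),
                       f1, auto_unbox = TRUE, matrix = "rowmajor", digits = NA)
  jsonlite::write_json(list(pae = pae,
                            token_chain_ids = rep(c("A", "B"), c(3, 2)),
                            token_res_ids = c(1:3, 1:2),
                            ptm = 0.6, iptm = 0.5),
                       f2, auto_unbox = TRUE, matrix = "rowmajor", digits = NA)
  b1 <- read_confidence(f1); b2 <- read_confidence(f2)
  expect_equal(b1$pae, b2$pae)
  expect_equal(b1$ptm, b2$ptm)
  expect_equal(b1$iptm, b2$iptm)
})

test_that("missing PAE key is a dialect error; oversized PAE is rejected", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(plddt = c(90, 90)), f, auto_unbox = TRUE)
  expect_error(read_confidence(f), "dialect error")
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pae = matrix(c(0, 40, 40, 0), 2, 2)),
                       f2, matrix = "rowmajor")
  expect_error(read_confidence(f2), "corrupt")
})

test_that("attach pairs by residue count and reports both counts on mismatch", {
  dm <- small_dimer(seed = 9, lens = c(10, 12))
  expect_s3_class(attach_confidence(dm$model, dm$bundle), "scored_complex")
  short <- confidence_bundle(matrix(1, 21, 21), ptm = 0.5, iptm = 0.5)
  expect_error(attach_confidence(dm$model, short), "22.*21|21.*22")
})

test_that("score table TSV round-trips and keeps the documented header order", {
  fx <- make_screen_fixture(4, 0.5, seed = 3, outdir = withr::local_tempdir(),
                            chain_lengths = c(25, 20))
  tab <- run_screen(fx$manifest)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, f)
  lines <- readLines(f)
  expect_length(lines, nrow(tab) + 1L)
  expect_identical(strsplit(lines[1], "\t")[[1]],
                   ppitriage:::screen_table_columns())
  back <- read_score_table(f)
  expect_equal(back$weighted, tab$weighted, tolerance = 1e-9)
  expect_identical(back$decision, tab$decision)
  expect_identical(back$exclusion_reason, tab$exclusion_reason)
  expect_error(write_score_table(tab[0, ], f), "empty")
})

test_that("network GraphML round-trips node and edge attributes", {
  edges <- data.frame(model_a = c("m1", "m2"), model_b = c("m2", "m3"),
                      interface_lddt = c(0.9, 0.82), n_pairs = c(10L, 12L))
  nodes <- data.frame(model_id = c("m1", "m2", "m3", "m4"),
                      weighted = c(0.9, 0.8, 0.7, 0.5),
                      method = c("af2m", "af3", "apd2", "af2m"))
  net <- build_network(edges, nodes, threshold = 0.8)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, f)
  g <- read_network(f)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$interface_lddt, c(0.9, 0.82))
  expect_setequal(igraph::V(g)$weighted, nodes$weighted)
})
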