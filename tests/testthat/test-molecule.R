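test_that("conformer embedding is deterministic and failure is an outcome", {
  a <- embed_conformer("[C][C][O]", seed = 1)
  b <- embed_conformer("[C][C][O]", seed = 1)
  expect_identical(a$status, "ok")
  expect_identical(a$graph$coords, b$graph$coords)
  expect_true(all(is.finite(a$graph$coords)))
  expect_identical(a$graph$atom_types, c("C", "C", "O"))

  # single heavy atom embeds to a finite one-atom graph
  m <- embed_conformer("[C]")
  expect_identical(m$status, "ok")
  expect_equal(m$graph$n_atoms, 1L)

  # an uninterpretable input is a first-class failure, not an error
  f <- embed_conformer("garbage")
  expect_identical(f$status, "failed")
  expect_identical(f$reason, "uninterpretable")
})

test_that("molecule records link string, token and graph views", {
  v <- build_vocabulary("[C][C][O]", max_length = 6)
  r <- molecule_record("[C][C][O]", vocab = v, embed = TRUE)
  expect_s3_class(r, "molecule_record")
  expect_identical(r$smiles, "CCO")
  expect_length(r$tokens, 6L)
  expect_identical(r$canonical_id, canonical_id("[C][C][O]"))
  expect_equal(r$graph$n_atoms, 3L)
})

test_that("coordinate perturbation with sigma = 0 is the identity", {
  r <- molecule_record("[C][C][O]", embed = TRUE)
  p <- perturb(r, "coord_noise", sigma = 0, seed = 5)
  expect_identical(p$status, "ok")
  expect_equal(p$graph$coords, r$graph$coords)
})

test_that("perturbations are seeded and reproducible", {
  r <- molecule_record("[C][C][C][C][O]", embed = TRUE)
  p1 <- perturb(r, "coord_noise", sigma = 0.1, seed = 9)
  p2 <- perturb(r, "coord_noise", sigma = 0.1, seed = 9)
  expect_identical(p1$graph$coords, p2$graph$coords)
  a1 <- perturb(r, "atom_type_swap", seed = 9)
  a2 <- perturb(r, "atom_type_swap", seed = 9)
  expect_identical(a1$graph$atom_types, a2$graph$atom_types)
  expect_false(identical(a1$graph$atom_types, r$graph$atom_types))
  s1 <- perturb(r, "selfies_swap", seed = 9)
  s2 <- perturb(r, "selfies_swap", seed = 9)
  expect_identical(s1$selfies, s2$selfies)
})

test_that("every string swap yields a decodable string", {
  set.seed(33)
  base <- molecule_record("[C][C][Branch1][=C][O][C][N][=O]")
  for (i in 1:1000) {
    p <- perturb(base, "selfies_swap", seed = i)
    expect_identical(p$status, "ok")
    topo <- decode_selfies(p$selfies)
    expect_gte(topo$n_atoms, 1)
  }
})

test_that("unknown perturbation modes and missing views error", {
  r <- molecule_record("[C][C]")
  expect_error(perturb(r, "bogus"))
  expect_error(perturb(r, "coord_noise"), "no 3D graph")
})

test_that("molecule files round-trip through the readers", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO", "CC(=O)N", "not_a_molecule"), smi)
  mols <- read_molecules(smi)
  expect_length(mols, 2L)
  expect_equal(nrow(attr(mols, "rejected")), 1L)
  expect_identical(canonical_id(mols[1]), "CCO")

  csv <- tempfile(fileext = ".csv")
  writeLines(c("molecule,act", "[C][C][O],1.5", "[C][N],2.5"), csv)
  d <- read_molecules(csv)
  expect_length(d$molecules, 2L)
  expect_equal(d$properties$act, c(1.5, 2.5))
})

test_that("embedded conformers serialize to parseable SDF", {
  r <- molecule_record("[C][C][O]", embed = TRUE)
  path <- tempfile(fileext = ".sdf")
  n <- write_conformers_sdf(list(r), path)
  expect_equal(n, 1L)
  blk <- uncertmol:::parse_sdf_block(readLines(path))
  expect_equal(blk$element, c("C", "C", "O"))
  expect_equal(unname(blk$coords), unname(r$graph$coords), tolerance = 1e-3)
})
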