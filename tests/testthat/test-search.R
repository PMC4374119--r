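# index construction, JSON round trip, the three search modes, ranking

dict <- default_fragment_dictionary()

test_that("build_index routes errors, collapses page duplicates, keeps stereo", {
  idx <- build_index(data.frame(
    smiles = c("CCO", "c1ccccc1", "CC(=O)O", "C1CC"),
    page = c("Ethanol", "Benzene", "Acetic acid", "Broken")), dict,
    built_at = "2026-01-01T00:00:00Z")
  expect_equal(idx$header$count, 3L)
  expect_equal(nrow(idx$errors), 1L)
  expect_equal(idx$errors$error_class, "UNCLOSED_RING")

  # same page, two stereo-different SMILES -> 2 records, same page name
  idx2 <- build_index(data.frame(
    smiles = c("N[C@@H](C)C(=O)O", "N[C@H](C)C(=O)O"),
    page = c("Alanine", "Alanine")), dict, built_at = "T")
  expect_equal(idx2$header$count, 2L)
  expect_equal(unique(idx2$records$page), "Alanine")

  # same page, same structure twice -> collapsed
  idx3 <- build_index(data.frame(smiles = c("CCO", "OCC"),
                                 page = c("Ethanol", "Ethanol")), dict,
                      built_at = "T")
  expect_equal(idx3$header$count, 1L)

  empty <- build_index(data.frame(smiles = character(), page = character()),
                       dict, built_at = "T")
  expect_equal(empty$header$count, 0L)
  expect_equal(empty$header$dictionary_version, dict$version)

  expect_error(build_index(data.frame(smiles = "C", page = "a\tb"), dict),
               "tab")
})

test_that("index records satisfy their invariants and survive JSON IO", {
  idx <- build_index(data.frame(
    smiles = c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"),
    page = c("Ethanol", "Benzene", "Aspirin")), dict, built_at = "T")
  for (r in seq_len(idx$header$count)) {
    g <- parse_smiles(idx$records$structure[r])
    expect_equal(idx$records$mw[r], molecular_weight(g))
    expect_equal(idx$records$mf[r], molecular_formula(g))
    expect_identical(as.integer(idx$bits[r, ]),
                     compute_descriptor(g, dict)$bits)
  }
  f <- withr::local_tempfile(fileext = ".json")
  write_index(idx, f)
  idx2 <- read_index(f)
  expect_equal(idx2$header$dictionary_version, dict$version)
  expect_equal(idx2$header$count, 3L)
  expect_equal(idx2$records, idx$records)
  expect_equal(idx2$words, idx$words, ignore_attr = TRUE)
  expect_identical(idx2$bits, idx$bits, ignore_attr = TRUE)
})

test_that("substructure search screens, confirms, and ranks by |dMW|", {
  idx <- build_index(data.frame(
    smiles = c("c1ccccc1", "Cc1ccccc1", "CCO", "CCc1ccccc1"),
    page = c("Benzene", "Toluene", "Ethanol", "Ethylbenzene")), dict,
    built_at = "T")
  r <- search_substructure("c1ccccc1", idx, dict)
  expect_equal(r$hits$page, c("Benzene", "Toluene", "Ethylbenzene"))
  expect_equal(r$hits$mw_delta[1], 0)
  expect_true(all(diff(r$hits$mw_delta) >= 0))

  # zero-hit query
  r0 <- search_substructure("C#N", idx, dict)
  expect_equal(nrow(r0$hits), 0L)

  # result set equals brute force (no screening) on this index
  brute <- which(vapply(idx$graphs, function(g) {
    is_substructure(parse_smiles("c1ccccc1"), g)
  }, logical(1)))
  expect_setequal(r$hits$page, idx$records$page[brute])
})

test_that("similarity search puts the exact match first and sorts scores", {
  idx <- build_index(data.frame(
    smiles = c("CCO", "CCCO", "CCOC", "c1ccccc1"),
    page = c("Ethanol", "Propanol", "Ether", "Benzene")), dict,
    built_at = "T")
  r <- search_similarity("CCO", idx, dict)
  expect_equal(r$hits$page[1], "Ethanol")
  expect_equal(r$hits$score[1], 1.0)
  expect_true(all(diff(r$hits$score[-1]) <= 0))
  expect_equal(nrow(r$hits), 4L)  # all records returned by default
  r2 <- search_similarity("CCO", idx, dict, top = 2L)
  expect_equal(nrow(r2$hits), 2L)

  one <- build_index(data.frame(smiles = "CC", page = "Ethane"), dict,
                     built_at = "T")
  r3 <- search_similarity("CCO", one, dict)
  expect_equal(nrow(r3$hits), 1L)
  expect_true(r3$hits$score >= 0 && r3$hits$score <= 1)
})

test_that("exact search is canonicalization- and stereo-aware", {
  idx <- build_index(data.frame(
    smiles = c("CCO", "N[C@@H](C)C(=O)O", "OCC"),
    page = c("Ethanol", "L-Alanine", "Alcohol")), dict, built_at = "T")
  r <- search_exact("OCC", idx)
  expect_equal(sort(r$hits$page), c("Alcohol", "Ethanol"))  # 2 pages, 1 structure
  r2 <- search_exact("N[C@H](C)C(=O)O", idx)  # opposite enantiomer
  expect_equal(nrow(r2$hits), 0L)
  r3 <- search_exact("N[C@@H](C)C(=O)O", idx)
  expect_equal(r3$hits$page, "L-Alanine")
})

test_that("self-retrieval: each record ranks first as its own query", {
  set.seed(51)
  smis <- unique(random_molecules(12, gen_config()))
  idx <- build_index(data.frame(smiles = smis,
                                page = sprintf("Mol %02d", seq_along(smis))),
                     dict, built_at = "T")
  for (r in seq_len(idx$header$count)) {
    q <- idx$graphs[[r]]
    can <- idx$records$structure[r]
    expect_equal(search_substructure(q, idx, dict)$hits$structure[1], can)
    expect_equal(search_similarity(q, idx, dict)$hits$structure[1], can)
    expect_equal(search_exact(q, idx)$hits$structure[1], can)
  }
})

test_that("name filtering applies after ranking, case-insensitively", {
  idx <- build_index(data.frame(
    smiles = c("CCO", "CCCO", "CCCCO"),
    page = c("Ethanol", "Propanol", "Butanol")), dict, built_at = "T")
  r <- filter_results(search_similarity("CCO", idx, dict), "PROP")
  expect_equal(r$hits$page, "Propanol")
})
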