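# deterministic fixture generation: molecules, permutations, corpora

test_that("gen_config validates its proportions", {
  expect_s3_class(gen_config(), "gen_config")
  expect_error(gen_config(missing_rate = 0.9, duplicate_rate = 0.3),
               "more than 1")
  expect_error(gen_config(atom_budget = c(5L, 2L)))
})

test_that("random_molecule output always parses; budget 1 gives one atom", {
  set.seed(71)
  for (smi in random_molecules(80, gen_config())) {
    expect_s3_class(parse_smiles(smi), "molgraph")
  }
  set.seed(72)
  for (smi in random_molecules(10, gen_config(atom_budget = c(1L, 1L)))) {
    expect_equal(n_atoms(parse_smiles(smi)), 1L)
  }
})

test_that("identical seeds reproduce identical outputs", {
  set.seed(73); a <- random_molecules(10, gen_config())
  set.seed(73); b <- random_molecules(10, gen_config())
  expect_identical(a, b)

  c1 <- synth_wiki_corpus(test_config(seed = 9, n = 25))
  c2 <- synth_wiki_corpus(test_config(seed = 9, n = 25))
  expect_identical(vapply(c1$pages, `[[`, "", "wikitext"),
                   vapply(c2$pages, `[[`, "", "wikitext"))
  expect_identical(c1$manifest[names(c1$manifest) != "categories"],
                   c2$manifest[names(c2$manifest) != "categories"])
})

test_that("permuted_smiles rewrites the same graph", {
  set.seed(74)
  for (smi in c("CCO", random_molecules(15, gen_config()))) {
    g <- parse_smiles(smi)
    p <- permuted_smiles(g)
    expect_true(same_structure(g, parse_smiles(p)), label = smi)
  }
  expect_equal(permuted_smiles("C"), "C")
})

test_that("a hundred permutations canonicalize identically", {
  set.seed(75)
  g <- parse_smiles(random_molecule(gen_config(atom_budget = c(8L, 12L),
                                               ring_probability = 0.8)))
  ref <- canonical_smiles(g)$canonical_smiles
  for (k in 1:100) {
    expect_identical(canonical_smiles(permuted_smiles(g))$canonical_smiles,
                     ref)
  }
})

test_that("error-free corpora produce no error rows", {
  cfg <- gen_config(seed = 10, n_molecules = 30,
                    error_mix = c(PYRROLE_NITROGEN = 0),
                    duplicate_rate = 0, missing_rate = 0,
                    stereo_pair_rate = 0, multi_identical_rate = 0)
  corpus <- synth_wiki_corpus(cfg)
  entries <- do.call(rbind, lapply(corpus$pages, extract_entries))
  cc <- consolidate(entries)
  expect_equal(nrow(cc$errors), 0L)
  expect_equal(corpus$manifest$missing_pages, 0L)
})

test_that("duplicate_rate 0 yields no cross-page duplicate groups", {
  cfg <- gen_config(seed = 11, n_molecules = 30, duplicate_rate = 0,
                    stereo_pair_rate = 0, multi_identical_rate = 0)
  corpus <- synth_wiki_corpus(cfg)
  expect_equal(corpus$manifest$duplicate_groups, 0L)
  entries <- do.call(rbind, lapply(corpus$pages, extract_entries))
  cc <- consolidate(entries)
  idx <- build_index(data.frame(smiles = cc$kept$smiles_raw,
                                page = cc$kept$page),
                     default_fragment_dictionary(), built_at = "T")
  expect_length(find_duplicates(idx)$stereo, 0L)
})

test_that("requested pyrrole proportion surfaces as classified fixable errors", {
  cfg <- gen_config(seed = 12, n_molecules = 60,
                    error_mix = c(PYRROLE_NITROGEN = 0.2),
                    duplicate_rate = 0, missing_rate = 0,
                    stereo_pair_rate = 0, multi_identical_rate = 0)
  corpus <- synth_wiki_corpus(cfg)
  n_pyr <- corpus$manifest$errors_by_class$PYRROLE_NITROGEN
  expect_gt(n_pyr, 0L)
  entries <- do.call(rbind, lapply(corpus$pages, extract_entries))
  cc <- consolidate(entries)
  pyr <- cc$errors[cc$errors$error_class == "PYRROLE_NITROGEN", ]
  expect_equal(nrow(pyr), n_pyr)
  for (fix in pyr$suggested_fix) {
    expect_s3_class(parse_smiles(fix), "molgraph")
  }
})

test_that("every configured error class is produced and classified", {
  mix <- c(PYRROLE_NITROGEN = 0.1, UNCLOSED_RING = 0.1,
           UNCLOSED_PARENTHESIS = 0.1, BARE_ATOM_NEEDS_BRACKETS = 0.1,
           KEKULIZATION_FAILURE = 0.1, BAD_TOKEN = 0.1, VALENCE_ERROR = 0.1)
  cfg <- gen_config(seed = 13, n_molecules = 120, error_mix = mix,
                    duplicate_rate = 0, missing_rate = 0,
                    stereo_pair_rate = 0, multi_identical_rate = 0)
  corpus <- synth_wiki_corpus(cfg)
  entries <- do.call(rbind, lapply(corpus$pages, extract_entries))
  cc <- consolidate(entries)
  got <- table(cc$errors$error_class)
  want <- unlist(corpus$manifest$errors_by_class)
  for (cls in names(mix)) {
    expect_equal(as.integer(got[cls]), unname(want[cls]),
                 label = cls)
  }
})
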