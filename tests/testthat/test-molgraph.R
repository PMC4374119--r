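# SMILES parsing, kekulization, hydrogen/valence model, error taxonomy

test_that("parse_smiles handles the organic subset and computes hydrogens", {
  g <- parse_smiles("C")
  expect_s3_class(g, "molgraph")
  expect_equal(n_atoms(g), 1L)
  expect_equal(g$implicit_h, 4L)

  cases <- list(
    list(smi = "CCO", mf = "C2H6O"),
    list(smi = "c1ccccc1", mf = "C6H6"),
    list(smi = "ClC(Cl)Cl", mf = "CHCl3"),
    list(smi = "N#N", mf = "N2"),
    list(smi = "CS(=O)(=O)C", mf = "C2H6O2S"),
    list(smi = "[13CH4]", mf = "CH4"),
    list(smi = "CC(=O)[O-]", mf = "C2H3O2"),
    list(smi = "C1CCCCC1.O", mf = "C6H14O"))
  for (cs in cases) {
    g <- parse_smiles(cs$smi)
    expect_s3_class(g, "molgraph")
    expect_equal(molecular_formula(g), cs$mf, label = cs$smi)
  }
})

test_that("syntax errors are classified with positions", {
  r <- parse_smiles("C1CC")
  expect_s3_class(r, "parse_issue")
  expect_equal(r$error_class, "UNCLOSED_RING")
  expect_equal(r$position, 1L)

  r <- parse_smiles("C(C")
  expect_equal(r$error_class, "UNCLOSED_PARENTHESIS")
  expect_equal(r$position, 1L)

  r <- parse_smiles("CC)C")
  expect_equal(r$error_class, "UNCLOSED_PARENTHESIS")

  r <- parse_smiles("HgCl")
  expect_equal(r$error_class, "BARE_ATOM_NEEDS_BRACKETS")
  expect_equal(r$position, 0L)
  expect_s3_class(parse_smiles("[Hg]"), "molgraph")

  expect_equal(parse_smiles("CC*")$error_class, "BAD_TOKEN")
  expect_equal(parse_smiles("C==C")$error_class, "BAD_TOKEN")
  expect_equal(parse_smiles("")$error_class, "BAD_TOKEN")
  expect_equal(parse_smiles("C(C)(C)(C)(C)C")$error_class, "VALENCE_ERROR")
  # syntax beats kekulization beats valence
  expect_equal(parse_smiles("c1cccc1(C)(C)(C)C1CC")$error_class,
               "UNCLOSED_RING")
})

test_that("the benzimidazole mis-encoding is repaired", {
  r <- parse_smiles("n2c1ccccc1nc2")
  expect_s3_class(r, "parse_issue")
  expect_equal(r$error_class, "PYRROLE_NITROGEN")
  fixed <- parse_smiles(r$suggested_fix)
  expect_s3_class(fixed, "molgraph")
  expect_equal(molecular_formula(fixed), "C7H6N2")
})

test_that("suggest_pyrrole_fix follows the smallest-subset, leftmost rule", {
  expect_equal(suggest_pyrrole_fix("n2c1ccccc1nc2"), "[nH]2c1ccccc1nc2")
  expect_null(suggest_pyrrole_fix("c1cc[nH]c1"))   # already valid
  expect_null(suggest_pyrrole_fix("C1CC"))         # not kekulization-related
  expect_null(suggest_pyrrole_fix("c1cccc1"))      # no bare n to repair
  # porphyrin-like double repair: two of four nitrogens need [nH]
  fix <- suggest_pyrrole_fix("c1cnnc1")            # pyrazole missing its H
  expect_false(is.null(fix))
  expect_s3_class(parse_smiles(fix), "molgraph")
})

test_that("kekulize agrees with exhaustive double-bond enumeration", {
  smis <- c("c1ccccc1", "c1cc[nH]c1", "c1ccncc1", "c1ccoc1", "c1ccsc1",
            "c1c[nH]cn1", "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1",
            "[nH]2c1ccccc1nc2", "Cc1ccc(O)cc1", "c1cc[nH]n1", "c1cnccn1")
  for (smi in smis) {
    g <- parse_smiles(smi)
    expect_s3_class(g, "molgraph")
    valid <- oracle_kekulizations(g)
    expect_gt(length(valid), 0, label = smi)
    chosen <- sort(which(g$bond_aromatic & g$bond_order == 2L))
    expect_true(any(vapply(valid, identical, logical(1), chosen)),
                label = paste(smi, "choice is a valid kekulization"))
    # deterministic tie-break: numerically lexicographically smallest
    # sorted list of double-bond endpoint-index pairs
    pair_seq <- function(bonds) {
      m <- t(vapply(bonds, function(b) sort(c(g$bond_i[b], g$bond_j[b])),
                    integer(2)))
      as.integer(t(m[order(m[, 1], m[, 2]), , drop = FALSE]))
    }
    seqs <- lapply(valid, pair_seq)
    lex_less <- function(a, b) {
      d <- which(a != b)
      if (!length(d)) FALSE else a[d[1]] < b[d[1]]
    }
    best <- seqs[[1]]
    for (s in seqs[-1]) if (lex_less(s, best)) best <- s
    expect_equal(pair_seq(chosen), best,
                 label = paste(smi, "lexicographic tie-break"))
  }
  expect_equal(parse_smiles("c1cccc1")$error_class, "KEKULIZATION_FAILURE")
})

test_that("benzene / pyrrole kekulize to the expected double-bond counts", {
  expect_equal(sum(parse_smiles("c1ccccc1")$bond_order == 2L), 3L)
  g <- parse_smiles("c1cc[nH]c1")
  expect_equal(sum(g$bond_order == 2L), 2L)
  nidx <- which(g$element == "N")
  ndbl <- any((g$bond_i == nidx | g$bond_j == nidx) & g$bond_order == 2L)
  expect_false(ndbl)
})

test_that("molecular weights use the frozen table and isotopes", {
  expect_equal(molecular_weight(parse_smiles("C")), 16.04)
  expect_equal(molecular_weight(parse_smiles("c1ccccc1")), 78.11)
  expect_equal(molecular_weight(parse_smiles("[13CH4]")), 17.03)
  expect_equal(molecular_weight(parse_smiles("O")), 18.02)
  expect_equal(molecular_weight(parse_smiles("ClC(Cl)Cl")), 119.37)
})

test_that("every generated molecule respects its element's valence set", {
  allowed <- list(B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
                  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L)
  set.seed(11)
  for (smi in random_molecules(60, gen_config())) {
    g <- parse_smiles(smi)
    expect_s3_class(g, "molgraph")
    bondsum <- integer(n_atoms(g))
    for (b in seq_len(n_bonds(g))) {
      bondsum[g$bond_i[b]] <- bondsum[g$bond_i[b]] + g$bond_order[b]
      bondsum[g$bond_j[b]] <- bondsum[g$bond_j[b]] + g$bond_order[b]
    }
    th <- wikichem:::total_h(g)
    for (a in seq_len(n_atoms(g))) {
      if (g$bracket[a]) next  # explicit spec wins
      expect_true((bondsum[a] + th[a]) %in% allowed[[g$element[a]]],
                  label = sprintf("%s atom %d in %s", g$element[a], a, smi))
    }
  }
})

test_that("parse -> write -> parse round trip preserves the graph", {
  set.seed(12)
  for (smi in random_molecules(40, gen_config())) {
    g1 <- parse_smiles(smi)
    g2 <- parse_smiles(wikichem:::write_smiles(g1))
    expect_true(same_structure(g1, g2), label = smi)
  }
})

test_that("multi-fragment input is flagged and the largest component kept", {
  g <- parse_smiles("CCO.C")
  expect_true(g$multi_fragment)
  expect_equal(g$n_fragments, 2L)
  lc <- wikichem:::largest_component(g)
  expect_equal(molecular_formula(lc), "C2H6O")
})
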