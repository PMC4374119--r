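# Chembox/Drugbox extraction, consolidation, duplicates, cross-reference

dict <- default_fragment_dictionary()

chembox <- function(title, ...) {
  fields <- list(...)
  lines <- paste0(vapply(names(fields), function(nm) {
    sprintf("| %s = %s\n", nm, fields[[nm]])
  }, character(1)), collapse = "")
  wiki_page(title, sprintf(
    "Intro text.\n{{Chembox\n| Name = %s\n| Section1 = {{Chembox Identifiers\n%s}}\n}}\nSee also.",
    title, lines))
}

test_that("extract_entries finds SMILES in Chembox and Drugbox templates", {
  e <- extract_entries(chembox("Ethanol", SMILES = "CCO"))
  expect_equal(nrow(e), 1L)
  expect_equal(e$smiles_raw, "CCO")
  expect_equal(e$template, "chembox")
  expect_equal(e$smiles_field, "SMILES")

  pg <- wiki_page("Aspirin",
    "{{Infobox drug\n| drug_name = Aspirin\n| smiles = CC(=O)Oc1ccccc1C(=O)O\n}}")
  e2 <- extract_entries(pg)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$template, "drugbox")

  # numeric suffixes, nowiki wrappers, pipe escapes
  e3 <- extract_entries(chembox("X", SMILES = "<nowiki>CCO</nowiki>",
                                SMILES1 = "  OCC ", SMILES2 = "CC{{!}}O"))
  expect_equal(nrow(e3), 3L)
  expect_equal(e3$smiles_raw, c("CCO", "OCC", "CC|O"))

  # no SMILES at all
  e4 <- extract_entries(chembox("Mixture", CAS = "123-45-6"))
  expect_equal(nrow(e4), 0L)
  # non-chemical template is ignored
  e5 <- extract_entries(wiki_page("Infobox", "{{Infobox person\n| SMILES = CCO\n}}"))
  expect_equal(nrow(e5), 0L)
})

test_that("extraction is insensitive to parameter order and whitespace", {
  a <- extract_entries(chembox("A", SMILES = "CCO", SMILES1 = "CCN"))
  b <- extract_entries(chembox("A", SMILES1 = "CCN", SMILES = "CCO"))
  expect_setequal(a$smiles_raw, b$smiles_raw)
  spaced <- wiki_page("A",
    "{{Chembox\n\n|   Name   =   A\n|  Section1   =  {{Chembox Identifiers\n\n|   SMILES   =   CCO\n\n}}\n\n}}")
  expect_equal(extract_entries(spaced)$smiles_raw, "CCO")
})

test_that("malformed braces flag the page instead of failing", {
  bad <- wiki_page("Broken", "{{Chembox\n| SMILES = CCO\n")
  e <- extract_entries(bad)
  expect_true(attr(e, "malformed"))
  expect_equal(nrow(e), 0L)
})

test_that("consolidate keeps first of same-structure groups, routes errors", {
  mk <- function(page, smis) data.frame(
    page = page, smiles_raw = smis,
    smiles_field = paste0("SMILES", seq_along(smis) - 1L),
    template = "chembox", stringsAsFactors = FALSE)

  cc <- consolidate(mk("E", c("CCO", "OCC")))
  expect_equal(nrow(cc$kept), 1L)
  expect_equal(cc$kept$smiles_raw, "CCO")
  expect_equal(nrow(cc$dropped), 1L)

  cc2 <- consolidate(mk("V", c("CCO", "C1CC")))
  expect_equal(nrow(cc2$kept), 1L)
  expect_equal(nrow(cc2$errors), 1L)
  expect_equal(cc2$errors$error_class, "UNCLOSED_RING")

  cc3 <- consolidate(mk("S", c("N[C@@H](C)C(=O)O", "N[C@H](C)C(=O)O")))
  expect_equal(nrow(cc3$kept), 2L)

  # pyrrole mis-encoding carries its fix into the error report
  cc4 <- consolidate(mk("B", "n2c1ccccc1nc2"))
  expect_equal(cc4$errors$error_class, "PYRROLE_NITROGEN")
  expect_equal(cc4$errors$suggested_fix, "[nH]2c1ccccc1nc2")
})

test_that("conservation: kept + errors + dropped == total SMILES params", {
  corpus <- synth_wiki_corpus(test_config(seed = 5, n = 40))
  entries <- do.call(rbind, lapply(corpus$pages, extract_entries))
  cc <- consolidate(entries)
  expect_equal(nrow(entries), corpus$manifest$total_smiles_params)
  expect_equal(nrow(cc$kept) + nrow(cc$errors) + nrow(cc$dropped),
               nrow(entries))
})

test_that("find_duplicates groups shared structures across pages", {
  # the same-SMILES-on-two-pages situation (mis-curated isomer pages)
  idx <- build_index(data.frame(
    smiles = c("CC(C)[N+](=O)[O-]", "CC(C)[N+](=O)[O-]", "CCO"),
    page = c("2-Nitropropane", "1-Nitropropane", "Ethanol")), dict,
    built_at = "T")
  d <- find_duplicates(idx)
  expect_length(d$stereo, 1L)
  expect_setequal(d$stereo[[1]]$page, c("1-Nitropropane", "2-Nitropropane"))

  # three pages sharing one skeleton with different printed stereo
  sugars <- data.frame(
    smiles = c("O[C@@H]1CCCC1", "O[C@H]1CCCC1", "OC1CCCC1"),
    page = c("Pinitol-like A", "Quebrachitol-like B", "Ononitol-like C"))
  idx2 <- build_index(sugars, dict, built_at = "T")
  d2 <- find_duplicates(idx2)
  expect_length(d2$stereo, 0L)
  expect_length(d2$stripped, 1L)
  expect_equal(nrow(d2$stripped[[1]]), 3L)
  expect_true(attr(d2$stripped[[1]], "merged_by_stripping"))

  # no duplicates -> empty report; groups partition grouped records
  idx3 <- build_index(data.frame(smiles = c("CCO", "CCC"),
                                 page = c("A", "B")), dict, built_at = "T")
  d3 <- find_duplicates(idx3)
  expect_length(d3$stereo, 0L)
  pages_in_groups <- unlist(lapply(d$stereo, `[[`, "page"))
  expect_equal(anyDuplicated(pages_in_groups), 0L)
})

test_that("classify_crossref distinguishes match, isomer, mismatch", {
  expect_equal(classify_crossref("CCO", "OCC")$verdict, "MATCH")
  expect_equal(classify_crossref("CC(O)C", "CCCO")$verdict,
               "SAME_FORMULA_DIFFERENT_STRUCTURE")
  expect_equal(classify_crossref("CCO", "CCC")$verdict, "FORMULA_MISMATCH")
  skipped <- classify_crossref("CCO", "C1CC")
  expect_true(is.na(skipped$verdict))
  expect_match(skipped$note, "unparseable")
  expect_error(classify_crossref("C1CC", "CCO"), "does not parse")
})

test_that("export_smiles_list writes stable canonical TSV lines", {
  idx <- build_index(data.frame(smiles = c("OCC", "c1ccccc1"),
                                page = c("Zeta", "Alpha")), dict,
                     built_at = "T")
  lines <- export_smiles_list(idx)
  expect_length(lines, 2L)
  expect_equal(lines[1], paste0(canonical_smiles("c1ccccc1")$canonical_smiles,
                                "\tAlpha"))
  expect_match(lines[2], "\tZeta$")
  empty <- build_index(data.frame(smiles = character(), page = character()),
                       dict, built_at = "T")
  expect_length(export_smiles_list(empty), 0L)
})

test_that("corpus JSONL round trip preserves pages", {
  corpus <- synth_wiki_corpus(test_config(seed = 6, n = 10))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus$pages, f)
  back <- read_corpus(f)
  expect_length(back, 10L)
  expect_identical(vapply(back, `[[`, "", "title"),
                   vapply(corpus$pages, `[[`, "", "title"))
  expect_identical(vapply(back, `[[`, "", "wikitext"),
                   vapply(corpus$pages, `[[`, "", "wikitext"))
})
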