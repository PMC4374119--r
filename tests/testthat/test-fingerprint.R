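# 512-bit fragment descriptor, packing, Tanimoto, screening

test_that("the default dictionary has exactly 512 parsing fragments", {
  d <- default_fragment_dictionary()
  expect_length(d$patterns, 512L)
  expect_length(d$min_count, 512L)
  expect_true(all(d$min_count >= 1L))
  expect_true(all(vapply(d$graphs, is_molgraph, logical(1))))
  # frozen order: (pattern, min_count) pairs are unique
  expect_equal(anyDuplicated(paste(d$patterns, d$min_count)), 0L)
})

test_that("dictionary round-trips through its plain-text serialization", {
  d <- default_fragment_dictionary()
  f <- withr::local_tempfile(fileext = ".txt")
  write_fragment_dictionary(d, f)
  d2 <- read_fragment_dictionary(f)
  expect_identical(d2$patterns, d$patterns)
  expect_identical(d2$min_count, d$min_count)
  expect_identical(d2$version, d$version)
})

test_that("descriptors have 512 bits in 16 words and 512 evaluations", {
  d <- default_fragment_dictionary()
  desc <- compute_descriptor("CC(=O)Oc1ccccc1C(=O)O", d)  # aspirin
  expect_length(desc$bits, 512L)
  expect_true(all(desc$bits %in% c(0L, 1L)))
  expect_identical(attr(desc, "evaluations"), 512L)
  w <- descriptor_words(desc)
  expect_length(w, 16L)
  expect_true(all(w >= 0 & w < 2^32))
  expect_true(all(w == floor(w)))
  expect_equal(sum(desc$bits), sum(vapply(w, function(x) {
    sum(words_to_bits(x))
  }, numeric(1))))
})

test_that("word packing round-trips random bit patterns", {
  set.seed(41)
  for (k in 1:20) {
    bits <- sample(0:1, 512L, replace = TRUE)
    expect_identical(words_to_bits(descriptor_words(bits)), as.integer(bits))
  }
})

test_that("descriptor bits honor fragment monotonicity and emptiness", {
  d <- default_fragment_dictionary()
  benzene <- compute_descriptor("c1ccccc1", d)
  toluene <- compute_descriptor("Cc1ccccc1", d)
  expect_true(all(benzene$bits <= toluene$bits))
  water <- compute_descriptor("O", d)
  ethane <- compute_descriptor("CC", d)
  carbon_bits <- which(vapply(d$graphs, function(g) {
    all(g$element == "C")
  }, logical(1)))
  expect_true(all(water$bits[carbon_bits] == 0L))
  expect_gt(sum(ethane$bits[carbon_bits]), 0L)
})

test_that("methane sets only single-carbon fragment bits", {
  d <- default_fragment_dictionary()
  desc <- compute_descriptor("C", d)
  on <- which(desc$bits == 1L)
  expect_true(length(on) >= 1L)
  for (b in on) {
    g <- d$graphs[[b]]
    expect_true(n_atoms(g) == 1L && g$element == "C" && !g$aromatic[1],
                label = d$patterns[b])
  }
})

test_that("tanimoto and screen_pass follow their definitions", {
  d <- default_fragment_dictionary()
  x <- compute_descriptor("CCO", d)
  expect_equal(tanimoto(x, x), 1.0)
  mk <- function(bits) structure(list(bits = bits, version = d$version),
                                 class = "descriptor")
  a <- mk(as.integer(c(rep(1L, 4), rep(0L, 508))))
  b <- mk(as.integer(c(rep(1L, 3), 0L, 1L, rep(0L, 507))))
  expect_equal(tanimoto(a, b), 3 / 5)
  disj <- mk(as.integer(c(rep(0L, 4), rep(1L, 2), rep(0L, 506))))
  expect_equal(tanimoto(a, disj), 0.0)
  zero <- mk(integer(512))
  expect_equal(tanimoto(zero, zero), 1.0)

  expect_true(screen_pass(x, x))
  expect_true(screen_pass(zero, x))
  expect_true(screen_pass(b, mk(pmax(a$bits, b$bits))))
  expect_false(screen_pass(a, b))  # a has bit 4 that b lacks

  other <- structure(list(bits = integer(512), version = "other"),
                     class = "descriptor")
  expect_error(tanimoto(x, other), "version")
  expect_error(screen_pass(x, other), "version")
})

test_that("identical structures yield identical descriptors", {
  d <- default_fragment_dictionary()
  set.seed(42)
  for (smi in random_molecules(15, gen_config())) {
    g <- parse_smiles(smi)
    d1 <- compute_descriptor(g, d)
    d2 <- compute_descriptor(parse_smiles(permuted_smiles(g)), d)
    expect_identical(d1$bits, d2$bits, label = smi)
  }
})

test_that("screening is sound on molecule/subgraph pairs (small sample)", {
  d <- default_fragment_dictionary()
  set.seed(43)
  for (i in 1:60) {
    mol <- parse_smiles(random_molecule(gen_config(atom_budget = c(4L, 12L))))
    sub <- random_connected_subgraph(mol)
    if (!is_substructure(sub, mol)) next
    expect_true(screen_pass(compute_descriptor(sub, d),
                            compute_descriptor(mol, d)),
                label = sprintf("pair %d", i))
  }
})
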