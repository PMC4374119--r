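#' Fragment dictionary for the 512-bit descriptor
#'
#' The descriptor is a fragment-dictionary fingerprint: bit i is set when
#' predefined fragment i occurs in the molecule at least `min_count[i]`
#' times as a substructure. The original 512-fragment dictionary behind the
#' FragFp descriptor is unpublished, so the package ships its own versioned
#' default built from element/count patterns, linear paths, ring systems and
#' functional groups, padded with count-threshold variants to exactly 512
#' entries. Any dictionary of substructure-present bits preserves the
#' soundness of fingerprint screening, because substructure containment
#' implies bit-set containment.
#'
#' Bracket-H constraints in fragment SMILES (e.g. the `[nH]` needed to make
#' pyrrole parse) are deliberately dropped when bits are evaluated: minimum-H
#' constraints do not compose through embeddings onto bare atoms and would
#' break screening soundness.
#'
#' @param patterns character vector of fragment SMILES.
#' @param min_count integer vector of occurrence thresholds (>= 1).
#' @param version dictionary version string (stored in index headers).
#' @return a `fragment_dictionary` object.
#' @export
fragment_dictionary <- function(patterns, min_count = rep(1L, length(patterns)),
                                version = "custom") {
  stopifnot(length(patterns) == length(min_count), all(min_count >= 1L))
  graphs <- lapply(patterns, function(p) {
    g <- parse_smiles(p)
    if (is_parse_issue(g)) {
      stop(sprintf("fragment '%s' does not parse: %s", p, g$error_class))
    }
    g
  })
  cgraphs <- lapply(graphs, function(g) {
    cg <- as_cgraph(g, as_query = FALSE)  # as_query FALSE: no min-H bits
    cg$minh <- rep(-1L, length(cg$el))
    cg
  })
  structure(list(patterns = patterns, min_count = as.integer(min_count),
                 graphs = graphs, cgraphs = cgraphs, version = version),
            class = "fragment_dictionary")
}

#' @rdname fragment_dictionary
#' @param x object to print.
#' @param ... ignored.
#' @export
print.fragment_dictionary <- function(x, ...) {
  cat(sprintf("<fragment_dictionary %s: %d fragments>\n",
              x$version, length(x$patterns)))
  invisible(x)
}

# cache for the default dictionary (built once per session)
.wikichem_cache <- new.env(parent = emptyenv())

#' @rdname fragment_dictionary
#' @export
default_fragment_dictionary <- function() {
  if (!is.null(.wikichem_cache$default_dict)) return(.wikichem_cache$default_dict)
  spec <- .default_fragment_patterns()
  d <- fragment_dictionary(spec$pattern, spec$min_count,
                           version = "wikichem-fragfp-v1")
  .wikichem_cache$default_dict <- d
  d
}

# Deterministic construction of the default 512-entry pattern list.
.default_fragment_patterns <- function() {
  pat <- character(); mc <- integer()
  add <- function(p, m = 1L) { pat <<- c(pat, p); mc <<- c(mc, as.integer(m)) }

  # element counts (non-aromatic atoms; aromatic content is covered by rings)
  for (m in c(1:8, 10L, 12L, 14L, 16L, 18L, 20L, 24L)) add("C", m)
  for (m in 1:4) add("N", m)
  for (m in 1:6) add("O", m)
  for (m in 1:2) add("S", m)
  add("P"); add("P", 2L)
  for (m in 1:3) add("F", m)
  for (m in 1:3) add("Cl", m)
  for (m in 1:2) add("Br", m)
  add("I")
  add("[O-]"); add("[O-]", 2L); add("[N+]"); add("[n+]1ccccc1")

  # linear single-bond paths, lengths 2-4 over {C,N,O,S}, deduped by reversal
  els <- c("C", "N", "O", "S")
  seen <- character()
  for (len in 2:4) {
    grid <- do.call(expand.grid,
                    c(rep(list(els), len), stringsAsFactors = FALSE))
    for (r in seq_len(nrow(grid))) {
      v <- unlist(grid[r, ], use.names = FALSE)
      if (len == 4L && "S" %in% v) next   # keep the list compact
      key <- paste(v, collapse = "")
      rkey <- paste(rev(v), collapse = "")
      if (key %in% seen || rkey %in% seen) next
      seen <- c(seen, key)
      add(key)
    }
  }
  # longer carbon chains with count thresholds
  for (len in 5:8) add(strrep("C", len))
  add(strrep("C", 6), 2L)

  # multiple-bond motifs
  for (p in c("C=C", "C=N", "C=O", "C=S", "N=N", "N=O", "C#C", "C#N",
              "C=CC", "CC=O", "CC=N", "OC=O", "NC=O", "NC=N", "OC=N",
              "C=CC=C", "C=CC=O", "O=CC=O", "N=C=O", "C=C(C)C", "CC(=O)C",
              "CC(=O)O", "CC(=O)N", "COC=O", "NC(=O)N", "NC(=N)N",
              "O=C(O)C=C", "C#CC", "CC#N")) add(p)
  add("C=C", 2L); add("C=O", 2L); add("C=O", 3L); add("C#N", 2L)

  # saturated / partially saturated rings
  for (p in c("C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCCCCC1",
              "C1CCCCCCC1", "C1CCOC1", "C1CCNC1", "C1CCSC1", "C1CCOCC1",
              "C1CCNCC1", "C1CCSCC1", "O1CCOCC1", "C1OCCO1", "N1CCNCC1",
              "C1CCC2CCCCC2C1", "C1CCC2CCCC2C1", "C1CC=CC1", "C1CC=CCC1",
              "O=C1CCCCC1", "O=C1CCCC1", "O=C1CCNC1", "O=C1CCCN1")) add(p)
  add("C1CCCCC1", 2L)

  # aromatic rings and fused systems
  for (p in c("c1ccccc1", "c1ccncc1", "c1cnccn1", "c1ncncc1", "c1ncncn1",
              "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "c1c[nH]cn1", "c1cc[nH]n1",
              "c1cnco1", "c1cncs1", "c1ccc2ccccc2c1", "c1ccc2ncccc2c1",
              "c1ccc2[nH]ccc2c1", "c1ccc2occc2c1", "c1ccc2sccc2c1",
              "c1ccc2[nH]cnc2c1", "c1ccc2ncncc2c1", "c1ccc2OCOc2c1",
              "c1ccccc1-c1ccccc1", "c1ccc2c(c1)cccc2C",
              "c1ccc2c(c1)CCCC2", "c1ccc2c(c1)CCC2")) add(p)
  add("c1ccccc1", 2L); add("c1ccccc1", 3L); add("c1ccncc1", 2L)

  # substituted aromatics (attachment-flavor bits)
  for (p in c("Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "COc1ccccc1",
              "Nc1ccccc1", "CNc1ccccc1", "Clc1ccccc1", "Fc1ccccc1",
              "Brc1ccccc1", "Ic1ccccc1", "Sc1ccccc1", "O=Cc1ccccc1",
              "OC(=O)c1ccccc1", "NC(=O)c1ccccc1", "CC(=O)c1ccccc1",
              "N#Cc1ccccc1", "C=Cc1ccccc1", "Cc1ccccn1", "Cc1ccco1",
              "Cc1cccs1", "Cc1cc[nH]c1", "Cc1ccccc1C", "Cc1ccc(C)cc1",
              "Cc1cccc(C)c1", "Oc1ccccc1O", "Oc1ccc(O)cc1",
              "Clc1ccccc1Cl", "Clc1ccc(Cl)cc1", "Cn1cccc1")) add(p)
  add("Cc1ccccc1", 2L)

  # functional groups and heteroatom motifs
  for (p in c("CO", "CN", "CS", "CCl", "CF", "CBr", "CI", "OCO", "OCN",
              "NCN", "SCN", "C(F)F", "C(F)(F)F", "C(Cl)Cl", "C(Cl)(Cl)Cl",
              "S=O", "S(=O)(=O)O", "S(=O)(=O)N", "CS(=O)(=O)C",
              "[N+](=O)[O-]", "O[N+](=O)[O-]", "P=O", "OP(=O)(O)O",
              "COP(=O)(O)O", "NS(=O)(=O)C", "OCC(O)C", "OCC(O)CO",
              "NCC(=O)O", "NC(C)C(=O)O", "OC(=O)CC(=O)O", "CSC", "CSSC",
              "CN(C)C", "CCN(CC)CC", "OCCN", "OCCO", "NCCN", "NCCO",
              "ClCCCl", "FC(F)(F)c1ccccc1", "CC(C)(C)C", "CC(C)C",
              "C=C(C)C=C", "CC(O)C", "CC(N)C", "OC(C)=O")) add(p)

  # pad with count-threshold variants of the leading patterns to exactly 512
  base <- data.frame(pattern = pat, min_count = mc, stringsAsFactors = FALSE)
  base <- base[!duplicated(base), , drop = FALSE]
  target <- 512L
  lvl <- 2L
  while (nrow(base) < target) {
    extra <- data.frame(pattern = pat, min_count = mc + lvl,
                        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(extra))) {
      if (nrow(base) >= target) break
      row <- extra[r, , drop = FALSE]
      if (!any(base$pattern == row$pattern & base$min_count == row$min_count)) {
        base <- rbind(base, row)
      }
    }
    lvl <- lvl + 1L
  }
  base <- base[seq_len(target), , drop = FALSE]
  rownames(base) <- NULL
  base
}

#' Read / write a fragment dictionary as plain text
#'
#' One fragment per line: SMILES pattern, a tab, and the minimum occurrence
#' count. Line order defines bit order. A leading `# version: <v>` comment
#' carries the dictionary version.
#'
#' @param path file path.
#' @param dict a `fragment_dictionary`.
#' @return `read_fragment_dictionary()` returns a `fragment_dictionary`.
#' @export
read_fragment_dictionary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  version <- "custom"
  vm <- grep("^#\\s*version:", lines, value = TRUE)
  if (length(vm)) version <- trimws(sub("^#\\s*version:", "", vm[1]))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  fragment_dictionary(
    patterns = vapply(parts, `[`, character(1), 1L),
    min_count = as.integer(vapply(parts, `[`, character(1), 2L)),
    version = version)
}

#' @rdname read_fragment_dictionary
#' @export
write_fragment_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "fragment_dictionary"))
  writeLines(c(sprintf("# version: %s", dict$version),
               paste0(dict$patterns, "\t", dict$min_count)), path)
  invisible(path)
}

#' Compute the 512-bit fragment descriptor of a molecule
#'
#' Evaluates every dictionary fragment as a substructure query against the
#' molecule (bit i set iff fragment i occurs at least `min_count[i]` times).
#' All fragments are evaluated on each call; the only short-circuit is a
#' provably sound element/size pre-check. The number of fragment evaluations
#' is attached as attribute `"evaluations"`.
#'
#' @param mol a parsed `molgraph` or SMILES text.
#' @param dict a `fragment_dictionary` (default: the packaged 512-entry one).
#' @return a `descriptor` object: 0/1 integer bit vector of length 512 plus
#'   the dictionary version.
#' @export
compute_descriptor <- function(mol, dict = default_fragment_dictionary()) {
  mol <- .as_molgraph(mol)
  bits <- cpp_descriptor(dict$cgraphs, dict$min_count, as_cgraph(mol),
                         TRUE, TRUE)
  structure(list(bits = as.integer(bits), version = dict$version),
            class = "descriptor",
            evaluations = length(dict$patterns))
}

#' @rdname compute_descriptor
#' @param x object to print.
#' @param ... ignored.
#' @export
print.descriptor <- function(x, ...) {
  cat(sprintf("<descriptor %s: %d/%d bits set>\n", x$version,
              sum(x$bits), length(x$bits)))
  invisible(x)
}

#' Pack descriptor bits into 16 unsigned 32-bit words
#'
#' Word `w` (0-based) bit `j` corresponds to global bit `32*w + j`
#' (little-endian within word). Words are returned as doubles because R has
#' no unsigned 32-bit integer type; all values are exact integers in
#' `[0, 2^32)`.
#'
#' @param d a `descriptor`, or a raw 0/1 bit vector whose length is a
#'   multiple of 32.
#' @return numeric vector of 16 words.
#' @export
descriptor_words <- function(d) {
  bits <- if (inherits(d, "descriptor")) d$bits else as.integer(d)
  stopifnot(length(bits) %% 32L == 0L, all(bits %in% c(0L, 1L)))
  nw <- length(bits) %/% 32L
  vapply(seq_len(nw), function(w) {
    sum(bits[(w - 1L) * 32L + 1:32] * 2^(0:31))
  }, numeric(1))
}

#' @rdname descriptor_words
#' @param words numeric vector of unsigned 32-bit words.
#' @export
words_to_bits <- function(words) {
  stopifnot(all(words >= 0), all(words < 2^32), all(words == floor(words)))
  out <- integer(length(words) * 32L)
  for (w in seq_along(words)) {
    v <- words[w]
    for (j in 0:31) {
      out[(w - 1L) * 32L + j + 1L] <- as.integer(v %% 2)
      v <- v %/% 2
    }
  }
  out
}

#' Tanimoto similarity of two descriptors
#'
#' `|a AND b| / |a OR b|`, defined as 1.0 when both bit sets are empty.
#' Descriptors must come from the same dictionary version.
#'
#' @param a,b `descriptor` objects.
#' @return numeric in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  .check_same_version(a, b)
  both <- sum(a$bits & b$bits)
  either <- sum(a$bits | b$bits)
  if (either == 0L) return(1.0)
  both / either
}

#' Fingerprint screening test
#'
#' `TRUE` iff every query bit is present in the target descriptor
#' (word-wise: `(q & ~t) == 0`). This is the sound pre-screen of the
#' two-step substructure search: every substructure of the query must also
#' be a substructure of any superstructure of the query.
#'
#' @param query_desc,target_desc `descriptor` objects (same dictionary).
#' @return logical.
#' @export
screen_pass <- function(query_desc, target_desc) {
  .check_same_version(query_desc, target_desc)
  !any(query_desc$bits == 1L & target_desc$bits == 0L)
}

.check_same_version <- function(a, b) {
  stopifnot(inherits(a, "descriptor"), inherits(b, "descriptor"))
  if (!identical(a$version, b$version)) {
    stop(sprintf("descriptor dictionary versions differ: '%s' vs '%s'",
                 a$version, b$version))
  }
  invisible(TRUE)
}
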