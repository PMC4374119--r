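#' Configuration for the synthetic fixture generator
#'
#' Defaults emulate the proportions observed in the Wikipedia chemical
#' corpus this package targets: roughly 14% of chemical pages carry no
#' SMILES at all, unparseable codes are dominated by the pyrrole-nitrogen
#' mis-encoding (about 2.7% of entries) with a tail of other syntax errors,
#' and a small fraction of structures recur on several pages. One integer
#' seed drives a single pseudo-random stream; identical seeds give
#' byte-identical corpora.
#'
#' @param seed integer seed for the generator stream.
#' @param n_molecules number of molecules / wiki pages to generate.
#' @param atom_budget length-2 integer range of heavy-atom counts.
#' @param ring_probability probability that a molecule is grown around a
#'   ring template.
#' @param error_mix named proportions per parse-error class.
#' @param duplicate_rate proportion of pages that restate an earlier page's
#'   molecule under a new title.
#' @param missing_rate proportion of pages without any SMILES parameter.
#' @param stereo_pair_rate proportion of pages carrying two stereo-divergent
#'   SMILES.
#' @param multi_identical_rate proportion of pages carrying two SMILES of
#'   the same structure (only the first is kept downstream).
#' @return a `gen_config` object.
#' @export
gen_config <- function(seed = 1L,
                       n_molecules = 100L,
                       atom_budget = c(4L, 12L),
                       ring_probability = 0.35,
                       error_mix = c(PYRROLE_NITROGEN = 0.027,
                                     UNCLOSED_RING = 0.004,
                                     UNCLOSED_PARENTHESIS = 0.004,
                                     BARE_ATOM_NEEDS_BRACKETS = 0.004,
                                     KEKULIZATION_FAILURE = 0.004,
                                     BAD_TOKEN = 0.004,
                                     VALENCE_ERROR = 0.004),
                       duplicate_rate = 0.002,
                       missing_rate = 0.142,
                       stereo_pair_rate = 0.04,
                       multi_identical_rate = 0.04) {
  stopifnot(length(atom_budget) == 2L, atom_budget[1] >= 1L,
            atom_budget[1] <= atom_budget[2],
            ring_probability >= 0, ring_probability <= 1,
            all(error_mix >= 0), duplicate_rate >= 0, missing_rate >= 0)
  total <- sum(error_mix) + duplicate_rate + missing_rate +
    stereo_pair_rate + multi_identical_rate
  if (total > 1) stop("category proportions sum to more than 1")
  structure(list(seed = as.integer(seed),
                 n_molecules = as.integer(n_molecules),
                 atom_budget = as.integer(atom_budget),
                 ring_probability = ring_probability,
                 error_mix = error_mix,
                 duplicate_rate = duplicate_rate,
                 missing_rate = missing_rate,
                 stereo_pair_rate = stereo_pair_rate,
                 multi_identical_rate = multi_identical_rate),
            class = "gen_config")
}

# ring templates the generator can grow substituents on
.ring_templates <- c("c1ccccc1", "c1ccncc1", "c1cc[nH]c1", "c1ccoc1",
                     "c1ccsc1", "c1c[nH]cn1", "C1CCCCC1", "C1CCCC1",
                     "C1CC1", "C1CCOC1", "C1CCNCC1", "c1ccc2ccccc2c1")

# conservative growth valences (guarantee the emitted SMILES reparses)
.grow_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                   F = 1L, Cl = 1L, Br = 1L, I = 1L)

#' Generate one random valid molecule
#'
#' Grows a random tree over common organic elements respecting valences,
#' optionally around an aromatic or aliphatic ring template, and emits a
#' SMILES string that always parses cleanly. Draws from the current RNG
#' stream (seed with `set.seed()` or use [synth_wiki_corpus()] for a fully
#' seeded corpus).
#'
#' @param config a [gen_config()].
#' @return SMILES text.
#' @export
random_molecule <- function(config = gen_config()) {
  budget <- config$atom_budget
  target <- sample(budget[1]:budget[2], 1L)
  g <- NULL
  if (stats::runif(1) < config$ring_probability) {
    fits <- .ring_templates[vapply(.ring_templates, function(t) {
      n_atoms(.template_graph(t)) <= target
    }, logical(1))]
    if (length(fits)) g <- .template_graph(sample(fits, 1L))
  }
  if (is.null(g)) {
    el <- sample(c("C", "N", "O", "S"), 1L, prob = c(0.7, 0.12, 0.12, 0.06))
    g <- new_molgraph(element = el)
    g$atom_pos <- 0L
  }

  bondsum <- integer(n_atoms(g))
  for (b in seq_len(n_bonds(g))) {
    bondsum[g$bond_i[b]] <- bondsum[g$bond_i[b]] + g$bond_order[b]
    bondsum[g$bond_j[b]] <- bondsum[g$bond_j[b]] + g$bond_order[b]
  }
  free <- function(a) {
    if (g$bracket[a]) return(0L)
    if (g$aromatic[a] && g$element[a] != "C") return(0L)
    .grow_valence[[g$element[a]]] - bondsum[a]
  }

  while (n_atoms(g) < target) {
    open <- Filter(function(a) free(a) > 0L, seq_len(n_atoms(g)))
    if (!length(open)) break
    host <- if (length(open) == 1L) open else sample(open, 1L)
    el <- sample(c("C", "N", "O", "S", "F", "Cl", "Br"), 1L,
                 prob = c(0.58, 0.12, 0.12, 0.05, 0.05, 0.05, 0.03))
    order <- 1L
    if (.grow_valence[[el]] >= 2L && free(host) >= 2L &&
        !g$aromatic[host] && stats::runif(1) < 0.12) order <- 2L
    g$element <- c(g$element, el)
    g$isotope <- c(g$isotope, NA_integer_)
    g$charge <- c(g$charge, 0L)
    g$explicit_h <- c(g$explicit_h, NA_integer_)
    g$aromatic <- c(g$aromatic, FALSE)
    g$bracket <- c(g$bracket, FALSE)
    g$parity <- c(g$parity, NA_character_)
    g$parity_order <- c(g$parity_order, list(integer()))
    g$atom_pos <- c(g$atom_pos, 0L)
    a <- n_atoms(g)
    g$bond_i <- c(g$bond_i, host); g$bond_j <- c(g$bond_j, a)
    g$bond_order <- c(g$bond_order, order)
    g$bond_aromatic <- c(g$bond_aromatic, FALSE)
    g$bond_dir <- c(g$bond_dir, NA_character_)
    bondsum[host] <- bondsum[host] + order
    bondsum <- c(bondsum, order)
  }
  g$implicit_h <- rep(0L, n_atoms(g))
  g <- .assign_hydrogens(g)
  write_smiles(g)
}

.template_graph <- function(smi) {
  key <- paste0("tpl_", smi)
  if (is.null(.wikichem_cache[[key]])) {
    .wikichem_cache[[key]] <- parse_smiles(smi)
  }
  .wikichem_cache[[key]]
}

#' Rewrite a molecule from a random starting atom
#'
#' Emits the same graph as SMILES with a random atom order and shuffled
#' neighbor priorities; the output always reparses to an isomorphic graph.
#' Feeds the canonicalization-invariance test suite.
#'
#' @param mol a parsed `molgraph` or SMILES text.
#' @return SMILES text.
#' @export
permuted_smiles <- function(mol) {
  g <- .as_molgraph(mol)
  write_smiles(g, priority = sample(n_atoms(g)))
}

# stereo-divergent SMILES pairs (tetrahedral and cis/trans families)
.stereo_pair_pool <- function() {
  pool <- list()
  for (r in c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CO", "CCO", "CN",
              "CCN", "CCCO", "CCCN")) {
    pool[[length(pool) + 1L]] <- c(sprintf("N[C@@H](%s)C(=O)O", r),
                                   sprintf("N[C@H](%s)C(=O)O", r))
  }
  for (xy in list(c("F", "F"), c("F", "Cl"), c("F", "Br"), c("Cl", "Cl"),
                  c("Cl", "Br"), c("Br", "Br"))) {
    pool[[length(pool) + 1L]] <- c(paste0(xy[1], "/C=C/", xy[2]),
                                   paste0(xy[1], "/C=C\\", xy[2]))
  }
  pool
}

# malformed-SMILES factories per error class; each returns a string whose
# parse yields exactly that class
.make_error_smiles <- function(class, config) {
  switch(class,
    PYRROLE_NITROGEN = {
      base <- sample(c("c1cc[nH]c1", "c1ccc2[nH]ccc2c1", "c1cc[nH]n1",
                       "c1ccc2[nH]cnc2c1", "Cc1cc[nH]c1"), 1L)
      sub("[nH]", "n", base, fixed = TRUE)
    },
    UNCLOSED_RING = sample(c("C1CCCCC", "C1CC(C)CC", "C1CCOCC", "C1CC(O)C"), 1L),
    UNCLOSED_PARENTHESIS = paste0(random_molecule(config), "(C"),
    BARE_ATOM_NEEDS_BRACKETS = paste0(sample(c("Hg", "Zn", "Al", "Mg"), 1L),
                                      random_molecule(config)),
    KEKULIZATION_FAILURE = sample(c("c1cccc1", "c1ccccc1c", "Cc1cccc1"), 1L),
    BAD_TOKEN = paste0(random_molecule(config), "*"),
    VALENCE_ERROR = sample(c("C(C)(C)(C)(C)C", "O=C(C)(C)C",
                             "CC(C)(C)(C)O"), 1L),
    stop("unknown error class ", class))
}

.chembox_markup <- function(title, smiles_fields, nowiki = logical(0)) {
  body <- "{{Chembox\n| Name = %s\n| Section1 = {{Chembox Identifiers\n%s}}\n| Section2 = {{Chembox Properties\n| MolarMass = \n}}\n}}"
  lines <- ""
  k <- 0L
  for (nm in names(smiles_fields)) {
    k <- k + 1L
    val <- smiles_fields[[nm]]
    if (length(nowiki) >= k && nowiki[k]) {
      val <- paste0("<nowiki>", val, "</nowiki>")
    }
    lines <- paste0(lines, sprintf("| %s = %s\n", nm, val))
  }
  sprintf(body, title, lines)
}

.drugbox_markup <- function(title, smiles_fields, nowiki = logical(0)) {
  lines <- ""
  k <- 0L
  for (nm in names(smiles_fields)) {
    k <- k + 1L
    val <- smiles_fields[[nm]]
    if (length(nowiki) >= k && nowiki[k]) {
      val <- paste0("<nowiki>", val, "</nowiki>")
    }
    lines <- paste0(lines, sprintf("| %s = %s\n", nm, val))
  }
  sprintf("{{Infobox drug\n| drug_name = %s\n%s| CAS_number = \n}}", title, lines)
}

#' Generate a synthetic wiki corpus with ground truth
#'
#' Emits Chembox and Drugbox pages exhibiting every behavior the extraction
#' pipeline must handle: single valid SMILES, multiple identical-structure
#' SMILES, stereo-divergent pairs, pages with no SMILES, each parse-error
#' class at its configured proportion (pyrrole cases built by stripping
#' `[nH]` to `n` from valid heteroaromatics), and cross-page duplicates. A
#' ground-truth manifest with the expected pipeline counts is returned
#' alongside.
#'
#' @param config a [gen_config()]; `config$seed` seeds the whole corpus.
#' @return list with `pages` (list of [wiki_page()]) and `manifest`.
#' @export
synth_wiki_corpus <- function(config = gen_config()) {
  set.seed(config$seed)
  n <- config$n_molecules
  err_classes <- names(config$error_mix)
  probs <- c(config$error_mix, missing = config$missing_rate,
             stereo = config$stereo_pair_rate,
             multi = config$multi_identical_rate,
             duplicate = config$duplicate_rate)
  cum <- cumsum(probs)

  pages <- vector("list", n)
  cats <- character(n)
  used_canonical <- character()
  mol_pool <- list()     # plain molecules available for duplication
  stereo_pool <- .stereo_pair_pool()
  stereo_left <- seq_along(stereo_pool)

  total_params <- 0L; kept <- 0L; dropped <- 0L; missing_pages <- 0L
  errors_by_class <- stats::setNames(integer(length(err_classes)), err_classes)
  kept_canonicals <- list()  # per kept entry: list(page, canonical)

  fresh_molecule <- function() {
    for (try in 1:25) {
      smi <- random_molecule(config)
      can <- canonical_smiles(smi)$canonical_smiles
      if (!(can %in% used_canonical)) {
        used_canonical <<- c(used_canonical, can)
        return(list(smiles = smi, canonical = can))
      }
    }
    list(smiles = smi, canonical = can)  # accept a rare collision
  }

  for (i in seq_len(n)) {
    title <- sprintf("Synthetic compound %04d", i)
    u <- stats::runif(1)
    cat_i <- "plain"
    for (k in seq_along(cum)) if (u < cum[k]) { cat_i <- names(cum)[k]; break }
    if (cat_i == "duplicate" && !length(mol_pool)) cat_i <- "plain"

    fields <- list(); nowiki <- logical(0)
    if (cat_i %in% err_classes) {
      bad <- .make_error_smiles(cat_i, config)
      fields <- stats::setNames(list(bad), "SMILES")
      total_params <- total_params + 1L
      errors_by_class[cat_i] <- errors_by_class[cat_i] + 1L
    } else if (cat_i == "missing") {
      missing_pages <- missing_pages + 1L
    } else if (cat_i == "stereo") {
      if (!length(stereo_left)) stereo_left <- seq_along(stereo_pool)
      pick <- if (length(stereo_left) == 1L) stereo_left else
        sample(stereo_left, 1L)
      stereo_left <- setdiff(stereo_left, pick)
      pair <- stereo_pool[[pick]]
      fields <- stats::setNames(as.list(pair), c("SMILES", "SMILES1"))
      total_params <- total_params + 2L
      kept <- kept + 2L
      for (smi in pair) {
        kept_canonicals[[length(kept_canonicals) + 1L]] <-
          list(page = title,
               canonical = canonical_smiles(smi)$canonical_smiles)
      }
    } else if (cat_i == "multi") {
      m <- fresh_molecule()
      alt <- permuted_smiles(m$smiles)
      fields <- stats::setNames(list(m$smiles, alt), c("SMILES", "SMILES1"))
      total_params <- total_params + 2L
      kept <- kept + 1L; dropped <- dropped + 1L
      kept_canonicals[[length(kept_canonicals) + 1L]] <-
        list(page = title, canonical = m$canonical)
    } else if (cat_i == "duplicate") {
      src <- mol_pool[[sample(length(mol_pool), 1L)]]
      alt <- permuted_smiles(src$smiles)
      fields <- stats::setNames(list(alt), "SMILES")
      total_params <- total_params + 1L
      kept <- kept + 1L
      kept_canonicals[[length(kept_canonicals) + 1L]] <-
        list(page = title, canonical = src$canonical)
    } else {  # plain
      m <- fresh_molecule()
      fields <- stats::setNames(list(m$smiles), "SMILES")
      total_params <- total_params + 1L
      kept <- kept + 1L
      kept_canonicals[[length(kept_canonicals) + 1L]] <-
        list(page = title, canonical = m$canonical)
      mol_pool[[length(mol_pool) + 1L]] <- m
    }

    if (length(fields)) nowiki <- stats::runif(length(fields)) < 0.2
    markup <- if (stats::runif(1) < 0.5) {
      .chembox_markup(title, fields, nowiki)
    } else {
      .drugbox_markup(title, fields, nowiki)
    }
    pages[[i]] <- wiki_page(title, markup)
    cats[i] <- cat_i
  }

  # expected duplicate groups: canonical structures kept on >= 2 pages
  canon <- vapply(kept_canonicals, `[[`, character(1), "canonical")
  pg <- vapply(kept_canonicals, `[[`, character(1), "page")
  dup_groups <- 0L; dup_sizes <- integer()
  for (cn in unique(canon)) {
    rows <- which(canon == cn)
    if (length(rows) >= 2L && length(unique(pg[rows])) >= 2L) {
      dup_groups <- dup_groups + 1L
      dup_sizes <- c(dup_sizes, length(rows))
    }
  }

  manifest <- list(
    seed = config$seed,
    pages = n,
    total_smiles_params = total_params,
    kept = kept,
    dropped_within_page = dropped,
    errors_by_class = as.list(errors_by_class),
    missing_pages = missing_pages,
    duplicate_groups = dup_groups,
    duplicate_group_sizes = dup_sizes,
    categories = data.frame(
      title = vapply(pages, `[[`, character(1), "title"),
      category = cats, stringsAsFactors = FALSE)
  )
  list(pages = pages, manifest = manifest)
}
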