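# Independent oracles for the acceptance and property suites. These are
# deliberately naive re-implementations, kept separate from the package's
# algorithms: plain injection enumeration instead of the C++ VF2 engine,
# exhaustive double-bond assignment instead of the matching-based kekulizer.

# --- brute-force subgraph monomorphism -------------------------------------

# Enumerate injective query->target mappings in plain query-atom order with
# incremental bond checking only. Returns TRUE / count of distinct images.
oracle_match <- function(query, target, aromatic_strict = TRUE,
                         charge_strict = TRUE, count = FALSE) {
  q <- query; t <- target
  nq <- n_atoms(q); nt <- n_atoms(t)
  if (nq > nt) return(if (count) 0L else FALSE)
  th_q <- wikichem:::total_h(q); th_t <- wikichem:::total_h(t)
  qeh <- q$explicit_h

  tbond <- matrix(0L, nt, nt)
  for (b in seq_len(n_bonds(t))) {
    tbond[t$bond_i[b], t$bond_j[b]] <- b
    tbond[t$bond_j[b], t$bond_i[b]] <- b
  }
  atom_ok <- function(qa, ta) {
    if (q$element[qa] != t$element[ta]) return(FALSE)
    if (aromatic_strict && q$aromatic[qa] != t$aromatic[ta]) return(FALSE)
    if (charge_strict && q$charge[qa] != t$charge[ta]) return(FALSE)
    if (q$bracket[qa] && !is.na(qeh[qa]) && th_t[ta] < qeh[qa]) return(FALSE)
    TRUE
  }
  bond_ok <- function(qb, tb) {
    qa <- q$bond_aromatic[qb]; ta <- t$bond_aromatic[tb]
    if (aromatic_strict) {
      if (qa != ta) return(FALSE)
      return(qa || q$bond_order[qb] == t$bond_order[tb])
    }
    if (qa) return(ta || t$bond_order[tb] <= 2L)
    if (q$bond_order[qb] == 3L) return(!ta && t$bond_order[tb] == 3L)
    if (ta) return(q$bond_order[qb] <= 2L)
    q$bond_order[qb] == t$bond_order[tb]
  }

  images <- new.env(hash = TRUE)
  found <- FALSE
  mapping <- integer(nq)
  recurse <- function(k) {
    if (found && !count) return()
    if (k > nq) {
      if (!count) { found <<- TRUE; return() }
      assign(paste(sort(mapping), collapse = ","), TRUE, envir = images)
      return()
    }
    for (ta in seq_len(nt)) {
      if (ta %in% mapping[seq_len(k - 1L)]) next
      if (!atom_ok(k, ta)) next
      ok <- TRUE
      for (b in seq_len(n_bonds(q))) {
        i <- q$bond_i[b]; j <- q$bond_j[b]
        if (i == k && j < k) {
          tb <- tbond[ta, mapping[j]]
          if (tb == 0L || !bond_ok(b, tb)) { ok <- FALSE; break }
        } else if (j == k && i < k) {
          tb <- tbond[ta, mapping[i]]
          if (tb == 0L || !bond_ok(b, tb)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      mapping[k] <<- ta
      recurse(k + 1L)
      mapping[k] <<- 0L
      if (found && !count) return()
    }
  }
  recurse(1L)
  if (count) length(ls(images)) else found
}

# --- exhaustive kekulization oracle ----------------------------------------

# All valid double-bond assignments over the aromatic bonds of a parsed
# graph, as a list of sorted bond-index vectors. Donor rules restated here
# independently of the package implementation.
oracle_kekulizations <- function(g) {
  arom_bonds <- which(g$bond_aromatic)
  deg <- tabulate(c(g$bond_i, g$bond_j), nbins = n_atoms(g))
  eh <- g$explicit_h; eh[is.na(eh)] <- 0L
  ext_double <- logical(n_atoms(g))
  for (b in seq_len(n_bonds(g))) {
    if (!g$bond_aromatic[b] && g$bond_order[b] >= 2L) {
      ext_double[g$bond_i[b]] <- TRUE; ext_double[g$bond_j[b]] <- TRUE
    }
  }
  needs <- vapply(seq_len(n_atoms(g)), function(a) {
    if (!g$aromatic[a] || ext_double[a]) return(FALSE)
    el <- g$element[a]; qch <- g$charge[a]
    conn <- deg[a] + (if (g$bracket[a]) eh[a] else 0L)
    if (el == "C") return(qch == 0L)
    if (el %in% c("N", "P", "As")) {
      return(!((qch == 0L && conn >= 3L) || (qch == -1L && conn == 2L)))
    }
    if (el %in% c("O", "S", "Se")) return(qch > 0L)
    if (el == "B") return(FALSE)
    TRUE
  }, logical(1))

  res <- list()
  nb <- length(arom_bonds)
  if (nb > 20L) stop("oracle_kekulizations: system too large")
  for (mask in 0:(2^nb - 1L)) {
    dbl <- arom_bonds[bitwAnd(mask, 2^(seq_len(nb) - 1L)) > 0]
    cnt <- integer(n_atoms(g))
    for (b in dbl) {
      cnt[g$bond_i[b]] <- cnt[g$bond_i[b]] + 1L
      cnt[g$bond_j[b]] <- cnt[g$bond_j[b]] + 1L
    }
    ok <- all(cnt[needs] == 1L) && all(cnt[!needs] == 0L)
    if (ok) res[[length(res) + 1L]] <- sort(dbl)
  }
  res
}

# double-bond endpoint pairs of a kekulized graph, sorted, for comparison
# against the oracle's lexicographically smallest assignment
kekule_pairs <- function(g) {
  dbl <- which(g$bond_aromatic & g$bond_order == 2L)
  m <- t(vapply(dbl, function(b) {
    sort(c(g$bond_i[b], g$bond_j[b]))
  }, integer(2)))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# --- random connected induced subgraph -------------------------------------

random_connected_subgraph <- function(g, k = NULL) {
  n <- n_atoms(g)
  adj <- wikichem:::mol_adjacency(g)$nbr
  comp <- wikichem:::mol_components(g)
  main <- which(comp == which.max(tabulate(comp)))
  if (is.null(k)) k <- sample(seq_len(max(1L, length(main))), 1L)
  start <- sample(main, 1L)
  chosen <- start
  frontier <- setdiff(adj[[start]], chosen)
  while (length(chosen) < k && length(frontier)) {
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    chosen <- c(chosen, nxt)
    frontier <- setdiff(unique(c(frontier, adj[[nxt]])), chosen)
  }
  wikichem:::induced_subgraph(g, sort(chosen))
}

# --- RDKit oracle (independent toolkit) ------------------------------------

rdkit_canonical <- function(smiles) {
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "for line in sys.stdin:",
    "    s = line.strip()",
    "    if not s:",
    "        continue",
    "    m = Chem.MolFromSmiles(s)",
    "    print('PARSE_FAIL' if m is None else Chem.MolToSmiles(m))",
    sep = "\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  input = smiles, stdout = TRUE))
  out
}

have_rdkit <- function() {
  ok <- tryCatch(
    identical(rdkit_canonical("CCO"), "CCO"),
    error = function(e) FALSE, warning = function(w) FALSE)
  isTRUE(ok)
}

# --- shared fixtures --------------------------------------------------------

# curated set of 100 structurally distinct small molecules
distinct_molecules_100 <- function() {
  c("C", "CC", "CCC", "CCCC", "CC(C)C", "CCCCC", "CC(C)CC", "C(C)(C)(C)C",
    "CCCCCC", "CO", "CCO", "CCCO", "CC(O)C", "OCCO", "OCC(O)CO", "COC",
    "CCOC", "CCOCC", "C=O", "CC=O", "CCC=O", "CC(=O)C", "CC(=O)O",
    "C(=O)O", "CC(=O)OC", "CC(=O)N", "C(=O)N", "NC(=O)N", "CN", "CCN",
    "CCCN", "CC(N)C", "CNC", "CN(C)C", "NCCN", "NCCO", "N", "O", "C=C",
    "CC=C", "CC=CC", "C=CC=C", "C#C", "CC#C", "C#N", "CC#N", "CS", "CCS",
    "CSC", "CSSC", "S=C=S", "CF", "CCl", "CBr", "CI", "C(F)(F)F",
    "ClCCl", "ClC(Cl)Cl", "FCC(F)F", "ClCCBr", "c1ccccc1", "Cc1ccccc1",
    "CCc1ccccc1", "Cc1ccccc1C", "Cc1ccc(C)cc1", "Cc1cccc(C)c1",
    "Oc1ccccc1", "COc1ccccc1", "Nc1ccccc1", "Clc1ccccc1", "Fc1ccccc1",
    "Brc1ccccc1", "O=Cc1ccccc1", "OC(=O)c1ccccc1", "N#Cc1ccccc1",
    "C=Cc1ccccc1", "c1ccncc1", "Cc1ccccn1", "c1cnccn1", "c1ncncc1",
    "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "c1c[nH]cn1", "c1cc[nH]n1",
    "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1", "c1ccc2occc2c1",
    "c1ccc2ncccc2c1", "c1ccccc1-c1ccccc1", "c1ccccc1Cc1ccccc1",
    "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCOC1", "C1CCNC1",
    "C1CCSC1", "O=C1CCCCC1", "C1CCNCC1", "O1CCOCC1")
}

# small deterministic config for generator-driven tests
test_config <- function(seed = 1L, n = 30L, ...) {
  gen_config(seed = seed, n_molecules = n, ...)
}

# generate k random molecules from the current RNG stream
random_molecules <- function(k, config = gen_config()) {
  vapply(seq_len(k), function(i) random_molecule(config), character(1))
}
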