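#' Kekulize the aromatic subgraph of a molecule
#'
#' Resolves single/double orders on aromatic bonds so that every aromatic
#' atom that requires a double bond (i.e. is not a lone-pair donor such as
#' `[nH]`, `[n-]`, aromatic O/S, or a charged carbon) receives exactly one.
#' Solved as a perfect matching on the subgraph of double-bond-requiring
#' atoms; among valid matchings the one whose sorted list of double-bond
#' endpoint pairs is lexicographically smallest is chosen, so the result is
#' deterministic.
#'
#' @param g a `molgraph` (may contain aromatic atoms/bonds).
#' @param use_total_h use computed total hydrogen counts in the donor rule
#'   (for re-kekulization after aromaticity perception); by default only
#'   bracket-explicit hydrogens are visible, as required at parse time.
#' @return the graph with aromatic bond orders assigned, or a `parse_issue`
#'   of class `KEKULIZATION_FAILURE` when no perfect matching exists.
#' @export
kekulize <- function(g, use_total_h = FALSE) {
  stopifnot(is_molgraph(g))
  if (!any(g$aromatic)) return(g)
  if (is.null(g$atom_pos)) g$atom_pos <- rep(0L, n_atoms(g))

  needs <- .needs_double(g, use_total_h = use_total_h)
  nd <- which(g$aromatic & needs)

  # adjacency restricted to aromatic bonds between two double-requiring atoms
  n <- n_atoms(g)
  cand <- vector("list", n)
  ndset <- logical(n); ndset[nd] <- TRUE
  arom_bond_ids <- which(g$bond_aromatic)
  bond_of <- new.env(hash = TRUE)
  for (b in arom_bond_ids) {
    i <- g$bond_i[b]; j <- g$bond_j[b]
    assign(paste(min(i, j), max(i, j)), b, envir = bond_of)
    if (ndset[i] && ndset[j]) {
      cand[[i]] <- c(cand[[i]], j)
      cand[[j]] <- c(cand[[j]], i)
    }
  }
  for (a in nd) cand[[a]] <- sort(cand[[a]])

  matched <- integer(n)  # 0 = unmatched
  if (length(nd) %% 2L == 1L || !.match_backtrack(nd, cand, matched, n)) {
    bad <- if (length(nd)) nd[1] else which(g$aromatic)[1]
    return(parse_issue("KEKULIZATION_FAILURE", g$atom_pos[bad],
      sprintf("no kekule structure: %d aromatic atoms require a double bond",
              length(nd))))
  }
  matched <- .kek_result$matched

  for (b in arom_bond_ids) {
    i <- g$bond_i[b]; j <- g$bond_j[b]
    g$bond_order[b] <- if (matched[i] == j) 2L else 1L
  }
  g
}

# result channel for the backtracking matcher
.kek_result <- new.env(parent = emptyenv())

# Greedy-lowest backtracking perfect matching. Taking the smallest unmatched
# atom and trying its candidates in ascending order yields the matching whose
# sorted (min,max) pair list is lexicographically smallest.
.match_backtrack <- function(nd, cand, matched, n) {
  recurse <- function(matched) {
    u <- 0L
    for (a in nd) if (matched[a] == 0L) { u <- a; break }
    if (u == 0L) { .kek_result$matched <- matched; return(TRUE) }
    for (v in cand[[u]]) {
      if (matched[v] != 0L) next
      matched[u] <- v; matched[v] <- u
      if (recurse(matched)) return(TRUE)
      matched[u] <- 0L; matched[v] <- 0L
    }
    FALSE
  }
  recurse(matched)
}

# Which aromatic atoms require an in-ring double bond. Donors: [nH]/n with
# three connections, [n-], neutral aromatic O/S/Se, charged carbon, boron
# (empty p orbital), and any atom already carrying a non-aromatic double or
# triple bond (exocyclic =O and friends).
.needs_double <- function(g, use_total_h = FALSE) {
  n <- n_atoms(g)
  deg <- atom_degree(g)
  h <- if (use_total_h) total_h(g) else {
    eh <- g$explicit_h; eh[is.na(eh)] <- 0L
    ifelse(g$bracket, eh, 0L)
  }
  ext_double <- logical(n)
  for (b in seq_len(n_bonds(g))) {
    if (!g$bond_aromatic[b] && g$bond_order[b] >= 2L) {
      ext_double[g$bond_i[b]] <- TRUE
      ext_double[g$bond_j[b]] <- TRUE
    }
  }
  out <- logical(n)
  for (a in which(g$aromatic)) {
    if (ext_double[a]) next
    el <- g$element[a]; q <- g$charge[a]
    conn <- deg[a] + h[a]
    out[a] <- switch(el,
      C = q == 0L,
      N = , P = , As = !((q == 0L && conn >= 3L) || (q == -1L && conn == 2L)),
      O = , S = , Se = q > 0L,
      B = FALSE,
      TRUE)
  }
  out
}

# Aromaticity perception on rings written in kekule form: a 5- or 6-membered
# ring of eligible elements becomes aromatic when every (not yet aromatic)
# member either carries an endocyclic double bond or is a lone-pair donor,
# and carries no exocyclic double/triple bond. Huckel electron counting is
# deliberately not enforced; kekulizability is the acceptance test.
.perceive_aromatic <- function(g) {
  rb <- ring_bonds(g)
  if (!any(rb)) return(list(graph = g, changed = FALSE))
  cycles <- find_cycles(g, sizes = c(5L, 6L))
  if (!length(cycles)) return(list(graph = g, changed = FALSE))

  deg <- atom_degree(g)
  h <- total_h(g)
  n <- n_atoms(g)
  ring_double <- logical(n); exo_double <- logical(n); has_triple <- logical(n)
  for (b in seq_len(n_bonds(g))) {
    if (g$bond_order[b] == 3L) {
      has_triple[g$bond_i[b]] <- TRUE; has_triple[g$bond_j[b]] <- TRUE
    }
    if (g$bond_order[b] == 2L && !g$bond_aromatic[b]) {
      if (rb[b]) {
        ring_double[g$bond_i[b]] <- TRUE; ring_double[g$bond_j[b]] <- TRUE
      } else {
        exo_double[g$bond_i[b]] <- TRUE; exo_double[g$bond_j[b]] <- TRUE
      }
    }
  }

  donor <- function(a) {
    el <- g$element[a]; q <- g$charge[a]; conn <- deg[a] + h[a]
    switch(el,
      N = , P = , As = (q == 0L && conn >= 3L) || (q == -1L && conn == 2L),
      O = , S = , Se = q == 0L && deg[a] == 2L,
      C = q != 0L,
      B = TRUE,
      FALSE)
  }

  mark_atoms <- integer(); mark_cycles <- list()
  for (cy in cycles) {
    ok <- TRUE
    for (a in cy) {
      if (g$aromatic[a]) next
      if (!(g$element[a] %in% .aromatic_elements) || has_triple[a] ||
          exo_double[a] || !(ring_double[a] || donor(a))) {
        ok <- FALSE; break
      }
    }
    if (ok && !all(g$aromatic[cy])) {
      mark_atoms <- union(mark_atoms, cy)
      mark_cycles[[length(mark_cycles) + 1L]] <- cy
    }
  }
  if (!length(mark_atoms)) return(list(graph = g, changed = FALSE))

  g$aromatic[mark_atoms] <- TRUE
  for (cy in mark_cycles) {
    m <- length(cy)
    for (k in seq_len(m)) {
      a <- cy[k]; b2 <- cy[if (k == m) 1L else k + 1L]
      bid <- which((g$bond_i == a & g$bond_j == b2) |
                   (g$bond_i == b2 & g$bond_j == a))
      g$bond_aromatic[bid] <- TRUE
    }
  }
  list(graph = g, changed = TRUE)
}
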