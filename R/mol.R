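#' Molecular graph objects
#'
#' A `molgraph` is the package's chemical graph: parallel atom vectors plus a
#' bond table. Atoms carry element, optional isotope mass number, formal
#' charge, an explicit hydrogen count when (and only when) the atom came from
#' a bracket expression, an aromatic flag, and an optional tetrahedral parity
#' with the neighbor order observed at parse time. Bonds carry endpoints,
#' order (after kekulization every former aromatic bond has a resolved 1/2
#' order), an aromatic flag and an optional cis/trans direction mark.
#'
#' @param element character vector of element symbols.
#' @param isotope integer mass numbers (`NA` when unspecified).
#' @param charge integer formal charges.
#' @param explicit_h integer bracket hydrogen counts (`NA` for bare atoms).
#' @param aromatic logical aromatic flags.
#' @param bracket logical, whether the atom came from a bracket expression.
#' @param bond_i,bond_j integer bond endpoints (1-based atom indices).
#' @param bond_order integer bond orders (1, 2 or 3).
#' @param bond_aromatic logical aromatic-bond flags.
#'
#' @return `new_molgraph()` returns a `molgraph` object.
#' @keywords internal
new_molgraph <- function(element = character(),
                         isotope = NA_integer_,
                         charge = 0L,
                         explicit_h = NA_integer_,
                         aromatic = FALSE,
                         bracket = FALSE,
                         bond_i = integer(),
                         bond_j = integer(),
                         bond_order = integer(),
                         bond_aromatic = logical()) {
  n <- length(element)
  g <- list(
    element = element,
    isotope = rep_len(as.integer(isotope), n),
    charge = rep_len(as.integer(charge), n),
    explicit_h = rep_len(as.integer(explicit_h), n),
    aromatic = rep_len(aromatic, n),
    bracket = rep_len(bracket, n),
    parity = rep_len(NA_character_, n),
    parity_order = vector("list", n),
    bond_i = as.integer(bond_i),
    bond_j = as.integer(bond_j),
    bond_order = as.integer(bond_order),
    bond_aromatic = rep_len(bond_aromatic, length(bond_i)),
    bond_dir = rep_len(NA_character_, length(bond_i)),
    implicit_h = rep_len(0L, n),
    n_fragments = 1L,
    multi_fragment = FALSE
  )
  class(g) <- "molgraph"
  g
}

#' @rdname new_molgraph
#' @param x object to test.
is_molgraph <- function(x) inherits(x, "molgraph")

#' Number of atoms / bonds in a molecular graph
#' @param g a `molgraph`.
#' @return integer count.
#' @export
n_atoms <- function(g) length(g$element)

#' @rdname n_atoms
#' @export
n_bonds <- function(g) length(g$bond_i)

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d atoms, %d bonds, %s>\n",
              n_atoms(x), n_bonds(x), molecular_formula(x)))
  invisible(x)
}

#' @export
format.molgraph <- function(x, ...) {
  sprintf("<molgraph %s>", molecular_formula(x))
}

# Adjacency as two parallel lists: nbr[[a]] = neighbor atom indices,
# abond[[a]] = corresponding bond indices, in bond-table order.
mol_adjacency <- function(g) {
  n <- n_atoms(g)
  nbr <- vector("list", n)
  abond <- vector("list", n)
  for (b in seq_len(n_bonds(g))) {
    i <- g$bond_i[b]; j <- g$bond_j[b]
    nbr[[i]] <- c(nbr[[i]], j); abond[[i]] <- c(abond[[i]], b)
    nbr[[j]] <- c(nbr[[j]], i); abond[[j]] <- c(abond[[j]], b)
  }
  for (a in seq_len(n)) {
    if (is.null(nbr[[a]])) { nbr[[a]] <- integer(); abond[[a]] <- integer() }
  }
  list(nbr = nbr, bond = abond)
}

# Total hydrogen count per atom (bracket atoms: the explicit spec; bare
# atoms: the computed implicit count).
total_h <- function(g) {
  eh <- g$explicit_h
  eh[is.na(eh)] <- 0L
  ifelse(g$bracket, eh, g$implicit_h)
}

atom_degree <- function(g) {
  tabulate(c(g$bond_i, g$bond_j), nbins = n_atoms(g))
}

# Connected components; returns integer membership vector.
mol_components <- function(g) {
  n <- n_atoms(g)
  adj <- mol_adjacency(g)$nbr
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s; comp[s] <- k
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      for (b in adj[[a]]) if (comp[b] == 0L) { comp[b] <- k; queue <- c(queue, b) }
    }
  }
  comp
}

# Logical vector over bonds: TRUE when the bond lies on a cycle (is not a
# bridge). Decided by connectivity of the endpoints with the bond removed;
# molecules are small, so the quadratic approach is fine.
ring_bonds <- function(g) {
  m <- n_bonds(g)
  out <- logical(m)
  if (m == 0L) return(out)
  adj <- mol_adjacency(g)
  for (b in seq_len(m)) {
    src <- g$bond_i[b]; dst <- g$bond_j[b]
    seen <- logical(n_atoms(g)); seen[src] <- TRUE
    queue <- src; found <- FALSE
    while (length(queue) && !found) {
      a <- queue[[1]]; queue <- queue[-1]
      nb <- adj$nbr[[a]]; bb <- adj$bond[[a]]
      for (k in seq_along(nb)) {
        if (bb[k] == b) next
        v <- nb[k]
        if (v == dst) { found <- TRUE; break }
        if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
      }
    }
    out[b] <- found
  }
  out
}

ring_atoms <- function(g, rb = ring_bonds(g)) {
  out <- logical(n_atoms(g))
  out[c(g$bond_i[rb], g$bond_j[rb])] <- TRUE
  out
}

# Size of the smallest ring through each atom, 0 for acyclic atoms.
smallest_ring_size <- function(g) {
  n <- n_atoms(g)
  out <- integer(n)
  rb <- ring_bonds(g)
  if (!any(rb)) return(out)
  adj <- mol_adjacency(g)
  for (a in which(ring_atoms(g, rb))) {
    best <- 0L
    inc <- which((g$bond_i == a | g$bond_j == a) & rb)
    for (b in inc) {
      other <- if (g$bond_i[b] == a) g$bond_j[b] else g$bond_i[b]
      # shortest path a -> other avoiding bond b, ring bonds only
      dist <- rep(NA_integer_, n); dist[a] <- 0L
      queue <- a
      while (length(queue) && is.na(dist[other])) {
        u <- queue[[1]]; queue <- queue[-1]
        nb <- adj$nbr[[u]]; bb <- adj$bond[[u]]
        for (k in seq_along(nb)) {
          if (bb[k] == b || !rb[bb[k]]) next
          v <- nb[k]
          if (is.na(dist[v])) { dist[v] <- dist[u] + 1L; queue <- c(queue, v) }
        }
      }
      if (!is.na(dist[other])) {
        sz <- dist[other] + 1L
        if (best == 0L || sz < best) best <- sz
      }
    }
    out[a] <- best
  }
  out
}

# All simple cycles of the requested sizes in the ring-bond subgraph, each as
# a vector of atom indices. Deduplicated by rotation/reflection.
find_cycles <- function(g, sizes = c(5L, 6L)) {
  rb <- ring_bonds(g)
  if (!any(rb)) return(list())
  adj <- mol_adjacency(g)
  maxlen <- max(sizes)
  cycles <- list()
  seen_keys <- character()
  n <- n_atoms(g)
  for (start in seq_len(n)) {
    # DFS paths start -> ... -> start, only visiting atoms >= start
    stack <- list(list(path = start))
    while (length(stack)) {
      fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      path <- fr$path
      u <- path[length(path)]
      nb <- adj$nbr[[u]]; bb <- adj$bond[[u]]
      for (k in seq_along(nb)) {
        if (!rb[bb[k]]) next
        v <- nb[k]
        if (v == start && length(path) %in% sizes && length(path) > 2L) {
          rot <- path  # starts at the minimum atom already (start <= all)
          key1 <- paste(rot, collapse = ",")
          rev_rot <- c(rot[1], rev(rot[-1]))
          key2 <- paste(rev_rot, collapse = ",")
          if (!(key1 %in% seen_keys) && !(key2 %in% seen_keys)) {
            seen_keys <- c(seen_keys, key1)
            cycles[[length(cycles) + 1L]] <- rot
          }
        } else if (v > start && !(v %in% path) && length(path) < maxlen) {
          stack[[length(stack) + 1L]] <- list(path = c(path, v))
        }
      }
    }
  }
  cycles
}

# Induced subgraph on the given atom indices (in the given order). Atom
# properties (including hydrogen counts, parity flags dropped) are retained.
induced_subgraph <- function(g, atoms) {
  atoms <- as.integer(atoms)
  map <- integer(n_atoms(g)); map[atoms] <- seq_along(atoms)
  keep <- map[g$bond_i] > 0L & map[g$bond_j] > 0L
  sub <- new_molgraph(
    element = g$element[atoms],
    isotope = g$isotope[atoms],
    charge = g$charge[atoms],
    explicit_h = g$explicit_h[atoms],
    aromatic = g$aromatic[atoms],
    bracket = g$bracket[atoms],
    bond_i = map[g$bond_i[keep]],
    bond_j = map[g$bond_j[keep]],
    bond_order = g$bond_order[keep],
    bond_aromatic = g$bond_aromatic[keep]
  )
  sub$implicit_h <- g$implicit_h[atoms]
  sub
}

# Largest connected component of a graph (ties broken by lowest atom index).
largest_component <- function(g) {
  comp <- mol_components(g)
  if (max(comp) == 1L) return(g)
  sizes <- tabulate(comp)
  keep <- which(comp == which.max(sizes))
  induced_subgraph(g, keep)
}
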