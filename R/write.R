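# SMILES writer. One engine serves both the canonical generator (priority =
# canonical ranks) and the fixture permuter (priority = random permutation):
# each component is written depth-first from its lowest-priority atom,
# neighbors visited in ascending priority, ring-closure digits assigned in
# order of first encounter with reuse after closing.

write_smiles <- function(g, priority = seq_len(n_atoms(g))) {
  stopifnot(is_molgraph(g), length(priority) == n_atoms(g))
  n <- n_atoms(g)
  if (n == 0L) return("")
  adj <- mol_adjacency(g)
  comp <- mol_components(g)
  configs <- .stereo_double_configs(g)

  pieces <- character()
  comp_order <- order(vapply(seq_len(max(comp)), function(k) {
    min(priority[comp == k])
  }, numeric(1)))
  for (k in comp_order) {
    atoms_k <- which(comp == k)
    start <- atoms_k[which.min(priority[atoms_k])]
    pieces <- c(pieces, .write_component(g, adj, priority, start, configs))
  }
  paste0(pieces, collapse = ".")
}

.write_component <- function(g, adj, priority, start, configs) {
  # --- plan pass: DFS tree, back edges, write order --------------------------
  n <- n_atoms(g)
  visited <- logical(n)
  parent <- integer(n)
  parent_bond <- integer(n)
  children <- vector("list", n)
  child_bond <- vector("list", n)
  edge_used <- logical(n_bonds(g))
  write_pos <- integer(n)
  order_seen <- integer(0)
  ring_open <- vector("list", n)  # at opener: list of c(partner, bond)
  ring_close <- vector("list", n)

  dfs <- function(u) {
    visited[u] <<- TRUE
    order_seen <<- c(order_seen, u)
    write_pos[u] <<- length(order_seen)
    nb <- adj$nbr[[u]]; bb <- adj$bond[[u]]
    ord <- order(priority[nb])
    for (k in ord) {
      v <- nb[k]; b <- bb[k]
      if (edge_used[b]) next
      if (visited[v]) {
        edge_used[b] <<- TRUE
        ring_open[[v]] <<- c(ring_open[[v]], list(c(v = u, b = b)))
        ring_close[[u]] <<- c(ring_close[[u]], list(c(v = v, b = b)))
      } else {
        edge_used[b] <<- TRUE
        parent[v] <<- u; parent_bond[v] <<- b
        children[[u]] <<- c(children[[u]], v)
        child_bond[[u]] <<- c(child_bond[[u]], b)
        dfs(v)
      }
    }
  }
  dfs(start)

  # --- ring digit assignment -------------------------------------------------
  # opening at the earlier-written endpoint; digits allocated smallest-free
  digit_of_bond <- list()      # bond id -> digit string
  free <- NULL
  next_digit <- 1L
  alloc <- function() {
    if (length(free)) { d <- free[1]; free <<- free[-1]; return(d) }
    d <- next_digit; next_digit <<- next_digit + 1L; d
  }
  fmt_digit <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)
  open_digits <- vector("list", n)  # per atom: list(list(v, b, d))
  close_digits <- vector("list", n)
  for (u in order_seen) {
    # digits closing at u become reusable before u opens new ones
    for (e in close_digits[[u]]) free <- sort(c(free, e$d))
    ro <- ring_open[[u]]
    if (length(ro)) {
      # order openings by the write position of the closing endpoint
      pos <- vapply(ro, function(e) write_pos[e[["v"]]], integer(1))
      ro <- ro[order(pos)]
      for (e in ro) {
        d <- alloc()
        open_digits[[u]] <- c(open_digits[[u]],
                              list(list(v = e[["v"]], b = e[["b"]], d = d)))
        close_digits[[e[["v"]]]] <- c(close_digits[[e[["v"]]]],
          list(list(v = u, b = e[["b"]], d = d)))
      }
    }
  }

  # --- stereo bond marks -----------------------------------------------------
  # bond id -> +1 ('/') / -1 ('\') in the bond's written direction
  written_from <- integer(n_bonds(g))  # atom the bond is written from
  for (v in order_seen) if (parent[v] > 0L) written_from[parent_bond[v]] <- parent[v]
  for (u in order_seen) for (e in open_digits[[u]]) written_from[e$b] <- u

  mark <- rep(NA_integer_, n_bonds(g))
  dir_of <- function(b, from, to) {
    # mark value converted to the direction from -> to
    if (written_from[b] == from) mark[b] else -mark[b]
  }
  set_dir <- function(b, from, to, val) {
    mark[b] <<- if (written_from[b] == from) val else -val
  }
  eligible_nbrs <- function(a, excl) {
    nb <- adj$nbr[[a]]; bb <- adj$bond[[a]]
    keep <- which(nb != excl & g$bond_order[bb] == 1L & !g$bond_aromatic[bb])
    keep <- keep[order(write_pos[nb[keep]])]
    list(nbr = nb[keep], bond = bb[keep])
  }
  for (cf in configs) {
    ea <- eligible_nbrs(cf$a, cf$b); eb <- eligible_nbrs(cf$b, cf$a)
    if (!length(ea$nbr) || !length(eb$nbr)) next
    pick <- function(e) {
      marked <- which(!is.na(mark[e$bond]))
      k <- if (length(marked)) marked[1] else 1L
      list(v = e$nbr[k], b = e$bond[k])
    }
    pa <- pick(ea); pb <- pick(eb)
    # is pa$v on the same side as cf$x? reference neighbors define the facts
    flip_a <- pa$v != cf$x
    flip_b <- pb$v != cf$y
    same <- cf$same_side
    if (flip_a) same <- !same
    if (flip_b) same <- !same
    p <- if (!is.na(mark[pa$b])) dir_of(pa$b, pa$v, cf$a) else {
      set_dir(pa$b, pa$v, cf$a, 1L); 1L
    }
    q <- if (same) -p else p
    if (is.na(mark[pb$b])) set_dir(pb$b, cf$b, pb$v, q)
  }

  # --- emission --------------------------------------------------------------
  bond_sym <- function(b, from, to) {
    if (g$bond_aromatic[b]) return("")
    o <- g$bond_order[b]
    if (o == 2L) return("=")
    if (o == 3L) return("#")
    if (!is.na(mark[b]))
      return(if (dir_of(b, from, to) > 0L) "/" else "\\")
    if (g$aromatic[from] && g$aromatic[to]) return("-")
    ""
  }

  emit <- function(u) {
    p <- parent[u]
    out <- if (p > 0L) bond_sym(parent_bond[u], p, u) else ""
    # output neighbor order for tetrahedral parity
    nbr_out <- integer()
    if (p > 0L) nbr_out <- p
    th <- total_h(g)[u]
    has_parity <- !is.na(g$parity[u])
    if (has_parity && th > 0L) nbr_out <- c(nbr_out, -1L)
    for (e in open_digits[[u]]) nbr_out <- c(nbr_out, e$v)
    for (e in close_digits[[u]]) nbr_out <- c(nbr_out, e$v)
    nbr_out <- c(nbr_out, children[[u]])
    out <- paste0(out, .atom_token(g, u, nbr_out))
    for (e in open_digits[[u]]) {
      out <- paste0(out, bond_sym(e$b, u, e$v), fmt_digit(e$d))
    }
    for (e in close_digits[[u]]) out <- paste0(out, fmt_digit(e$d))
    ch <- children[[u]]
    if (length(ch)) {
      for (k in seq_along(ch)) {
        body <- emit(ch[k])
        out <- paste0(out, if (k < length(ch)) paste0("(", body, ")") else body)
      }
    }
    out
  }
  emit(start)
}

# Atom token, bracketed only when necessary; aromatic atoms lowercase.
.atom_token <- function(g, a, nbr_out) {
  el <- g$element[a]
  arom <- g$aromatic[a]
  th <- total_h(g)[a]
  parity_out <- NA_character_
  if (!is.na(g$parity[a])) {
    parsed <- g$parity_order[[a]]
    if (length(parsed) == length(nbr_out) && setequal(parsed, nbr_out) &&
        !anyDuplicated(parsed) && !anyDuplicated(nbr_out)) {
      perm <- match(nbr_out, parsed)
      parity_out <- if (.perm_is_even(perm)) g$parity[a] else {
        if (g$parity[a] == "@") "@@" else "@"
      }
    } else {
      parity_out <- g$parity[a]  # degenerate bookkeeping; keep as stored
    }
  }

  sym <- if (arom) tolower(el) else el
  needs_bracket <- !is.na(g$isotope[a]) || g$charge[a] != 0L ||
    !is.na(parity_out) ||
    (arom && !(sym %in% .aromatic_organic)) ||
    (!arom && !(el %in% .organic_subset))
  if (!needs_bracket) {
    # would a bare token reparse to the same hydrogen count?
    implied <- if (arom) {
      if (el == "C") th else 0L   # bare aromatic heteroatoms imply 0 H
    } else {
      bs <- 0L
      for (b in seq_len(n_bonds(g))) {
        if (g$bond_i[b] == a || g$bond_j[b] == a) bs <- bs + g$bond_order[b]
      }
      allowed <- .valence_sets[[el]]
      if (bs > max(allowed)) -1L else min(allowed[allowed >= bs]) - bs
    }
    if (!identical(as.integer(implied), as.integer(th))) needs_bracket <- TRUE
  }
  if (!needs_bracket) return(sym)

  paste0("[",
         if (!is.na(g$isotope[a])) g$isotope[a] else "",
         sym,
         if (!is.na(parity_out)) parity_out else "",
         if (th == 1L) "H" else if (th > 1L) paste0("H", th) else "",
         .charge_token(g$charge[a]),
         "]")
}

.charge_token <- function(q) {
  if (q == 0L) return("")
  if (q == 1L) return("+")
  if (q == -1L) return("-")
  sprintf("%+d", q)
}

.perm_is_even <- function(perm) {
  inv <- 0L
  n <- length(perm)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      inv <- inv + sum(perm[(i + 1L):n] < perm[i])
    }
  }
  inv %% 2L == 0L
}

# Configuration facts for stereo double bonds: for each non-aromatic double
# bond with direction-marked single bonds on both sides, record reference
# neighbors x (of a) and y (of b) and whether they lie on the same side.
# For F/C=C/F (trans) the as-written marks give same_side = FALSE.
.stereo_double_configs <- function(g) {
  if (all(is.na(g$bond_dir))) return(list())
  adj <- mol_adjacency(g)
  out <- list()
  for (b in seq_len(n_bonds(g))) {
    if (g$bond_order[b] != 2L || g$bond_aromatic[b]) next
    a1 <- g$bond_i[b]; a2 <- g$bond_j[b]
    marked_nbr <- function(a, excl) {
      nb <- adj$nbr[[a]]; bb <- adj$bond[[a]]
      for (k in seq_along(nb)) {
        if (nb[k] != excl && !is.na(g$bond_dir[bb[k]]))
          return(list(v = nb[k], b = bb[k]))
      }
      NULL
    }
    ma <- marked_nbr(a1, a2); mb <- marked_nbr(a2, a1)
    if (is.null(ma) || is.null(mb)) next
    s <- function(bid, from, to) {
      val <- if (g$bond_dir[bid] == "/") 1L else -1L
      if (g$bond_i[bid] == from) val else -val
    }
    p <- s(ma$b, ma$v, a1)   # direction x -> a
    q <- s(mb$b, a2, mb$v)   # direction b -> y
    out[[length(out) + 1L]] <- list(a = a1, b = a2, x = ma$v, y = mb$v,
                                    same_side = (p != q))
  }
  out
}
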