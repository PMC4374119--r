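#' SMILES parse issues
#'
#' A classified SMILES malformation. `error_class` is one of
#' `PYRROLE_NITROGEN`, `UNCLOSED_RING`, `UNCLOSED_PARENTHESIS`,
#' `BARE_ATOM_NEEDS_BRACKETS`, `KEKULIZATION_FAILURE`, `BAD_TOKEN`,
#' `VALENCE_ERROR`. `position` is the 0-based character offset into the
#' SMILES string. `suggested_fix`, when present, is a corrected SMILES that
#' itself parses without error (guaranteed for `PYRROLE_NITROGEN`).
#'
#' @param error_class character, one of the classes above.
#' @param position integer 0-based offset.
#' @param message human-readable description.
#' @param suggested_fix optional corrected SMILES string.
#' @return a `parse_issue` object.
#' @export
parse_issue <- function(error_class, position, message, suggested_fix = NULL) {
  stopifnot(error_class %in% c(
    "PYRROLE_NITROGEN", "UNCLOSED_RING", "UNCLOSED_PARENTHESIS",
    "BARE_ATOM_NEEDS_BRACKETS", "KEKULIZATION_FAILURE", "BAD_TOKEN",
    "VALENCE_ERROR"))
  structure(
    list(error_class = error_class, position = as.integer(position),
         message = message, suggested_fix = suggested_fix),
    class = "parse_issue")
}

#' @rdname parse_issue
#' @param x object to test.
#' @export
is_parse_issue <- function(x) inherits(x, "parse_issue")

#' @export
print.parse_issue <- function(x, ...) {
  cat(sprintf("<parse_issue %s at %d: %s%s>\n", x$error_class, x$position,
              x$message,
              if (!is.null(x$suggested_fix))
                paste0(" [fix: ", x$suggested_fix, "]") else ""))
  invisible(x)
}

#' Parse a SMILES string into a molecular graph
#'
#' Parses the organic-subset SMILES dialect (B C N O P S F Cl Br I, aromatic
#' b c n o p s, bracket atoms with isotope / charge / H count / `@` / `@@`,
#' ring-closure digits and `%nn`, bond symbols `- = # : / \`, dots). On
#' success the result is kekulized (every aromatic bond has a resolved 1/2
#' order while keeping its aromatic flag), aromaticity is perceived on 5- and
#' 6-membered rings written in alternating kekule form, implicit hydrogens
#' are assigned and valences checked. On failure the single most specific
#' [parse_issue()] is returned, with precedence syntax > kekulization >
#' valence.
#'
#' @param smiles SMILES text (non-empty).
#' @return a `molgraph`, or a `parse_issue` on failure.
#' @examples
#' parse_smiles("c1ccccc1")
#' parse_smiles("C1CC")           # UNCLOSED_RING
#' parse_smiles("n2c1ccccc1nc2")  # PYRROLE_NITROGEN with suggested fix
#' @export
parse_smiles <- function(smiles) {
  .parse_smiles_impl(smiles, suggest = TRUE)
}

.parse_smiles_impl <- function(smiles, suggest = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("smiles must be a single character string")
  smiles <- trimws(smiles)
  if (!nzchar(smiles))
    return(parse_issue("BAD_TOKEN", 0L, "empty SMILES"))
  g <- .parse_syntax(smiles)
  if (is_parse_issue(g)) return(g)
  .finalize_graph(g, smiles, suggest = suggest)
}

# --- syntax pass ------------------------------------------------------------

# Builds the raw graph: atoms, bonds (aromatic bonds unresolved, order 0 when
# aromatic), ring closures, branches, stereo bookkeeping. Returns molgraph
# (pre-kekulization) or parse_issue.
.parse_syntax <- function(s) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]

  el <- character(); iso <- integer(); chg <- integer(); exh <- integer()
  arom <- logical(); brk <- logical(); par <- character()
  apos <- integer()
  events <- list()   # per-atom neighbor-order events for stereo

  bi <- integer(); bj <- integer(); bord <- integer(); barom <- logical()
  bdir <- character(); bdefault <- logical()

  prev <- NA_integer_
  stack <- integer()          # branch stack of prev atoms
  paren_pos <- integer()      # 0-based positions of open '('
  pending <- NULL             # list(order, aromatic, dir, pos)
  rings <- list()             # key -> list(atom, pending, pos)

  bad <- function(pos, msg) parse_issue("BAD_TOKEN", pos, msg)

  add_event <- function(a, type, val) {
    ev <- events[[a]]
    events[[a]] <<- c(ev, list(list(type = type, val = val)))
  }

  add_bond <- function(a, b, pend, pos0) {
    # reject parallel bonds
    if (any((bi == a & bj == b) | (bi == b & bj == a)))
      return(bad(pos0, "duplicate bond between the same atoms"))
    if (a == b) return(bad(pos0, "bond from an atom to itself"))
    if (is.null(pend)) {
      # default bond: aromatic if both atoms aromatic (ring membership is
      # confirmed in a later pass), else single
      bord <<- c(bord, 1L); barom <<- c(barom, arom[a] && arom[b])
      bdir <<- c(bdir, NA_character_); bdefault <<- c(bdefault, TRUE)
    } else {
      bord <<- c(bord, pend$order); barom <<- c(barom, pend$aromatic)
      bdir <<- c(bdir, pend$dir); bdefault <<- c(bdefault, FALSE)
    }
    bi <<- c(bi, a); bj <<- c(bj, b)
    NULL
  }

  new_atom <- function(element, aromatic, bracket, isotope = NA_integer_,
                       charge = 0L, expl_h = NA_integer_,
                       parity = NA_character_, pos0 = 0L) {
    el <<- c(el, element); arom <<- c(arom, aromatic); brk <<- c(brk, bracket)
    iso <<- c(iso, isotope); chg <<- c(chg, charge); exh <<- c(exh, expl_h)
    par <<- c(par, parity); apos <<- c(apos, pos0)
    a <- length(el)
    events[[a]] <<- list()
    if (!is.na(prev)) {
      err <- add_bond(prev, a, pending, pos0)
      if (!is.null(err)) return(err)
      add_event(prev, "a", a)
      add_event(a, "a", prev)
    }
    # the bracket implicit H of a chiral center occupies the slot right after
    # the preceding atom (or the first slot for a leading atom)
    if (!is.na(parity) && !is.na(expl_h) && expl_h > 0L) add_event(a, "h", -1L)
    pending <<- NULL
    prev <<- a
    NULL
  }

  close_or_open_ring <- function(key, pos0) {
    if (is.na(prev)) return(bad(pos0, "ring closure digit before any atom"))
    slot <- rings[[key]]
    if (is.null(slot)) {
      rings[[key]] <<- list(atom = prev, pending = pending, pos = pos0)
      add_event(prev, "r", key)
      pending <<- NULL
      return(NULL)
    }
    # closing
    a <- slot$atom; b <- prev
    pend <- pending
    if (!is.null(slot$pending) && !is.null(pend)) {
      if (!identical(slot$pending$order, pend$order) ||
          !identical(slot$pending$aromatic, pend$aromatic))
        return(bad(pos0, "conflicting bond symbols on ring closure"))
    } else if (!is.null(slot$pending)) {
      pend <- slot$pending
      # a direction mark recorded at the opening site is written from the
      # opening atom towards the closing atom
    }
    err <- add_bond(a, b, pend, pos0)
    if (!is.null(err)) return(err)
    # resolve the opener's placeholder event; record the closing atom's slot
    add_event(b, "a", a)
    ev <- events[[a]]
    for (k in seq_along(ev)) {
      if (ev[[k]]$type == "r" && identical(ev[[k]]$val, key)) {
        ev[[k]] <- list(type = "a", val = b)
        break
      }
    }
    events[[a]] <<- ev
    rings[[key]] <<- NULL
    pending <<- NULL
    NULL
  }

  i <- 1L
  while (i <= n) {
    c0 <- ch[i]; pos0 <- i - 1L
    nxt <- if (i < n) ch[i + 1L] else ""
    if (c0 == "C" && nxt == "l") {
      err <- new_atom("Cl", FALSE, FALSE, pos0 = pos0)
      if (!is.null(err)) return(err)
      i <- i + 2L
    } else if (c0 == "B" && nxt == "r") {
      err <- new_atom("Br", FALSE, FALSE, pos0 = pos0)
      if (!is.null(err)) return(err)
      i <- i + 2L
    } else if (c0 %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      err <- new_atom(c0, FALSE, FALSE, pos0 = pos0)
      if (!is.null(err)) return(err)
      i <- i + 1L
    } else if (c0 %in% .aromatic_organic) {
      err <- new_atom(toupper(c0), TRUE, FALSE, pos0 = pos0)
      if (!is.null(err)) return(err)
      i <- i + 1L
    } else if (c0 == "[") {
      close_idx <- NA_integer_
      j <- i + 1L
      while (j <= n) { if (ch[j] == "]") { close_idx <- j; break }; j <- j + 1L }
      if (is.na(close_idx))
        return(bad(pos0, "unterminated bracket atom"))
      content <- substr(s, i + 1L, close_idx - 1L)
      at <- .parse_bracket(content, pos0)
      if (is_parse_issue(at)) return(at)
      err <- new_atom(at$element, at$aromatic, TRUE, isotope = at$isotope,
                      charge = at$charge, expl_h = at$h, parity = at$parity,
                      pos0 = pos0)
      if (!is.null(err)) return(err)
      i <- close_idx + 1L
    } else if (c0 %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.null(pending)) return(bad(pos0, "two consecutive bond symbols"))
      if (is.na(prev)) return(bad(pos0, "bond symbol before any atom"))
      pending <- switch(c0,
        "-" = list(order = 1L, aromatic = FALSE, dir = NA_character_),
        "=" = list(order = 2L, aromatic = FALSE, dir = NA_character_),
        "#" = list(order = 3L, aromatic = FALSE, dir = NA_character_),
        ":" = list(order = 1L, aromatic = TRUE, dir = NA_character_),
        "/" = list(order = 1L, aromatic = FALSE, dir = "/"),
        "\\" = list(order = 1L, aromatic = FALSE, dir = "\\"))
      i <- i + 1L
    } else if (c0 >= "0" && c0 <= "9") {
      err <- close_or_open_ring(c0, pos0)
      if (!is.null(err)) return(err)
      i <- i + 1L
    } else if (c0 == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(s, i + 1L, i + 2L)))
        return(bad(pos0, "% must be followed by two digits"))
      err <- close_or_open_ring(substr(s, i + 1L, i + 2L), pos0)
      if (!is.null(err)) return(err)
      i <- i + 3L
    } else if (c0 == "(") {
      if (is.na(prev)) return(bad(pos0, "branch open before any atom"))
      if (!is.null(pending)) return(bad(pos0, "bond symbol before branch open"))
      stack <- c(stack, prev)
      paren_pos <- c(paren_pos, pos0)
      i <- i + 1L
    } else if (c0 == ")") {
      if (!length(stack))
        return(parse_issue("UNCLOSED_PARENTHESIS", pos0,
                           "closing parenthesis without a matching open"))
      if (!is.null(pending)) return(bad(pos0, "dangling bond at branch close"))
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      paren_pos <- paren_pos[-length(paren_pos)]
      i <- i + 1L
    } else if (c0 == ".") {
      if (!is.null(pending)) return(bad(pos0, "bond symbol before dot"))
      prev <- NA_integer_
      i <- i + 1L
    } else {
      # not part of the grammar: is it a recognizable element symbol that
      # should have been written in brackets?
      two <- paste0(c0, nxt)
      if (is_known_element(two) || two %in% c("se", "as"))
        return(parse_issue("BARE_ATOM_NEEDS_BRACKETS", pos0,
          sprintf("'%s' must be written in square brackets", two)))
      if (is_known_element(c0))
        return(parse_issue("BARE_ATOM_NEEDS_BRACKETS", pos0,
          sprintf("'%s' must be written in square brackets", c0)))
      return(bad(pos0, sprintf("unexpected character '%s'", c0)))
    }
  }

  if (!is.null(pending))
    return(bad(n - 1L, "dangling bond symbol at end of SMILES"))

  # end-of-input structural errors: report the earliest opening position
  end_issues <- list()
  if (length(rings)) {
    pmin <- min(vapply(rings, function(r) r$pos, integer(1)))
    end_issues <- c(end_issues, list(parse_issue("UNCLOSED_RING", pmin,
      "ring closure digit never closed")))
  }
  if (length(stack)) {
    end_issues <- c(end_issues, list(parse_issue("UNCLOSED_PARENTHESIS",
      paren_pos[1], "unclosed parenthesis")))
  }
  if (length(end_issues)) {
    pos <- vapply(end_issues, function(x) x$position, integer(1))
    return(end_issues[[which.min(pos)]])
  }
  if (!length(el)) return(bad(0L, "no atoms in SMILES"))

  g <- new_molgraph(element = el, isotope = iso, charge = chg,
                    explicit_h = exh, aromatic = arom, bracket = brk,
                    bond_i = bi, bond_j = bj, bond_order = bord,
                    bond_aromatic = barom)
  g$parity <- par
  g$bond_dir <- bdir
  g$bond_default <- bdefault
  g$atom_pos <- apos
  # resolve neighbor-order events to integer vectors (-1 = implicit H)
  g$parity_order <- lapply(events, function(ev) {
    vapply(ev, function(e) if (e$type == "h") -1L else as.integer(e$val),
           integer(1))
  })
  g
}

# Bracket atom body, e.g. "13CH4", "nH+", "C@@H", "O-", "Fe+3".
.parse_bracket <- function(content, pos0) {
  m <- regexec(
    "^([0-9]+)?(se|as|[A-Z][a-z]?|[bcnops])(@@|@)?(H[0-9]*)?([+-][0-9]+|[+]+|[-]+)?(:[0-9]+)?$",
    content)
  parts <- regmatches(content, m)[[1]]
  if (!length(parts))
    return(parse_issue("BAD_TOKEN", pos0,
                       sprintf("malformed bracket atom '[%s]'", content)))
  isotope <- if (nzchar(parts[2])) as.integer(parts[2]) else NA_integer_
  sym <- parts[3]
  aromatic <- sym %in% c(.aromatic_organic, "se", "as")
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  if (!is_known_element(element))
    return(parse_issue("BAD_TOKEN", pos0,
                       sprintf("unknown element '%s'", sym)))
  if (aromatic && !(element %in% .aromatic_elements))
    return(parse_issue("BAD_TOKEN", pos0,
                       sprintf("'%s' cannot be aromatic", sym)))
  parity <- if (nzchar(parts[4])) parts[4] else NA_character_
  h <- if (nzchar(parts[5])) {
    if (parts[5] == "H") 1L else as.integer(substring(parts[5], 2))
  } else 0L
  charge <- 0L
  cg <- parts[6]
  if (nzchar(cg)) {
    charge <- if (grepl("^[+-][0-9]+$", cg)) {
      as.integer(cg)
    } else {
      sgn <- if (substr(cg, 1, 1) == "+") 1L else -1L
      sgn * nchar(cg)
    }
  }
  list(element = element, aromatic = aromatic, isotope = isotope,
       charge = charge, h = h, parity = parity)
}

# --- semantic pass ----------------------------------------------------------

.finalize_graph <- function(g, smiles, suggest = TRUE) {
  # default bonds between two aromatic atoms are aromatic only on rings
  # (e.g. the biphenyl inter-ring bond stays single)
  if (any(g$bond_aromatic)) {
    rb <- ring_bonds(g)
    demote <- g$bond_aromatic & g$bond_default & !rb
    g$bond_aromatic[demote] <- FALSE
  }
  g$bond_default <- NULL

  kk <- kekulize(g)
  if (is_parse_issue(kk)) {
    if (suggest && kk$error_class == "KEKULIZATION_FAILURE") {
      fix <- suggest_pyrrole_fix(smiles)
      if (!is.null(fix)) {
        npos <- .bare_aromatic_n_positions(smiles)
        return(parse_issue("PYRROLE_NITROGEN",
                           if (length(npos)) npos[1] else kk$position,
                           "pyrrole-type nitrogen written as bare 'n'; must be [nH]",
                           suggested_fix = fix))
      }
    }
    return(kk)
  }
  g <- kk

  hv <- .assign_hydrogens(g)
  if (is_parse_issue(hv)) return(hv)
  g <- hv

  # perceive aromatic rings written in kekule form, then re-kekulize the
  # whole aromatic system so both surface forms share one internal state
  pg <- .perceive_aromatic(g)
  if (pg$changed) {
    g <- pg$graph
    g$bond_order[g$bond_aromatic] <- 1L
    kk <- kekulize(g, use_total_h = TRUE)
    if (is_parse_issue(kk)) return(kk)
    g <- kk
    hv <- .assign_hydrogens(g)
    if (is_parse_issue(hv)) return(hv)
    g <- hv
  }

  comp <- mol_components(g)
  g$n_fragments <- max(comp)
  g$multi_fragment <- g$n_fragments > 1L
  g
}

# Implicit hydrogens for bare atoms from the allowed valence sets; bracket
# atoms are exempt (their explicit H specification wins).
.assign_hydrogens <- function(g) {
  n <- n_atoms(g)
  bondsum <- rep(0L, n)
  for (b in seq_len(n_bonds(g))) {
    o <- g$bond_order[b]
    bondsum[g$bond_i[b]] <- bondsum[g$bond_i[b]] + o
    bondsum[g$bond_j[b]] <- bondsum[g$bond_j[b]] + o
  }
  g$implicit_h <- rep(0L, n)
  for (a in seq_len(n)) {
    if (g$bracket[a]) next
    allowed <- .valence_sets[[g$element[a]]]
    if (is.null(allowed)) next
    if (bondsum[a] > max(allowed)) {
      return(parse_issue("VALENCE_ERROR", g$atom_pos[a],
        sprintf("atom %s has bond order sum %d exceeding max valence %d",
                g$element[a], bondsum[a], max(allowed))))
    }
    g$implicit_h[a] <- min(allowed[allowed >= bondsum[a]]) - bondsum[a]
  }
  g
}

# 0-based positions of bare aromatic 'n' tokens (outside brackets).
.bare_aromatic_n_positions <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  out <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "[") depth <- depth + 1L
    else if (ch[i] == "]") depth <- depth - 1L
    else if (depth == 0L && ch[i] == "n") out <- c(out, i - 1L)
  }
  out
}

#' Suggest a pyrrole-nitrogen repair for an unkekulizable SMILES
#'
#' Tries replacing each bare aromatic `n` token (then each minimal subset,
#' smallest subsets first, leftmost-first tie-break) by `[nH]` and returns
#' the first candidate that parses cleanly. Returns `NULL` when the input
#' already parses, when its failure is not kekulization-related, or when no
#' replacement helps.
#'
#' @param smiles SMILES text that fails kekulization.
#' @return corrected SMILES string, or `NULL`.
#' @examples
#' suggest_pyrrole_fix("n2c1ccccc1nc2")  # "[nH]2c1ccccc1nc2"
#' @export
suggest_pyrrole_fix <- function(smiles) {
  base <- .parse_smiles_impl(smiles, suggest = FALSE)
  if (!is_parse_issue(base)) return(NULL)
  if (base$error_class != "KEKULIZATION_FAILURE") return(NULL)
  npos <- .bare_aromatic_n_positions(smiles)
  if (!length(npos)) return(NULL)
  k <- length(npos)
  max_size <- min(k, 4L)  # bound the combinatorics
  for (size in seq_len(max_size)) {
    subsets <- utils::combn(npos, size, simplify = FALSE)
    # combn over an ascending vector already yields lexicographic order
    for (sub in subsets) {
      cand <- smiles
      for (p in rev(sort(sub))) {  # right-to-left keeps earlier offsets valid
        cand <- paste0(substr(cand, 1L, p), "[nH]",
                       substring(cand, p + 2L))
      }
      res <- .parse_smiles_impl(cand, suggest = FALSE)
      if (!is_parse_issue(res)) return(cand)
    }
  }
  NULL
}
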