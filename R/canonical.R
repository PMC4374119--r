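#' Canonical atom ranks
#'
#' Morgan-style iterative refinement. The initial invariant combines element,
#' charge, isotope, degree, total hydrogen count, aromatic flag and
#' smallest-ring membership; refinement then folds in the sorted multiset of
#' (bond type, neighbor rank) pairs until stable. Remaining ties are broken
#' deterministically by doubling all ranks and promoting the lowest-index
#' atom of the first tied class, re-refining after each promotion.
#'
#' @param g a parsed, kekulized `molgraph`.
#' @return integer vector: a permutation of `0:(n-1)` (rank 0 = first atom
#'   of the canonical output).
#' @export
canonical_ranks <- function(g) {
  stopifnot(is_molgraph(g))
  n <- n_atoms(g)
  if (n == 0L) return(integer())
  adj <- mol_adjacency(g)
  bond_code <- ifelse(g$bond_aromatic, "a", as.character(g$bond_order))
  th <- total_h(g)
  srs <- smallest_ring_size(g)

  dense <- function(keys) match(keys, sort(unique(keys), method = "radix"))

  refine <- function(r) {
    repeat {
      keys <- vapply(seq_len(n), function(a) {
        nb <- adj$nbr[[a]]; bb <- adj$bond[[a]]
        nbk <- sort(paste0(bond_code[bb], ":", sprintf("%06d", r[nb])),
                    method = "radix")
        paste0(sprintf("%06d", r[a]), "|", paste0(nbk, collapse = ","))
      }, character(1))
      r2 <- dense(keys)
      if (identical(r2, r) || length(unique(r2)) == length(unique(r))) {
        return(r2)
      }
      r <- r2
    }
  }

  init <- vapply(seq_len(n), function(a) {
    paste(g$element[a], g$charge[a],
          if (is.na(g$isotope[a])) 0L else g$isotope[a],
          length(adj$nbr[[a]]), th[a], as.integer(g$aromatic[a]), srs[a],
          sep = "/")
  }, character(1))
  r <- refine(dense(init))

  while (anyDuplicated(r)) {
    r <- r * 2L
    tied_vals <- sort(unique(r[duplicated(r) | duplicated(r, fromLast = TRUE)]))
    v <- tied_vals[1]
    a <- which(r == v)[1]
    r[a] <- r[a] - 1L
    r <- refine(dense(r))
  }
  match(r, sort(unique(r))) - 1L
}

#' Canonical SMILES
#'
#' Writes the molecule depth-first from the lowest-rank atom, visiting
#' neighbors in ascending canonical rank, with ring-closure digits assigned
#' in order of first encounter. Aromatic systems are written in lowercase;
#' tetrahedral parity is re-expressed relative to the canonical neighbor
#' order via permutation parity, and double-bond cis/trans relative to the
#' canonically chosen reference neighbors.
#'
#' @param g a parsed `molgraph` (or SMILES text, parsed on the fly).
#' @return a `canonical_form` object with fields `canonical_smiles`,
#'   `stereo_stripped_smiles` and `has_stereo`.
#' @examples
#' canonical_smiles("OCC")$canonical_smiles ==
#'   canonical_smiles("CCO")$canonical_smiles  # TRUE
#' @export
canonical_smiles <- function(g) {
  g <- .as_molgraph(g)
  ranks <- canonical_ranks(g)
  smi <- write_smiles(g, priority = ranks)
  has_stereo <- any(!is.na(g$parity)) ||
    length(.stereo_double_configs(g)) > 0L
  stripped <- if (has_stereo) {
    gs <- g
    gs$parity <- rep(NA_character_, n_atoms(g))
    gs$bond_dir <- rep(NA_character_, n_bonds(g))
    write_smiles(gs, priority = ranks)
  } else smi
  structure(list(canonical_smiles = smi,
                 stereo_stripped_smiles = stripped,
                 has_stereo = has_stereo),
            class = "canonical_form")
}

#' @export
print.canonical_form <- function(x, ...) {
  cat(sprintf("<canonical %s%s>\n", x$canonical_smiles,
              if (x$has_stereo) paste0(" (skeleton ",
                                       x$stereo_stripped_smiles, ")") else ""))
  invisible(x)
}

#' Do two inputs encode exactly the same structure?
#'
#' Stereo-aware: enantiomers compare as different. Use the
#' `stereo_stripped_smiles` field of [canonical_smiles()] for
#' skeleton-level comparison.
#'
#' @param a,b parsed `molgraph` objects or SMILES text.
#' @return logical.
#' @examples
#' same_structure("CCO", "OCC")  # TRUE
#' same_structure("CCO", "COC")  # FALSE
#' @export
same_structure <- function(a, b) {
  ca <- canonical_smiles(.as_molgraph(a))
  cb <- canonical_smiles(.as_molgraph(b))
  identical(ca$canonical_smiles, cb$canonical_smiles)
}

# Accept molgraph or SMILES text; error (with the issue attached) on
# unparseable text.
.as_molgraph <- function(x) {
  if (is_molgraph(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    g <- parse_smiles(x)
    if (is_parse_issue(g)) {
      stop(sprintf("SMILES '%s' does not parse: %s at %d (%s)",
                   x, g$error_class, g$position, g$message), call. = FALSE)
    }
    return(g)
  }
  stop("expected a molgraph or a single SMILES string")
}
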