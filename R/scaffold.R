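#' Murcko-style scaffold of a molecule
#'
#' The molecular framework: ring systems plus the linkers connecting them,
#' side chains removed. Terminal atoms are pruned iteratively; atoms
#' double- or triple-bonded to a framework atom (exocyclic carbonyls and
#' friends) are retained, matching common Murcko practice. Stereo
#' descriptors are dropped (frameworks are counted achiral). Acyclic
#' molecules have no scaffold.
#'
#' @param mol a parsed `molgraph` or SMILES text.
#' @return a `molgraph`, or `NULL` for acyclic molecules.
#' @examples
#' molecular_formula(murcko_scaffold("Cc1ccccc1"))  # benzene, "C6H6"
#' murcko_scaffold("CCO")                           # NULL
#' @export
murcko_scaffold <- function(mol) {
  g <- .as_molgraph(mol)
  rb <- ring_bonds(g)
  if (!any(rb)) return(NULL)

  # prune terminal atoms until only rings + linkers remain
  keep <- rep(TRUE, n_atoms(g))
  repeat {
    deg <- integer(n_atoms(g))
    for (b in seq_len(n_bonds(g))) {
      if (keep[g$bond_i[b]] && keep[g$bond_j[b]]) {
        deg[g$bond_i[b]] <- deg[g$bond_i[b]] + 1L
        deg[g$bond_j[b]] <- deg[g$bond_j[b]] + 1L
      }
    }
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # re-attach exocyclic multiply-bonded atoms
  repeat {
    added <- FALSE
    for (b in seq_len(n_bonds(g))) {
      if (g$bond_order[b] < 2L || g$bond_aromatic[b]) next
      i <- g$bond_i[b]; j <- g$bond_j[b]
      if (keep[i] && !keep[j]) { keep[j] <- TRUE; added <- TRUE }
      else if (keep[j] && !keep[i]) { keep[i] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }

  sub <- induced_subgraph(g, which(keep))
  sub$parity <- rep(NA_character_, n_atoms(sub))
  sub$bond_dir <- rep(NA_character_, n_bonds(sub))
  sub$atom_pos <- rep(0L, n_atoms(sub))
  # hydrogens change where substituents were removed
  sub <- .assign_hydrogens(sub)
  if (is_parse_issue(sub)) stop("internal: scaffold hydrogen assignment failed")
  comp <- mol_components(sub)
  sub$n_fragments <- max(comp)
  sub$multi_fragment <- sub$n_fragments > 1L
  sub
}

#' Scaffold frequency report
#'
#' Counts index records per canonical scaffold (a record with no scaffold —
#' an acyclic molecule — contributes to none), sorted by descending count
#' with ties broken by scaffold string. `covered` is the number of records
#' whose scaffold made the top-n list; stereo-distinct entries count
#' separately since the report counts database entries.
#'
#' @param index a `chem_index`.
#' @param n number of scaffolds to report.
#' @return a `scaffold_report`: list(rows = data.frame(scaffold_smiles,
#'   count), covered, with_scaffold).
#' @export
top_scaffolds <- function(index, n = 250L) {
  stopifnot(n >= 1L)
  scafs <- character(0)
  for (g in index$graphs) {
    s <- murcko_scaffold(g)
    if (is.null(s)) next
    scafs <- c(scafs, canonical_smiles(s)$canonical_smiles)
  }
  if (!length(scafs)) {
    return(structure(list(
      rows = data.frame(scaffold_smiles = character(), count = integer(),
                        stringsAsFactors = FALSE),
      covered = 0L, with_scaffold = 0L), class = "scaffold_report"))
  }
  tab <- table(scafs)
  df <- data.frame(scaffold_smiles = names(tab),
                   count = as.integer(tab), stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$scaffold_smiles, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  top <- utils::head(df, n)
  structure(list(rows = top, covered = sum(top$count),
                 with_scaffold = length(scafs)),
            class = "scaffold_report")
}

#' @export
print.scaffold_report <- function(x, ...) {
  cat(sprintf("<scaffold_report: %d scaffolds, %d records covered>\n",
              nrow(x$rows), x$covered))
  if (nrow(x$rows)) print(utils::head(x$rows, 10L))
  invisible(x)
}
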