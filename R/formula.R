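#' Molecular formula in Hill order
#'
#' Carbon first, hydrogen second, then all other elements alphabetically
#' (all alphabetically including H when there is no carbon). Implicit and
#' explicit hydrogens are both counted.
#'
#' @param g a parsed `molgraph`.
#' @return formula text, e.g. `"C2H6O"`.
#' @examples
#' molecular_formula(parse_smiles("CCO"))  # "C2H6O"
#' @export
molecular_formula <- function(g) {
  stopifnot(is_molgraph(g))
  counts <- table(g$element)
  nh <- sum(total_h(g)) + if ("H" %in% names(counts)) counts[["H"]] else 0L
  counts <- counts[names(counts) != "H"]
  syms <- names(counts)
  out <- character()
  fmt <- function(sym, k) if (k == 1L) sym else paste0(sym, k)
  if ("C" %in% syms) {
    out <- c(out, fmt("C", counts[["C"]]))
    if (nh > 0L) out <- c(out, fmt("H", nh))
    rest <- sort(setdiff(syms, "C"))
    for (s in rest) out <- c(out, fmt(s, counts[[s]]))
  } else {
    withH <- c(as.list(counts), if (nh > 0L) list(H = nh))
    names_all <- sort(names(withH))
    for (s in names_all) out <- c(out, fmt(s, withH[[s]]))
  }
  paste0(out, collapse = "")
}

#' Molecular weight in Daltons
#'
#' Sum of standard atomic weights over all atoms including hydrogens.
#' When an isotope mass number is specified it is used in place of the
#' standard weight. Reported to two decimals.
#'
#' @param g a parsed `molgraph`.
#' @return numeric mass in Daltons, rounded to 2 decimals.
#' @examples
#' molecular_weight(parse_smiles("c1ccccc1"))  # 78.11
#' @export
molecular_weight <- function(g) {
  stopifnot(is_molgraph(g))
  w <- ifelse(is.na(g$isotope), element_weight(g$element), g$isotope)
  round(sum(w) + sum(total_h(g)) * .element_weights[["H"]], 2)
}
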