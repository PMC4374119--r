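#' Substructure matching options
#'
#' `aromatic_strict` requires aromatic query bonds/atoms to match only
#' aromatic target bonds/atoms (the default keeps fingerprint screening
#' sound); turning it off lets kekule-drawn queries hit aromatic targets.
#' `charge_strict` requires formal charges to be equal.
#'
#' @param aromatic_strict logical, default `TRUE`.
#' @param charge_strict logical, default `TRUE`.
#' @return a `match_options` object.
#' @export
match_options <- function(aromatic_strict = TRUE, charge_strict = TRUE) {
  structure(list(aromatic_strict = isTRUE(aromatic_strict),
                 charge_strict = isTRUE(charge_strict)),
            class = "match_options")
}

# Flat integer representation consumed by the C++ matcher. Query-side
# hydrogen constraints: bracket atoms impose their explicit H count as a
# minimum; bare atoms impose none.
as_cgraph <- function(g, as_query = FALSE) {
  stopifnot(is_molgraph(g))
  minh <- rep(-1L, n_atoms(g))
  if (as_query) {
    eh <- g$explicit_h
    minh[g$bracket & !is.na(eh)] <- eh[g$bracket & !is.na(eh)]
  }
  list(el = match(g$element, .element_symbols),
       arom = as.integer(g$aromatic),
       charge = g$charge,
       minh = minh,
       toth = as.integer(total_h(g)),
       bi = g$bond_i - 1L,
       bj = g$bond_j - 1L,
       bord = g$bond_order,
       barom = as.integer(g$bond_aromatic))
}

#' Is the query a substructure of the target?
#'
#' True iff an injective mapping of query atoms to target atoms exists
#' preserving element, aromatic flag and charge (per `opts`) and bond
#' compatibility (single/double/triple exact, aromatic matches aromatic).
#'
#' @param query,target parsed `molgraph` objects or SMILES text.
#' @param opts a [match_options()] object.
#' @return logical.
#' @examples
#' is_substructure("c1ccccc1", "c1ccc2ccccc2c1")  # TRUE
#' is_substructure("N", "CCO")                    # FALSE
#' @export
is_substructure <- function(query, target, opts = match_options()) {
  query <- .as_molgraph(query); target <- .as_molgraph(target)
  cpp_is_substructure(as_cgraph(query, as_query = TRUE), as_cgraph(target),
                      opts$aromatic_strict, opts$charge_strict)
}

#' Number of distinct substructure images
#'
#' Counts distinct target atom subsets admitting a match (symmetry-equivalent
#' mappings onto the same atom set count once).
#'
#' @inheritParams is_substructure
#' @param cap stop counting after this many images (protection for
#'   pathological queries).
#' @return non-negative integer.
#' @examples
#' count_matches("O", "OCCO")  # 2
#' @export
count_matches <- function(query, target, opts = match_options(),
                          cap = .Machine$integer.max) {
  query <- .as_molgraph(query); target <- .as_molgraph(target)
  cpp_count_matches(as_cgraph(query, as_query = TRUE), as_cgraph(target),
                    opts$aromatic_strict, opts$charge_strict, as.integer(cap))
}
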