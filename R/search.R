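#' Build a fingerprint-indexed structure database
#'
#' One index record per parseable entry: the stereo-aware canonical SMILES,
#' the 512 descriptor bits packed as 16 unsigned 32-bit words, the Hill
#' formula, the molecular weight (2 decimals) and the source page title.
#' Unparseable entries are routed to the attached error report, never
#' silently dropped. Duplicate (page, canonical structure) pairs collapse to
#' one record. Multi-fragment SMILES are indexed by their largest component.
#'
#' @param entries data.frame with columns `smiles` and `page` (page titles
#'   must not contain tabs or newlines), or a list of such pairs.
#' @param dict a [fragment_dictionary()].
#' @param built_at optional header timestamp (defaults to the current time;
#'   pass a fixed string for byte-reproducible output).
#' @return a `chem_index` object with fields `header`, `records` (data.frame
#'   `structure`, `mf`, `mw`, `page`), `words` (n x 16 matrix), plus
#'   in-memory `bits`, `graphs` and the `errors` report.
#' @export
build_index <- function(entries, dict = default_fragment_dictionary(),
                        built_at = NULL) {
  if (is.list(entries) && !is.data.frame(entries)) {
    entries <- data.frame(
      smiles = vapply(entries, function(e) e$smiles, character(1)),
      page = vapply(entries, function(e) e$page, character(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("smiles", "page") %in% names(entries)))
  if (any(grepl("[\t\n]", entries$page))) {
    stop("page titles must not contain tabs or newlines")
  }
  if (is.null(built_at)) built_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC")

  recs <- list(); errs <- list()
  seen <- character()
  for (r in seq_len(nrow(entries))) {
    smi <- entries$smiles[r]; page <- entries$page[r]
    g <- parse_smiles(smi)
    if (is_parse_issue(g)) {
      errs[[length(errs) + 1L]] <- data.frame(
        page = page, smiles_raw = smi, error_class = g$error_class,
        position = g$position,
        suggested_fix = if (is.null(g$suggested_fix)) "" else g$suggested_fix,
        stringsAsFactors = FALSE)
      next
    }
    if (g$multi_fragment) g <- largest_component(g)
    can <- canonical_smiles(g)$canonical_smiles
    key <- paste0(page, "\r", can)
    if (key %in% seen) next
    seen <- c(seen, key)
    d <- compute_descriptor(g, dict)
    recs[[length(recs) + 1L]] <- list(
      structure = can, bits = d$bits, mf = molecular_formula(g),
      mw = molecular_weight(g), page = page, graph = g)
  }

  n <- length(recs)
  bits <- if (n) do.call(rbind, lapply(recs, `[[`, "bits")) else
    matrix(integer(), 0L, length(dict$min_count))
  words <- if (n) t(apply(bits, 1L, descriptor_words)) else
    matrix(numeric(), 0L, length(dict$min_count) %/% 32L)
  idx <- structure(list(
    header = list(dictionary_version = dict$version, built_at = built_at,
                  count = n),
    records = data.frame(
      structure = vapply(recs, `[[`, character(1), "structure"),
      mf = vapply(recs, `[[`, character(1), "mf"),
      mw = vapply(recs, `[[`, numeric(1), "mw"),
      page = vapply(recs, `[[`, character(1), "page"),
      stringsAsFactors = FALSE),
    words = words,
    bits = bits,
    graphs = lapply(recs, `[[`, "graph"),
    errors = if (length(errs)) do.call(rbind, errs) else
      data.frame(page = character(), smiles_raw = character(),
                 error_class = character(), position = integer(),
                 suggested_fix = character(), stringsAsFactors = FALSE)
  ), class = "chem_index")
  idx
}

#' @export
print.chem_index <- function(x, ...) {
  cat(sprintf("<chem_index: %d records, dictionary %s, built %s; %d errors>\n",
              x$header$count, x$header$dictionary_version, x$header$built_at,
              nrow(x$errors)))
  invisible(x)
}

#' Write / read the index JSON file
#'
#' The on-disk format is a JSON object with a `header`
#' (`dictionary_version`, `built_at`, `count`) and a `records` array; each
#' record carries `structure`, `words` (16 decimal integers), `mf`, `mw` and
#' `page`. Bits and parsed graphs are reconstructed on read.
#'
#' @param index a `chem_index`.
#' @param path file path.
#' @return `read_index()` returns a `chem_index` (without the error report,
#'   which is not part of the index file).
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "chem_index"))
  n <- nrow(index$records)
  records <- lapply(seq_len(n), function(r) {
    list(structure = jsonlite::unbox(index$records$structure[r]),
         words = index$words[r, ],
         mf = jsonlite::unbox(index$records$mf[r]),
         mw = jsonlite::unbox(index$records$mw[r]),
         page = jsonlite::unbox(index$records$page[r]))
  })
  obj <- list(header = lapply(index$header, jsonlite::unbox),
              records = records)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE), path)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  n <- length(obj$records)
  words <- if (n) {
    do.call(rbind, lapply(obj$records, function(r) as.numeric(unlist(r$words))))
  } else matrix(numeric(), 0L, 16L)
  bits <- if (n) t(apply(words, 1L, words_to_bits)) else
    matrix(integer(), 0L, 512L)
  graphs <- lapply(obj$records, function(r) parse_smiles(r$structure))
  structure(list(
    header = list(dictionary_version = obj$header$dictionary_version,
                  built_at = obj$header$built_at,
                  count = as.integer(obj$header$count)),
    records = data.frame(
      structure = vapply(obj$records, function(r) r$structure, character(1)),
      mf = vapply(obj$records, function(r) r$mf, character(1)),
      mw = vapply(obj$records, function(r) as.numeric(r$mw), numeric(1)),
      page = vapply(obj$records, function(r) r$page, character(1)),
      stringsAsFactors = FALSE),
    words = words, bits = bits, graphs = graphs,
    errors = data.frame(page = character(), smiles_raw = character(),
                        error_class = character(), position = integer(),
                        suggested_fix = character(), stringsAsFactors = FALSE)
  ), class = "chem_index")
}

.record_descriptor <- function(index, r) {
  structure(list(bits = as.integer(index$bits[r, ]),
                 version = index$header$dictionary_version),
            class = "descriptor")
}

.empty_result <- function(mode) {
  structure(list(hits = data.frame(
    structure = character(), page = character(), mf = character(),
    mw = numeric(), score = numeric(), mw_delta = numeric(),
    stringsAsFactors = FALSE), mode = mode), class = "search_result")
}

.make_result <- function(index, rows, mode, score = NULL, mw_delta = NULL) {
  hits <- index$records[rows, , drop = FALSE]
  hits$score <- if (is.null(score)) NA_real_ else score
  hits$mw_delta <- if (is.null(mw_delta)) NA_real_ else mw_delta
  rownames(hits) <- NULL
  structure(list(hits = hits, mode = mode), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result %s: %d hits>\n", x$mode, nrow(x$hits)))
  if (nrow(x$hits)) print(utils::head(x$hits, 10L))
  invisible(x)
}

#' Two-step substructure search
#'
#' Step 1 keeps records whose descriptors contain at least all query bits
#' ([screen_pass()]); step 2 confirms them by subgraph isomorphism
#' ([is_substructure()]). Hits are sorted by ascending absolute molecular
#' weight difference from the query, ties broken with the exact structural
#' match first, then by page title, so the query structure itself is always
#' the first hit.
#'
#' @param query a parsed `molgraph` or SMILES text.
#' @param index a `chem_index` built with the same dictionary.
#' @param dict the [fragment_dictionary()] of the index.
#' @param opts a [match_options()] object for the confirmation step.
#' @return a `search_result`; `attr(, "screened")` records how many
#'   candidates survived the fingerprint screen.
#' @export
search_substructure <- function(query, index,
                                dict = default_fragment_dictionary(),
                                opts = match_options()) {
  query <- .as_molgraph(query)
  if (query$multi_fragment) query <- largest_component(query)
  if (!identical(dict$version, index$header$dictionary_version)) {
    stop("index was built with a different dictionary version")
  }
  n <- nrow(index$records)
  if (n == 0L) return(.empty_result("substructure"))
  qd <- compute_descriptor(query, dict)
  qbits <- which(qd$bits == 1L)
  pass <- if (length(qbits)) {
    rowSums(index$bits[, qbits, drop = FALSE]) == length(qbits)
  } else rep(TRUE, n)
  cand <- which(pass)
  qc <- as_cgraph(query, as_query = TRUE)
  confirmed <- cand[vapply(cand, function(r) {
    cpp_is_substructure(qc, as_cgraph(index$graphs[[r]]),
                        opts$aromatic_strict, opts$charge_strict)
  }, logical(1))]
  if (!length(confirmed)) {
    out <- .empty_result("substructure")
    attr(out, "screened") <- length(cand)
    return(out)
  }
  qmw <- molecular_weight(query)
  qcan <- canonical_smiles(query)$canonical_smiles
  mwd <- abs(index$records$mw[confirmed] - qmw)
  exact <- index$records$structure[confirmed] == qcan
  ord <- order(mwd, !exact,
               index$records$page[confirmed], method = "radix")
  out <- .make_result(index, confirmed[ord], "substructure",
                      mw_delta = mwd[ord])
  attr(out, "screened") <- length(cand)
  out
}

#' Tanimoto similarity search
#'
#' Scores every record by Tanimoto similarity of the fragment descriptors,
#' sorts by descending score with ties broken by ascending absolute
#' molecular-weight difference (then page title), and forces any record with
#' the query's exact structure to the top of the list.
#'
#' @inheritParams search_substructure
#' @param top optional limit on the number of hits returned (default: all).
#' @return a `search_result` with a `score` column.
#' @export
search_similarity <- function(query, index,
                              dict = default_fragment_dictionary(),
                              top = NULL) {
  query <- .as_molgraph(query)
  if (query$multi_fragment) query <- largest_component(query)
  if (!identical(dict$version, index$header$dictionary_version)) {
    stop("index was built with a different dictionary version")
  }
  n <- nrow(index$records)
  if (n == 0L) return(.empty_result("similarity"))
  qd <- compute_descriptor(query, dict)
  qb <- qd$bits
  both <- as.numeric(index$bits %*% qb)
  either <- rowSums(index$bits) + sum(qb) - both
  score <- ifelse(either == 0, 1.0, both / either)
  qmw <- molecular_weight(query)
  qcan <- canonical_smiles(query)$canonical_smiles
  mwd <- abs(index$records$mw - qmw)
  exact <- index$records$structure == qcan
  ord <- order(!exact, -score, mwd, index$records$page,
               method = "radix")
  if (!is.null(top)) ord <- utils::head(ord, top)
  .make_result(index, ord, "similarity", score = score[ord],
               mw_delta = mwd[ord])
}

#' Exact (equivalence) search
#'
#' The query is canonicalized (stereo-aware) and compared to the canonical
#' structure strings of the index; all matching records are returned (a
#' structure shared by several pages yields several hits).
#'
#' @inheritParams search_substructure
#' @return a `search_result`.
#' @export
search_exact <- function(query, index) {
  query <- .as_molgraph(query)
  if (query$multi_fragment) query <- largest_component(query)
  qcan <- canonical_smiles(query)$canonical_smiles
  rows <- which(index$records$structure == qcan)
  rows <- rows[order(index$records$page[rows], method = "radix")]
  if (!length(rows)) return(.empty_result("exact"))
  .make_result(index, rows, "exact",
               mw_delta = rep(0, length(rows)))
}

#' Filter search hits by page-title substring
#'
#' Case-insensitive substring filter on the page title, applied after
#' ranking (mirrors the interactive name filter of structure explorers).
#'
#' @param result a `search_result`.
#' @param text substring to require.
#' @return the filtered `search_result`.
#' @export
filter_results <- function(result, text) {
  stopifnot(inherits(result, "search_result"))
  keep <- grepl(text, result$hits$page, ignore.case = TRUE, fixed = FALSE)
  result$hits <- result$hits[keep, , drop = FALSE]
  rownames(result$hits) <- NULL
  result
}
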