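#' Wiki pages
#'
#' A raw wiki-markup page: title plus wikitext.
#'
#' @param title page title (non-empty).
#' @param wikitext raw wiki markup.
#' @return a `wiki_page` object.
#' @export
wiki_page <- function(title, wikitext) {
  stopifnot(is.character(title), nzchar(title))
  structure(list(title = title, wikitext = wikitext), class = "wiki_page")
}

#' @export
print.wiki_page <- function(x, ...) {
  cat(sprintf("<wiki_page '%s': %d chars>\n", x$title, nchar(x$wikitext)))
  invisible(x)
}

# Locate {{...}} templates in wikitext with balanced-brace scanning.
# Returns list of list(name, body, start); on unbalanced braces sets
# attr "malformed" = TRUE and returns what was parseable.
.find_templates <- function(text) {
  out <- list()
  malformed <- FALSE
  n <- nchar(text)
  i <- 1L
  while (i < n) {
    if (substr(text, i, i + 1L) == "{{") {
      depth <- 1L
      j <- i + 2L
      while (j < n && depth > 0L) {
        tok <- substr(text, j, j + 1L)
        if (tok == "{{") { depth <- depth + 1L; j <- j + 2L }
        else if (tok == "}}") { depth <- depth - 1L; j <- j + 2L }
        else j <- j + 1L
      }
      if (depth > 0L) { malformed <- TRUE; break }
      body <- substr(text, i + 2L, j - 3L)
      name <- trimws(sub("^([^|]*).*$", "\\1", body))
      out[[length(out) + 1L]] <- list(name = name, body = body, start = i)
      i <- j
    } else i <- i + 1L
  }
  attr(out, "malformed") <- malformed
  out
}

# Split a template body on top-level pipes (nested {{ }} and [[ ]] stay
# intact); returns the parameter strings after the template name.
.split_params <- function(body) {
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  n <- length(chars)
  depth_t <- 0L; depth_l <- 0L
  cuts <- integer()
  i <- 1L
  while (i <= n) {
    two <- if (i < n) paste0(chars[i], chars[i + 1L]) else ""
    if (two == "{{") { depth_t <- depth_t + 1L; i <- i + 2L; next }
    if (two == "}}") { depth_t <- depth_t - 1L; i <- i + 2L; next }
    if (two == "[[") { depth_l <- depth_l + 1L; i <- i + 2L; next }
    if (two == "]]") { depth_l <- depth_l - 1L; i <- i + 2L; next }
    if (chars[i] == "|" && depth_t == 0L && depth_l == 0L) cuts <- c(cuts, i)
    i <- i + 1L
  }
  if (!length(cuts)) return(character())
  starts <- cuts + 1L
  ends <- c(cuts[-1] - 1L, n)
  vapply(seq_along(starts), function(k) {
    paste0(chars[starts[k]:ends[k]], collapse = "")
  }, character(1))
}

# Recursively collect name=value parameters from a template body and all
# nested templates (Chembox section sub-templates).
.collect_params <- function(body) {
  params <- list()
  for (p in .split_params(body)) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0L) next
    name <- trimws(substr(p, 1L, eq - 1L))
    value <- trimws(substring(p, eq + 1L))
    if (nzchar(name)) {
      params[[length(params) + 1L]] <- list(name = name, value = value)
    }
    for (tpl in .find_templates(value)) {
      params <- c(params, .collect_params(tpl$body))
    }
  }
  params
}

# Unwrap <nowiki> wrappers, {{!}} pipe escapes, surrounding whitespace.
.clean_smiles_value <- function(v) {
  v <- gsub("</?nowiki/?>", "", v)
  v <- gsub("{{!}}", "|", v, fixed = TRUE)
  trimws(v)
}

#' Extract SMILES entries from a wiki page
#'
#' Locates `{{Chembox ...}}` / `{{Infobox drug ...}}` (Drugbox) templates,
#' including nested section sub-templates, and collects every parameter
#' whose name matches `SMILES` case-insensitively with an optional numeric
#' suffix. Pages with no SMILES yield an empty data.frame (callers tally
#' them as "missing SMILES"). Malformed template braces flag the page via
#' `attr(, "malformed")` instead of failing.
#'
#' @param page a [wiki_page()].
#' @return data.frame with columns `page`, `smiles_raw`, `smiles_field`,
#'   `template`.
#' @export
extract_entries <- function(page) {
  stopifnot(inherits(page, "wiki_page"))
  tpls <- .find_templates(page$wikitext)
  rows <- list()
  for (tpl in tpls) {
    nm <- tolower(tpl$name)
    template <- if (grepl("^chembox", nm)) "chembox"
      else if (grepl("^(infobox[ _]+drug|drugbox)", nm)) "drugbox"
      else next
    for (pr in .collect_params(tpl$body)) {
      if (!grepl("^smiles[0-9]*$", tolower(pr$name))) next
      val <- .clean_smiles_value(pr$value)
      if (!nzchar(val)) next
      rows[[length(rows) + 1L]] <- data.frame(
        page = page$title, smiles_raw = val, smiles_field = pr$name,
        template = template, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(page = character(), smiles_raw = character(),
               smiles_field = character(), template = character(),
               stringsAsFactors = FALSE)
  attr(out, "malformed") <- isTRUE(attr(tpls, "malformed"))
  out
}

#' Consolidate per-page SMILES entries
#'
#' Within a page, entries that encode exactly the same structure
#' (stereo-aware canonical comparison) are collapsed to the first one;
#' genuinely different structures (usually stereo variants) each stay.
#' Unparseable entries are routed to the error report with their classified
#' [parse_issue()] attached.
#'
#' @param entries data.frame as produced by [extract_entries()] (one or
#'   several pages).
#' @return list with `kept` (entries plus `canonical` column), `errors`
#'   (page, smiles_raw, error_class, position, suggested_fix) and `dropped`
#'   (within-page duplicates).
#' @export
consolidate <- function(entries) {
  kept <- list(); errs <- list(); dropped <- list()
  for (pg in unique(entries$page)) {
    sub <- entries[entries$page == pg, , drop = FALSE]
    seen_canon <- character()
    for (r in seq_len(nrow(sub))) {
      g <- parse_smiles(sub$smiles_raw[r])
      if (is_parse_issue(g)) {
        errs[[length(errs) + 1L]] <- data.frame(
          page = pg, smiles_raw = sub$smiles_raw[r],
          error_class = g$error_class, position = g$position,
          suggested_fix = if (is.null(g$suggested_fix)) "" else
            g$suggested_fix,
          stringsAsFactors = FALSE)
        next
      }
      can <- canonical_smiles(g)$canonical_smiles
      if (can %in% seen_canon) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          page = pg, smiles_raw = sub$smiles_raw[r], canonical = can,
          stringsAsFactors = FALSE)
        next
      }
      seen_canon <- c(seen_canon, can)
      row <- sub[r, , drop = FALSE]
      row$canonical <- can
      kept[[length(kept) + 1L]] <- row
    }
  }
  bindr <- function(lst, proto) {
    if (length(lst)) {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    } else proto
  }
  list(
    kept = bindr(kept, data.frame(
      page = character(), smiles_raw = character(),
      smiles_field = character(), template = character(),
      canonical = character(), stringsAsFactors = FALSE)),
    errors = bindr(errs, data.frame(
      page = character(), smiles_raw = character(), error_class = character(),
      position = integer(), suggested_fix = character(),
      stringsAsFactors = FALSE)),
    dropped = bindr(dropped, data.frame(
      page = character(), smiles_raw = character(), canonical = character(),
      stringsAsFactors = FALSE)))
}

#' Find cross-page duplicate structures in an index
#'
#' Groups of two or more records on different pages sharing a stereo-aware
#' canonical structure; a second listing uses stereo-stripped structures and
#' marks the groups that only merge after stripping (the nonstereo-duplicate
#' situation).
#'
#' @param index a `chem_index`.
#' @return list with `stereo` and `stripped`, each a list of data.frames
#'   (`structure`, `page`); stripped groups carry
#'   `attr(, "merged_by_stripping")`.
#' @export
find_duplicates <- function(index) {
  recs <- index$records
  group_by_key <- function(keys) {
    out <- list()
    for (k in unique(keys)) {
      rows <- which(keys == k)
      if (length(rows) < 2L) next
      if (length(unique(recs$page[rows])) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        structure = recs$structure[rows], page = recs$page[rows],
        stringsAsFactors = FALSE)
    }
    out
  }
  stereo <- group_by_key(recs$structure)
  stripped_keys <- vapply(seq_len(nrow(recs)), function(r) {
    canonical_smiles(index$graphs[[r]])$stereo_stripped_smiles
  }, character(1))
  stripped <- group_by_key(stripped_keys)
  stripped <- lapply(stripped, function(gr) {
    attr(gr, "merged_by_stripping") <-
      length(unique(gr$structure)) > 1L
    gr
  })
  list(stereo = stereo, stripped = stripped)
}

#' Classify a Wikipedia-vs-reference structure disagreement
#'
#' `MATCH` when the stereo-aware canonical forms are equal;
#' `SAME_FORMULA_DIFFERENT_STRUCTURE` when only the Hill formulas agree
#' (tautomer / positional-isomer candidates); `FORMULA_MISMATCH` otherwise.
#' An unparseable reference yields a skipped verdict (`NA`) with a note.
#'
#' @param wiki_smiles SMILES found in the wiki infobox (must parse).
#' @param reference_smiles SMILES from the external database.
#' @return a `crossref_verdict`: list(verdict, note).
#' @examples
#' classify_crossref("CC(O)C", "CCCO")$verdict
#' @export
classify_crossref <- function(wiki_smiles, reference_smiles) {
  gw <- parse_smiles(wiki_smiles)
  if (is_parse_issue(gw)) {
    stop(sprintf("wiki SMILES does not parse: %s", gw$error_class))
  }
  gr <- parse_smiles(reference_smiles)
  if (is_parse_issue(gr)) {
    return(structure(list(verdict = NA_character_,
                          note = sprintf("reference SMILES unparseable (%s)",
                                         gr$error_class)),
                     class = "crossref_verdict"))
  }
  verdict <- if (same_structure(gw, gr)) {
    "MATCH"
  } else if (identical(molecular_formula(gw), molecular_formula(gr))) {
    "SAME_FORMULA_DIFFERENT_STRUCTURE"
  } else {
    "FORMULA_MISMATCH"
  }
  structure(list(verdict = verdict, note = ""), class = "crossref_verdict")
}

#' Export the index as a SMILES list
#'
#' One line per record: canonical SMILES, a tab, the page title; ordered by
#' page title (then structure) for stable output.
#'
#' @param index a `chem_index`.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of lines (invisibly when written to a file).
#' @export
export_smiles_list <- function(index, path = NULL) {
  recs <- index$records
  ord <- order(recs$page, recs$structure, method = "radix")
  lines <- if (nrow(recs)) {
    paste0(recs$structure[ord], "\t", recs$page[ord])
  } else character()
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read / write line-delimited JSON corpora of wiki pages
#'
#' Each line is a JSON object `{"title": ..., "wikitext": ...}`. A directory
#' path is also accepted: every `*.wiki` file becomes one page titled by its
#' base name.
#'
#' @param path JSONL file or directory of `.wiki` files.
#' @param pages list of [wiki_page()] objects.
#' @return `read_corpus()` returns a list of `wiki_page` objects.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.wiki$", full.names = TRUE))
    return(lapply(files, function(f) {
      wiki_page(sub("\\.wiki$", "", basename(f)),
                paste(readLines(f, warn = FALSE), collapse = "\n"))
    }))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    wiki_page(obj$title, obj$wikitext)
  })
}

#' @rdname read_corpus
#' @export
write_corpus <- function(pages, path) {
  lines <- vapply(pages, function(p) {
    jsonlite::toJSON(list(title = jsonlite::unbox(p$title),
                          wikitext = jsonlite::unbox(p$wikitext)))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
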