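#' Extract the integer portion of an HGNC identifier
#'
#' Genes are keyed across resources by the integer portion of their HGNC id,
#' so `"HGNC:5"` and `"5"` both denote gene 5.
#'
#' @param raw Character vector of the form `"HGNC:<digits>"` or bare digits.
#' @return Integer vector of the same length.
#' @examples
#' parse_hgnc_id(c("HGNC:5", "1100"))
#' @export
parse_hgnc_id <- function(raw) {
  raw <- as.character(raw)
  digits <- ifelse(grepl("^HGNC:[0-9]+$", raw), sub("^HGNC:", "", raw),
                   ifelse(grepl("^[0-9]+$", raw), raw, NA_character_))
  if (anyNA(digits) | !length(raw)) {
    bad <- raw[is.na(digits)]
    abort(paste0("malformed HGNC id(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")),
          class = "idmap_format_error")
  }
  as.integer(digits)
}

#' Build a gene alias table
#'
#' HGNC's current symbols plus outdated symbols and synonyms, all pointing
#' at the integer HGNC id, so legacy symbols in resource tables can be
#' resolved. Each current symbol must map to exactly one gene; aliases may
#' be shared (and then resolve as ambiguous).
#'
#' @param records Data frame with columns `symbol`, `hgnc_id`, `status`
#'   (one of `"current"`, `"outdated"`, `"synonym"`).
#' @return An object of class `alias_table`.
#' @export
alias_table <- function(records) {
  records <- as_tibble(records)
  need <- c("symbol", "hgnc_id", "status")
  if (!all(need %in% names(records))) {
    abort("alias records need columns symbol, hgnc_id, status",
          class = "hetnet_schema_error")
  }
  records$symbol <- as.character(records$symbol)
  records$hgnc_id <- as.integer(records$hgnc_id)
  records$status <- as.character(records$status)
  if (any(is.na(records$hgnc_id) | records$hgnc_id <= 0)) {
    abort("hgnc_id must be a positive integer", class = "idmap_format_error")
  }
  if (any(!nzchar(records$symbol))) {
    abort("symbols must be non-empty", class = "idmap_format_error")
  }
  bad <- setdiff(unique(records$status), c("current", "outdated", "synonym"))
  if (length(bad)) {
    abort(paste0("unknown status value(s): ", paste(bad, collapse = ", ")),
          class = "idmap_format_error")
  }
  records <- distinct(records)
  cur <- filter(records, status == "current")
  dup <- cur |> distinct(symbol, hgnc_id) |> count(symbol) |> filter(n > 1)
  if (nrow(dup)) {
    abort(paste0("current symbol(s) mapped to multiple genes: ",
                 paste(dup$symbol, collapse = ", ")),
          class = "idmap_format_error")
  }
  structure(list(records = records), class = "alias_table")
}

#' @export
print.alias_table <- function(x, ...) {
  cat(sprintf("<alias_table> %d records (%d current symbols)\n",
              nrow(x$records), sum(x$records$status == "current")))
  invisible(x)
}

#' Resolve gene symbols to HGNC ids
#'
#' Resolution precedence: a current symbol wins outright; otherwise a symbol
#' that is an alias (outdated symbol or synonym) of exactly one gene
#' resolves to that gene; an alias shared by several genes is reported as
#' ambiguous, never picked arbitrarily; anything else is not found.
#' Matching is case-sensitive exact match by default (HGNC symbols are
#' case-significant).
#'
#' @param table An [alias_table()].
#' @param query Character vector of symbols to resolve.
#' @param case_insensitive Fall back to case-folded matching. Default off.
#' @return A tibble with one row per query: `symbol`, `hgnc_id` (NA unless
#'   resolved), `match` (`"current"`, `"alias"`, `"ambiguous"`,
#'   `"not_found"`) and `candidates` (list column of all candidate ids).
#' @export
resolve_gene <- function(table, query, case_insensitive = FALSE) {
  stopifnot(inherits(table, "alias_table"))
  query <- as.character(query)
  rec <- table$records
  key <- if (case_insensitive) tolower(rec$symbol) else rec$symbol
  qkey <- if (case_insensitive) tolower(query) else query

  one <- function(q) {
    hit <- rec[key == q & !is.na(key), ]
    cur <- unique(hit$hgnc_id[hit$status == "current"])
    if (length(cur) == 1) {
      return(list(hgnc_id = cur, match = "current", candidates = cur))
    }
    ali <- sort(unique(hit$hgnc_id[hit$status != "current"]))
    if (length(ali) == 1) {
      return(list(hgnc_id = ali, match = "alias", candidates = ali))
    }
    if (length(ali) > 1) {
      return(list(hgnc_id = NA_integer_, match = "ambiguous",
                  candidates = ali))
    }
    list(hgnc_id = NA_integer_, match = "not_found", candidates = integer())
  }
  res <- map(qkey, one)
  tibble(
    symbol = query,
    hgnc_id = map_int(res, "hgnc_id"),
    match = map_chr(res, "match"),
    candidates = map(res, "candidates")
  )
}

#' Build a phenotype cross-reference map
#'
#' Maps identifiers from the OMIM, MeSH and EFO vocabularies onto the
#' disease-ontology (DO) id they cross-reference, unifying phenotype nodes
#' across resources. Sources without a cross-reference keep their own
#' namespaced id (and so stay distinct nodes).
#'
#' @param entries Data frame with columns `vocab` (one of `"DO"`, `"OMIM"`,
#'   `"MeSH"`, `"EFO"`), `source_id`, `do_id`.
#' @return An object of class `xref_map`.
#' @export
xref_map <- function(entries) {
  entries <- as_tibble(entries)
  need <- c("vocab", "source_id", "do_id")
  if (!all(need %in% names(entries))) {
    abort("xref entries need columns vocab, source_id, do_id",
          class = "hetnet_schema_error")
  }
  entries <- entries |>
    mutate(vocab = as.character(vocab), source_id = as.character(source_id),
           do_id = as.character(do_id)) |>
    distinct()
  bad <- setdiff(unique(entries$vocab), c("DO", "OMIM", "MeSH", "EFO"))
  if (length(bad)) {
    abort(paste0("unknown vocabulary label(s): ",
                 paste(bad, collapse = ", ")),
          class = "idmap_format_error")
  }
  structure(list(entries = entries), class = "xref_map")
}

#' @export
print.xref_map <- function(x, ...) {
  cat(sprintf("<xref_map> %d cross-references (%s)\n", nrow(x$entries),
              paste(sort(unique(x$entries$vocab)), collapse = ", ")))
  invisible(x)
}

xref_prefix <- c(DO = "", OMIM = "OMIM:", MeSH = "MESH:", EFO = "EFO:")

#' Map phenotype identifiers to the canonical vocabulary
#'
#' Returns the DO id when a cross-reference exists; otherwise the namespaced
#' source id passes through unchanged so unmapped terms remain distinct
#' nodes. A source id cross-referenced to several DO terms is reported as
#' ambiguous with all candidates, never silently merged.
#'
#' @param xm An [xref_map()].
#' @param vocab Vocabulary label(s), each one of `"DO"`, `"OMIM"`, `"MeSH"`,
#'   `"EFO"` (recycled against `source_id`).
#' @param source_id Character vector of source identifiers.
#' @return A tibble with one row per input: `vocab`, `source_id`,
#'   `canonical_id` (NA when ambiguous), `match` (`"do"`, `"xref"`,
#'   `"passthrough"`, `"ambiguous"`), `candidates` (list column).
#' @examples
#' xm <- xref_map(data.frame(vocab = "OMIM", source_id = "152700",
#'                           do_id = "DOID:9074"))
#' map_phenotype(xm, "OMIM", c("152700", "999999"))
#' @export
map_phenotype <- function(xm, vocab, source_id) {
  stopifnot(inherits(xm, "xref_map"))
  source_id <- as.character(source_id)
  vocab <- as.character(vocab)
  if (length(vocab) == 1) vocab <- rep(vocab, length(source_id))
  if (length(vocab) != length(source_id)) {
    abort("vocab must have length 1 or length(source_id)",
          class = "idmap_format_error")
  }
  bad <- setdiff(unique(vocab), names(xref_prefix))
  if (length(bad)) {
    abort(paste0("unknown vocabulary label(s): ",
                 paste(bad, collapse = ", ")),
          class = "idmap_format_error")
  }
  ent <- xm$entries
  one <- function(v, s) {
    if (v == "DO") {
      return(list(canonical_id = s, match = "do", candidates = s))
    }
    hits <- sort(unique(ent$do_id[ent$vocab == v & ent$source_id == s]))
    if (length(hits) == 1) {
      list(canonical_id = hits, match = "xref", candidates = hits)
    } else if (length(hits) > 1) {
      list(canonical_id = NA_character_, match = "ambiguous",
           candidates = hits)
    } else {
      pass <- paste0(xref_prefix[[v]], s)
      list(canonical_id = pass, match = "passthrough", candidates = pass)
    }
  }
  res <- map2(vocab, source_id, one)
  tibble(
    vocab = vocab,
    source_id = source_id,
    canonical_id = map_chr(res, "canonical_id"),
    match = map_chr(res, "match"),
    candidates = map(res, "candidates")
  )
}
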