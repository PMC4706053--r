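#' Read an OBO ontology
#'
#' Parses the OBO 1.2 flat-file subset used by the disease, tissue and
#' side-effect vocabularies: `[Term]` stanzas with `id`, `name`, `is_a`,
#' `xref` and `is_obsolete` tags. Trailing `! comments` on `is_a` lines are
#' stripped; unknown tags and non-Term stanzas are ignored. The `is_a`
#' relation must form a DAG over existing terms.
#'
#' @param path Path to an OBO file, or a character vector of OBO lines.
#' @return An object of class `ontology`: a list with tibbles `terms`
#'   (`id`, `name`, `obsolete`), `parents` (`id`, `parent`), `xrefs`
#'   (`id`, `xref`) and a `root` (NA until [root_at()] is applied).
#' @examples
#' ont <- read_obo(c("[Term]", "id: A", "name: child", "is_a: B",
#'                   "[Term]", "id: B", "name: parent"))
#' ont$parents
#' @export
read_obo <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readr::read_lines(path)
  } else {
    as.character(path)
  }
  lines <- sub("\r$", "", lines)

  stanza_starts <- grep("^\\[", lines)
  terms <- list()
  for (k in seq_along(stanza_starts)) {
    s <- stanza_starts[k]
    if (lines[s] != "[Term]") next
    e <- if (k < length(stanza_starts)) stanza_starts[k + 1] - 1 else length(lines)
    body <- lines[(s + 1):e]
    body <- body[nzchar(body)]
    tag_val <- stringr::str_match(body, "^([A-Za-z_]+):\\s*(.*)$")
    tags <- tag_val[, 2]
    vals <- tag_val[, 3]
    get1 <- function(tag) {
      v <- vals[which(tags == tag)]
      if (length(v)) v[1] else NA_character_
    }
    id <- get1("id")
    if (is.na(id) || !nzchar(id)) {
      abort("[Term] stanza without an id tag", class = "obo_parse_error")
    }
    is_a <- vals[which(tags == "is_a")]
    is_a <- stringr::str_trim(sub("!.*$", "", is_a))
    xr <- stringr::str_trim(sub("!.*$", "", vals[which(tags == "xref")]))
    terms[[length(terms) + 1]] <- list(
      id = id,
      name = get1("name") %||% id,
      obsolete = identical(tolower(get1("is_obsolete")), "true"),
      is_a = is_a[nzchar(is_a)],
      xrefs = xr[nzchar(xr)]
    )
  }

  term_tbl <- tibble(
    id = map_chr(terms, "id"),
    name = map_chr(terms, function(t) t$name %||% t$id),
    obsolete = map_lgl(terms, "obsolete")
  )
  if (anyDuplicated(term_tbl$id)) {
    abort(paste0("duplicate term id(s): ",
                 paste(unique(term_tbl$id[duplicated(term_tbl$id)]),
                       collapse = ", ")),
          class = "obo_parse_error")
  }
  parent_tbl <- list_rbind(map(terms, function(t) {
    if (length(t$is_a)) tibble(id = t$id, parent = t$is_a) else NULL
  })) %||% tibble(id = character(), parent = character())
  if (!nrow(parent_tbl)) {
    parent_tbl <- tibble(id = character(), parent = character())
  }
  xref_tbl <- list_rbind(map(terms, function(t) {
    if (length(t$xrefs)) tibble(id = t$id, xref = t$xrefs) else NULL
  })) %||% tibble(id = character(), xref = character())
  if (!nrow(xref_tbl)) {
    xref_tbl <- tibble(id = character(), xref = character())
  }

  dangling <- setdiff(parent_tbl$parent, term_tbl$id)
  if (length(dangling)) {
    off <- parent_tbl$id[parent_tbl$parent %in% dangling]
    abort(paste0("is_a target(s) not defined in the ontology: ",
                 paste(unique(dangling), collapse = ", "),
                 " (referenced by ", paste(unique(off), collapse = ", "), ")"),
          class = "obo_parse_error")
  }
  if (nrow(parent_tbl)) {
    g <- igraph::graph_from_data_frame(parent_tbl, directed = TRUE,
                                       vertices = term_tbl["id"])
    if (!igraph::is_dag(g)) {
      abort("is_a relation contains a cycle", class = "obo_cycle_error")
    }
  }

  structure(list(terms = term_tbl, parents = distinct(parent_tbl),
                 xrefs = distinct(xref_tbl), root = NA_character_),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms (%d obsolete), %d is_a links%s\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$parents),
              if (!is.na(x$root)) paste0(", rooted at ", x$root) else ""))
  invisible(x)
}

#' Tidy an ontology into its term table
#'
#' @param x An [ontology][read_obo].
#' @param ... Unused.
#' @return The `terms` tibble joined with a parent count.
#' @method tidy ontology
#' @export
tidy.ontology <- function(x, ...) {
  x$terms |>
    left_join(count(x$parents, id, name = "n_parents"), by = "id") |>
    mutate(n_parents = coalesce(n_parents, 0L))
}

ont_check_term <- function(ont, term_id) {
  missing <- setdiff(term_id, ont$terms$id)
  if (length(missing)) {
    abort(paste0("term(s) not in ontology: ",
                 paste(missing, collapse = ", ")),
          class = "ontology_lookup_error")
  }
}

# child adjacency: named list parent -> children ids
ont_children_index <- function(ont) {
  split(ont$parents$id, ont$parents$parent)
}

# parent adjacency: named list id -> parent ids
ont_parent_index <- function(ont) {
  split(ont$parents$parent, ont$parents$id)
}

bfs_reach <- function(index, start) {
  seen <- character()
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(index[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, start))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Descendants of an ontology term
#'
#' All terms from which `term_id` is reachable by `is_a` chains — the terms
#' that are "more specific" than it. Excludes the term itself.
#'
#' @param ont An [ontology][read_obo].
#' @param term_id A term accession present in the ontology.
#' @return Character vector of descendant term ids (sorted).
#' @export
ont_descendants <- function(ont, term_id) {
  ont_check_term(ont, term_id)
  sort(bfs_reach(ont_children_index(ont), term_id))
}

#' Ancestors of an ontology term
#'
#' All terms reachable from `term_id` by following `is_a` links upward.
#' Excludes the term itself.
#'
#' @inheritParams ont_descendants
#' @return Character vector of ancestor term ids (sorted).
#' @export
ont_ancestors <- function(ont, term_id) {
  ont_check_term(ont, term_id)
  sort(bfs_reach(ont_parent_index(ont), term_id))
}

#' Root an ontology at a term
#'
#' Keeps exactly the root and its descendants, dropping everything else and
#' pruning `is_a` links that point outside the retained set. This is how the
#' tissue ontology is restricted to its animal portion by rooting at
#' 'whole body' (BTO:0001489).
#'
#' @param ont An [ontology][read_obo].
#' @param root_id Term id to root at.
#' @return The restricted ontology, with `root` set.
#' @export
root_at <- function(ont, root_id) {
  ont_check_term(ont, root_id)
  keep <- c(root_id, ont_descendants(ont, root_id))
  ont$terms <- filter(ont$terms, id %in% keep)
  ont$parents <- filter(ont$parents, id %in% keep, parent %in% keep)
  ont$xrefs <- filter(ont$xrefs, id %in% keep)
  ont$root <- root_id
  ont
}

#' Propagate tissue annotations down an ontology
#'
#' Implements ontology inference of term-to-tissue links: high-level terms
#' are manually mapped to affected tissues, and every term inherits the
#' union of the manual annotations of itself and all of its ancestors, so
#' only high-level terms need manual curation. Propagation follows `is_a`
#' only and is downward-only (ancestors of an annotated term gain nothing).
#' Obsolete terms receive no inferred annotations.
#'
#' @param ont An [ontology][read_obo].
#' @param manual Data frame with columns `term_id`, `tissue_id`: the manual
#'   high-level mapping. Every `term_id` must exist in `ont`.
#' @return A tibble with columns `term_id`, `tissue_id`, one row per
#'   inferred (term, tissue) pair; terms with no annotation are absent.
#' @examples
#' ont <- read_obo(c("[Term]", "id: DOID:65", "name: connective tissue disease",
#'                   "[Term]", "id: DOID:0050", "is_a: DOID:65"))
#' propagate_annotations(ont,
#'   data.frame(term_id = "DOID:65", tissue_id = "BTO:0000421"))
#' @export
propagate_annotations <- function(ont, manual) {
  manual <- as_tibble(manual)
  if (!all(c("term_id", "tissue_id") %in% names(manual))) {
    abort("manual map needs columns term_id, tissue_id",
          class = "hetnet_schema_error")
  }
  if (!nrow(manual)) return(tibble(term_id = character(),
                                   tissue_id = character()))
  unknown <- setdiff(unique(manual$term_id), ont$terms$id)
  if (length(unknown)) {
    abort(paste0("manual map key(s) absent from ontology: ",
                 paste(unknown, collapse = ", ")),
          class = "ontology_lookup_error")
  }
  manual <- distinct(manual, term_id, tissue_id)

  # process terms in topological order (parents before children) and take
  # ann[t] = manual[t] U union of ann[parents]
  g <- igraph::graph_from_data_frame(
    ont$parents[c("parent", "id")], directed = TRUE,
    vertices = ont$terms["id"])
  topo <- names(igraph::topo_sort(g, mode = "out"))
  pidx <- ont_parent_index(ont)
  midx <- split(manual$tissue_id, manual$term_id)
  ann <- list()
  for (t in topo) {
    own <- midx[[t]] %||% character()
    inherited <- unique(unlist(ann[pidx[[t]] %||% character()],
                               use.names = FALSE))
    tissues <- unique(c(own, inherited))
    if (length(tissues)) ann[[t]] <- tissues
  }
  obsolete_ids <- ont$terms$id[ont$terms$obsolete]
  # obsolete terms keep manual rows verbatim but gain nothing by inference
  for (t in intersect(obsolete_ids, names(ann))) {
    own <- midx[[t]] %||% character()
    if (length(own)) ann[[t]] <- own else ann[[t]] <- NULL
  }
  if (!length(ann)) return(tibble(term_id = character(),
                                  tissue_id = character()))
  out <- tibble(term_id = rep(names(ann), lengths(ann)),
                tissue_id = unlist(ann, use.names = FALSE)) |>
    arrange(term_id, tissue_id)
  out
}
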