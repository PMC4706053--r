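# metagraph reconstructed from observed node/edge kinds, used when a file
# format (SIF, GraphML, plain tables) does not carry the schema itself
infer_metagraph <- function(nodes, edges) {
  kinds <- sort(unique(nodes$kind))
  kind_of <- setNames(nodes$kind, nodes$id)
  if (!nrow(edges)) {
    dmg <- default_metagraph()
    if (all(kinds %in% dmg$node_kinds)) return(dmg)
    return(metagraph(kinds, tibble(kind = character(),
                                   kind_a = character(),
                                   kind_b = character())))
  }
  ek <- edges |>
    mutate(kind_a = unname(kind_of[source]),
           kind_b = unname(kind_of[target])) |>
    rowwise() |>
    mutate(kind_a2 = min(kind_a, kind_b), kind_b2 = max(kind_a, kind_b)) |>
    ungroup() |>
    distinct(kind, kind_a = kind_a2, kind_b = kind_b2)
  if (anyDuplicated(ek$kind)) {
    abort("an edge kind connects more than one pair of node kinds",
          class = "hetnet_type_error")
  }
  # prefer the default metagraph whenever the data fits it, so files written
  # from default-schema networks read back with the full schema
  dmg <- default_metagraph()
  deps <- mg_endpoints(dmg)
  fits <- all(kinds %in% dmg$node_kinds) &&
    all(map_lgl(seq_len(nrow(ek)), function(i) {
      identical(deps[[ek$kind[i]]] %||% "",
                sort(c(ek$kind_a[i], ek$kind_b[i])))
    }))
  if (fits) return(dmg)
  metagraph(kinds, ek)
}

#' Write a hetnet as SIF with a node-attribute sidecar
#'
#' SIF (simple interaction format) carries one tab-delimited edge per line:
#' `source<TAB>edge_kind<TAB>target`. Isolated nodes are written as bare-id
#' lines. Node kinds and labels go to a sidecar TSV (`<path>.nodes.tsv` by
#' default). Output is sorted so exports are diffable. Edge attributes are
#' not representable in SIF; use [write_graphml()] to keep them.
#'
#' @param net A [hetnet()].
#' @param path Output SIF path.
#' @param nodes_path Sidecar TSV path; default `paste0(path, ".nodes.tsv")`.
#' @return Invisibly, a list with `sif` and `nodes` paths.
#' @export
write_sif <- function(net, path, nodes_path = paste0(path, ".nodes.tsv")) {
  stopifnot(inherits(net, "hetnet"))
  e <- arrange(net$edges, source, kind, target)
  lines <- sprintf("%s\t%s\t%s", e$source, e$kind, e$target)
  isolated <- sort(setdiff(net$nodes$id, c(e$source, e$target)))
  writeLines(c(lines, isolated), path)
  readr::write_tsv(arrange(select(net$nodes, id, kind, label), id),
                   nodes_path, progress = FALSE)
  invisible(list(sif = path, nodes = nodes_path))
}

#' Read a hetnet from SIF plus its node sidecar
#'
#' @param path SIF path as written by [write_sif()].
#' @param nodes_path Sidecar TSV path.
#' @param metagraph Optional [metagraph]; by default it is inferred from
#'   the observed node and edge kinds (the default metagraph is used when
#'   the data conforms to it).
#' @return A [hetnet()].
#' @export
read_sif <- function(path, nodes_path = paste0(path, ".nodes.tsv"),
                     metagraph = NULL) {
  nodes <- readr::read_tsv(nodes_path, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- stringr::str_split(lines, "\t")
  n_fields <- lengths(parts)
  if (any(!n_fields %in% c(1L, 3L))) {
    abort("malformed SIF line (expected 1 or 3 tab-separated fields)",
          class = "hetnet_parse_error")
  }
  ep <- parts[n_fields == 3L]
  edges <- tibble(
    source = map_chr(ep, 1), kind = map_chr(ep, 2), target = map_chr(ep, 3)
  )
  mg <- metagraph %||% infer_metagraph(nodes, edges)
  hetnet(nodes = nodes, edges = edges, metagraph = mg)
}

#' Write a hetnet as GraphML
#'
#' Nodes carry `kind` and `label` attributes; edges carry `kind` plus any
#' extra attribute columns (`weight`, `p_value`, ...). The graph is
#' undirected.
#'
#' @param net A [hetnet()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "hetnet"))
  # integer NA would be serialized as the -2^31 sentinel; doubles round-trip
  # (missing values as NaN, restored to NA on read)
  to_double <- function(df) {
    for (col in names(df)) {
      if (is.integer(df[[col]])) df[[col]] <- as.double(df[[col]])
    }
    df
  }
  net$nodes <- to_double(net$nodes)
  net$edges <- to_double(net$edges)
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a hetnet from GraphML
#'
#' Numeric edge attributes holding whole numbers (notably projection
#' `weight`s) are restored as integers. Missing attribute values survive a
#' write/read cycle: numeric NaN and the literal string "NA" are read back
#' as NA (the writer emits those spellings for missing values).
#'
#' @param path GraphML file written by [write_graphml()] (or any GraphML
#'   whose nodes carry `kind`, with node ids in the `name` attribute).
#' @param metagraph Optional [metagraph]; inferred from the data when NULL.
#' @return A [hetnet()].
#' @export
read_graphml <- function(path, metagraph = NULL) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0) {
    return(hetnet(metagraph = metagraph %||% default_metagraph()))
  }
  va <- igraph::vertex_attr(g)
  if (is.null(va$name)) {
    abort("GraphML nodes carry no 'name' attribute", class = "hetnet_parse_error")
  }
  nodes <- as_tibble(va[setdiff(names(va), "id")]) |>
    rename(id = name)
  ea <- igraph::edge_attr(g)
  ends <- igraph::as_edgelist(g, names = TRUE)
  edges <- bind_cols(tibble(source = ends[, 1], target = ends[, 2]),
                     as_tibble(ea))
  fix_na <- function(df) {
    for (col in names(df)) {
      v <- df[[col]]
      if (is.numeric(v)) v[is.nan(v)] <- NA
      if (is.character(v)) v[v == "NA"] <- NA_character_
      df[[col]] <- v
    }
    df
  }
  nodes <- fix_na(nodes)
  edges <- fix_na(edges)
  for (col in names(edges)) {
    v <- edges[[col]]
    if (is.numeric(v) && all(is.na(v) | v == floor(v))) {
      edges[[col]] <- as.integer(v)
    }
  }
  mg <- metagraph %||% infer_metagraph(nodes, edges)
  net <- hetnet(nodes = nodes, edges = edges, metagraph = mg)
  if ("weight" %in% names(net$edges) &&
      setequal(mg$edge_kinds$kind, "similarity")) {
    class(net) <- c("similarity_network", class(net))
  }
  net
}

#' Write a hetnet as plain node and edge TSV tables
#'
#' Node table columns: `id`, `kind`, `label` (plus attribute columns).
#' Edge table columns: `source`, `target`, `kind` (plus attribute columns).
#'
#' @param net A [hetnet()].
#' @param nodes_path,edges_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_hetnet_tables <- function(net, nodes_path, edges_path) {
  stopifnot(inherits(net, "hetnet"))
  readr::write_tsv(arrange(net$nodes, id), nodes_path, progress = FALSE)
  readr::write_tsv(arrange(net$edges, source, target, kind), edges_path,
                   progress = FALSE)
  invisible(list(nodes = nodes_path, edges = edges_path))
}

#' Read a hetnet from plain node and edge TSV tables
#'
#' @param nodes_path,edges_path Paths written by [write_hetnet_tables()].
#' @param metagraph Optional [metagraph]; inferred when NULL.
#' @return A [hetnet()].
#' @export
read_hetnet_tables <- function(nodes_path, edges_path, metagraph = NULL) {
  nodes <- readr::read_tsv(nodes_path, show_col_types = FALSE,
                           progress = FALSE)
  edges <- readr::read_tsv(edges_path, show_col_types = FALSE,
                           progress = FALSE)
  mg <- metagraph %||% infer_metagraph(nodes, edges)
  hetnet(nodes = nodes, edges = edges, metagraph = mg)
}
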