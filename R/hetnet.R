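#' Construct a typed heterogeneous network
#'
#' A hetnet holds typed nodes and undirected typed edges and type-checks
#' both against a [metagraph]. Edges are stored once under a canonical
#' undirected key (lexicographically ordered endpoint pair plus edge kind);
#' re-adding an edge merges its attribute columns instead of duplicating it.
#'
#' @param nodes Optional data frame with columns `id`, `kind` and optionally
#'   `label` (defaults to the id). Extra columns are kept as node attributes.
#' @param edges Optional data frame with columns `source`, `target`, `kind`;
#'   extra columns (e.g. `p_value`, `evidence`, `weight`, `frequency`) are
#'   kept as edge attributes.
#' @param metagraph The [metagraph] the network must conform to.
#' @return An object of class `hetnet` with elements `metagraph`, `nodes`
#'   (tibble) and `edges` (tibble).
#' @examples
#' net <- hetnet(
#'   nodes = data.frame(id = c("DOID:65", "HGNC:5"),
#'                      kind = c("phenotype", "gene")),
#'   edges = data.frame(source = "DOID:65", target = "HGNC:5",
#'                      kind = "phenotype-gene")
#' )
#' glance(net)
#' @export
hetnet <- function(nodes = NULL, edges = NULL, metagraph = default_metagraph()) {
  net <- structure(
    list(metagraph = metagraph,
         nodes = tibble(id = character(), kind = character(),
                        label = character()),
         edges = tibble(source = character(), target = character(),
                        kind = character())),
    class = "hetnet"
  )
  if (!is.null(nodes)) net <- add_nodes(net, nodes)
  if (!is.null(edges)) net <- add_edges(net, edges)
  net
}

#' Add nodes to a hetnet
#'
#' Nodes are identified by their namespaced id string; the `(id, kind)` pair
#' must be unique, and one id cannot carry two kinds. Re-adding an existing
#' node merges attribute columns (later non-missing value wins).
#'
#' @param net A [hetnet()].
#' @param nodes Data frame with columns `id`, `kind` and optional `label`
#'   plus attribute columns.
#' @return The updated hetnet.
#' @export
add_nodes <- function(net, nodes) {
  stopifnot(inherits(net, "hetnet"))
  nodes <- as_tibble(nodes)
  if (!all(c("id", "kind") %in% names(nodes))) {
    abort("nodes need columns id and kind", class = "hetnet_schema_error")
  }
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  if (!nrow(nodes)) return(net)
  if (any(!nzchar(nodes$id) | is.na(nodes$id))) {
    abort("node ids must be non-empty", class = "hetnet_error")
  }
  if (any(grepl("\t", nodes$id))) {
    abort("node ids may not contain tab characters", class = "hetnet_error")
  }
  bad <- setdiff(unique(nodes$kind), net$metagraph$node_kinds)
  if (length(bad)) {
    abort(paste0("unknown node kind(s): ", paste(bad, collapse = ", ")),
          class = "hetnet_type_error")
  }
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  nodes$label <- coalesce(as.character(nodes$label), nodes$id)
  all_n <- bind_rows(net$nodes, nodes)
  conflict <- all_n |> distinct(id, kind) |> count(id) |> filter(n > 1)
  if (nrow(conflict)) {
    abort(paste0("node id(s) registered under two kinds: ",
                 paste(conflict$id, collapse = ", ")),
          class = "hetnet_type_error")
  }
  net$nodes <- merge_keyed(all_n, c("id", "kind"))
  net
}

#' Add edges to a hetnet
#'
#' Both endpoints must already be present and the edge kind must be
#' registered in the metagraph with endpoint kinds matching the endpoints
#' (in either order). Edges are undirected: the stored key orders the two
#' ids lexicographically. Adding an edge that already exists merges its
#' attribute columns, later non-missing value winning per column.
#'
#' @param net A [hetnet()].
#' @param edges Data frame with columns `source`, `target`, `kind` plus
#'   optional attribute columns.
#' @return The updated hetnet.
#' @export
add_edges <- function(net, edges) {
  stopifnot(inherits(net, "hetnet"))
  edges <- as_tibble(edges)
  if (!all(c("source", "target", "kind") %in% names(edges))) {
    abort("edges need columns source, target, kind",
          class = "hetnet_schema_error")
  }
  if (!nrow(edges)) return(net)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$kind <- as.character(edges$kind)

  missing_ids <- setdiff(unique(c(edges$source, edges$target)), net$nodes$id)
  if (length(missing_ids)) {
    abort(paste0("edge endpoint(s) not present as nodes: ",
                 paste(head(missing_ids, 10), collapse = ", ")),
          class = "hetnet_missing_node")
  }
  eps <- mg_endpoints(net$metagraph)
  bad_kind <- setdiff(unique(edges$kind), names(eps))
  if (length(bad_kind)) {
    abort(paste0("edge kind(s) not in metagraph: ",
                 paste(bad_kind, collapse = ", ")),
          class = "hetnet_type_error")
  }
  kind_of <- setNames(net$nodes$kind, net$nodes$id)
  got <- map_chr(seq_len(nrow(edges)), function(i) {
    paste(sort(c(kind_of[[edges$source[i]]], kind_of[[edges$target[i]]])),
          collapse = "|")
  })
  want <- map_chr(edges$kind, function(k) paste(eps[[k]], collapse = "|"))
  if (any(got != want)) {
    i <- which(got != want)[1]
    abort(sprintf(
      "edge %s -- %s has endpoint kinds (%s) incompatible with kind '%s' (%s)",
      edges$source[i], edges$target[i], got[i], edges$kind[i], want[i]),
      class = "hetnet_type_error")
  }

  swap <- edges$source > edges$target
  if (any(swap)) {
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
  }
  net$edges <- merge_keyed(bind_rows(net$edges, edges),
                           c("source", "target", "kind"))
  net
}

# collapse duplicate rows on `keys`, later non-missing value wins per column;
# result sorted by keys so construction order never leaks into output
merge_keyed <- function(df, keys) {
  df$.ord <- seq_len(nrow(df))
  out <- df |>
    group_by(across(all_of(keys))) |>
    arrange(.ord, .by_group = TRUE) |>
    summarise(across(-any_of(".ord"), last_non_na), .groups = "drop") |>
    arrange(across(all_of(keys)))
  out
}

last_non_na <- function(x) {
  keep <- !is.na(x)
  if (any(keep)) x[max(which(keep))] else x[length(x)]
}

#' Per-kind node and edge counts
#'
#' @param net A [hetnet()].
#' @return A tibble with columns `element` ("node" or "edge"), `kind` and
#'   `n`. Kinds with zero members are included for the network's metagraph.
#' @examples
#' counts <- hetnet_counts(hetnet())
#' sum(counts$n)  # 0
#' @export
hetnet_counts <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  nk <- tibble(element = "node", kind = net$metagraph$node_kinds) |>
    left_join(count(net$nodes, kind), by = "kind") |>
    mutate(n = coalesce(n, 0L))
  ek <- tibble(element = "edge", kind = net$metagraph$edge_kinds$kind) |>
    left_join(count(net$edges, kind), by = "kind") |>
    mutate(n = coalesce(n, 0L))
  bind_rows(nk, ek)
}

#' @export
print.hetnet <- function(x, ...) {
  cat(sprintf("<hetnet> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  cnt <- hetnet_counts(x) |> filter(n > 0)
  for (i in seq_len(nrow(cnt))) {
    cat(sprintf("  %-5s %-20s %d\n", cnt$element[i], cnt$kind[i], cnt$n[i]))
  }
  invisible(x)
}

#' Tidy a hetnet into its edge table
#'
#' @param x A [hetnet()].
#' @param ... Unused.
#' @return The edge tibble (canonicalized, one row per undirected edge).
#' @method tidy hetnet
#' @export
tidy.hetnet <- function(x, ...) x$edges

#' One-row summary of a hetnet
#'
#' @param x A [hetnet()].
#' @param ... Unused.
#' @return A tibble with `n_nodes`, `n_edges`, `n_node_kinds`,
#'   `n_edge_kinds` (kinds actually present).
#' @method glance hetnet
#' @export
glance.hetnet <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_node_kinds = dplyr::n_distinct(x$nodes$kind),
    n_edge_kinds = dplyr::n_distinct(x$edges$kind)
  )
}

#' Convert a hetnet to an igraph graph
#'
#' @param net A [hetnet()].
#' @param simplify Drop self-loops and collapse parallel edges of different
#'   kinds between the same node pair (used for topology statistics).
#' @return An undirected [igraph::graph] with node attributes `kind`,
#'   `label` and edge attribute `kind` (plus any extra edge columns).
#' @export
as_igraph <- function(net, simplify = FALSE) {
  stopifnot(inherits(net, "hetnet"))
  g <- igraph::graph_from_data_frame(
    d = net$edges,
    directed = FALSE,
    vertices = net$nodes
  )
  if (simplify) {
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = "first")
  }
  g
}
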