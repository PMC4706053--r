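# half-up decimal rounding (round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Project a bipartite layer into a similarity network
#'
#' Converts a bipartite layer of the hetnet (e.g. disease-gene) into a
#' homogeneous similarity network: two nodes of `project_kind` are connected
#' iff they share at least `min_shared` neighbors of `via_kind`, and the
#' edge weight is the exact shared-neighbor count. "More than 2 shared
#' genes" therefore corresponds to `min_shared = 3`.
#'
#' @param net A [hetnet()].
#' @param project_kind Node kind retained in the projection (e.g.
#'   `"phenotype"`).
#' @param via_kind Node kind counted as shared neighbors (e.g. `"gene"`).
#' @param min_shared Minimum shared-neighbor count for an edge
#'   (`>= 1`).
#' @return A `similarity_network` (also a [hetnet()] over a one-kind
#'   metagraph with edge kind `"similarity"` and integer `weight`). All
#'   `project_kind` nodes of `net` are kept, connected or not.
#' @export
similarity_projection <- function(net, project_kind, via_kind, min_shared = 1) {
  stopifnot(inherits(net, "hetnet"))
  if (!is.numeric(min_shared) || min_shared < 1) {
    abort("min_shared must be >= 1", class = "hetnet_parameter_error")
  }
  link_kinds <- mg_kinds_between(net$metagraph, project_kind, via_kind)
  if (!length(link_kinds)) {
    abort(paste0("metagraph has no edge kind linking ", project_kind,
                 " and ", via_kind),
          class = "hetnet_type_error")
  }
  kind_of <- setNames(net$nodes$kind, net$nodes$id)
  bip <- filter(net$edges, kind %in% link_kinds)
  nb <- bind_rows(
    tibble(proj = bip$source, via = bip$target),
    tibble(proj = bip$target, via = bip$source)
  ) |>
    filter(kind_of[proj] == project_kind, kind_of[via] == via_kind) |>
    distinct()

  pairs <- inner_join(nb, nb, by = "via", relationship = "many-to-many") |>
    filter(proj.x < proj.y) |>
    count(proj.x, proj.y, name = "weight") |>
    filter(weight >= min_shared)

  proj_nodes <- filter(net$nodes, kind == project_kind) |>
    select(id, kind, label)
  sim_mg <- metagraph(project_kind,
                      tibble(kind = "similarity", kind_a = project_kind,
                             kind_b = project_kind))
  sim <- hetnet(nodes = proj_nodes, metagraph = sim_mg)
  if (nrow(pairs)) {
    sim <- add_edges(sim, tibble(source = pairs$proj.x,
                                 target = pairs$proj.y,
                                 kind = "similarity",
                                 weight = as.integer(pairs$weight)))
  } else {
    sim$edges$weight <- integer()
  }
  class(sim) <- c("similarity_network", class(sim))
  attr(sim, "project_kind") <- project_kind
  attr(sim, "via_kind") <- via_kind
  attr(sim, "min_shared") <- min_shared
  sim
}

#' Topology report for a hetnet
#'
#' Computes the statistics used to contrast network topologies: node and
#' edge counts with the N/E ratio (nodes over edges, half-up to two
#' decimals), per-kind counts, connected-component sizes, the degree
#' distribution, neighborhood connectivity (mean neighbor degree,
#' aggregated by degree) and the unweighted shortest-path length
#' distribution of the largest connected component. Degrees, components and
#' paths are computed on the simple undirected graph induced by the hetnet
#' (self-loops ignored, parallel edges of different kinds collapsed);
#' `n_nodes`/`n_edges`/`ne_ratio` describe the hetnet itself.
#'
#' @param net A [hetnet()].
#' @return An object of class `topology_report`; see [glance.topology_report()]
#'   and [tidy.topology_report()].
#' @examples
#' net <- hetnet(nodes = data.frame(id = c("D1", "G1"),
#'                                  kind = c("phenotype", "gene")),
#'               edges = data.frame(source = "D1", target = "G1",
#'                                  kind = "phenotype-gene"))
#' topology_report(net)$ne_ratio
#' @export
topology_report <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  n_nodes <- nrow(net$nodes)
  n_edges <- nrow(net$edges)
  ne_ratio <- if (n_edges > 0) round_half_up(n_nodes / n_edges, 2) else NA_real_

  if (n_nodes == 0) {
    return(structure(list(
      n_nodes = 0L, n_edges = 0L, ne_ratio = NA_real_,
      n_edges_simple = 0L, counts = hetnet_counts(net),
      component_sizes = integer(),
      degree_distribution = tibble(degree = integer(), n_nodes = integer()),
      neighborhood_connectivity = tibble(degree = integer(),
                                         mean_neighbor_degree = double()),
      path_length_distribution = tibble(distance = integer(),
                                        n_pairs = double()),
      largest_component_size = 0L
    ), class = "topology_report"))
  }

  g <- as_igraph(net, simplify = TRUE)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  comp_sizes <- sort(as.integer(comp$csize), decreasing = TRUE)

  deg_dist <- tibble(degree = as.integer(deg)) |>
    count(degree, name = "n_nodes") |>
    arrange(degree)

  nc <- tibble(degree = integer(), mean_neighbor_degree = double())
  if (igraph::ecount(g) > 0) {
    knnk <- suppressWarnings(igraph::knn(g)$knnk)
    nc <- tibble(degree = seq_along(knnk), mean_neighbor_degree = knnk) |>
      filter(is.finite(mean_neighbor_degree))
  }

  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  pld <- tibble(distance = integer(), n_pairs = double())
  if (igraph::vcount(sub) > 1) {
    dt <- igraph::distance_table(sub, directed = FALSE)$res
    pld <- tibble(distance = seq_along(dt), n_pairs = as.double(dt)) |>
      filter(n_pairs > 0)
  }

  structure(list(
    n_nodes = n_nodes, n_edges = n_edges, ne_ratio = ne_ratio,
    n_edges_simple = igraph::ecount(g),
    counts = hetnet_counts(net),
    component_sizes = comp_sizes,
    degree_distribution = deg_dist,
    neighborhood_connectivity = nc,
    path_length_distribution = pld,
    largest_component_size = max(comp_sizes)
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> %d nodes, %d edges (N/E %s)\n",
              x$n_nodes, x$n_edges,
              ifelse(is.na(x$ne_ratio), "-", format(x$ne_ratio))))
  cat(sprintf("  components: %s\n",
              paste(head(x$component_sizes, 8), collapse = ", ")))
  cat(sprintf("  largest component: %d nodes\n", x$largest_component_size))
  invisible(x)
}

#' One-row summary of a topology report
#'
#' @param x A [topology_report()].
#' @param ... Unused.
#' @return A tibble with `n_nodes`, `n_edges`, `ne_ratio`,
#'   `n_components`, `largest_component_size`, `max_degree`,
#'   `mean_path_length` (largest component).
#' @method glance topology_report
#' @export
glance.topology_report <- function(x, ...) {
  mean_pl <- if (nrow(x$path_length_distribution)) {
    with(x$path_length_distribution, sum(distance * n_pairs) / sum(n_pairs))
  } else NA_real_
  tibble(
    n_nodes = x$n_nodes,
    n_edges = x$n_edges,
    ne_ratio = x$ne_ratio,
    n_components = length(x$component_sizes),
    largest_component_size = x$largest_component_size,
    max_degree = if (nrow(x$degree_distribution))
      max(x$degree_distribution$degree) else 0L,
    mean_path_length = mean_pl
  )
}

#' Tidy a topology report into its degree distribution
#'
#' @param x A [topology_report()].
#' @param ... Unused.
#' @return The degree-distribution tibble, joined with neighborhood
#'   connectivity where defined.
#' @method tidy topology_report
#' @export
tidy.topology_report <- function(x, ...) {
  left_join(x$degree_distribution, x$neighborhood_connectivity,
            by = "degree")
}

#' Serialize a topology report to JSON
#'
#' @param x A [topology_report()].
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "topology_report"))
  obj <- list(
    n_nodes = x$n_nodes, n_edges = x$n_edges, ne_ratio = x$ne_ratio,
    n_edges_simple = x$n_edges_simple,
    counts = x$counts,
    component_sizes = x$component_sizes,
    largest_component_size = x$largest_component_size,
    degree_distribution = x$degree_distribution,
    neighborhood_connectivity = x$neighborhood_connectivity,
    path_length_distribution = x$path_length_distribution
  )
  txt <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                          na = "null", digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Largest connected component of a hetnet
#'
#' @param net A [hetnet()].
#' @return The induced sub-hetnet on the largest connected node set
#'   (components computed on the simplified graph; isolated nodes count as
#'   size-1 components). Ties are broken toward the component containing
#'   the lexicographically smallest node id. An empty network is returned
#'   unchanged.
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  if (!nrow(net$nodes)) return(net)
  g <- as_igraph(net, simplify = TRUE)
  comp <- igraph::components(g)
  max_size <- max(comp$csize)
  cand <- which(comp$csize == max_size)
  mins <- map_chr(cand, function(ci) {
    min(igraph::V(g)$name[comp$membership == ci])
  })
  pick <- cand[[which(mins == min(mins))[1]]]
  keep <- igraph::V(g)$name[comp$membership == pick]
  hetnet(
    nodes = filter(net$nodes, id %in% keep),
    edges = filter(net$edges, source %in% keep, target %in% keep),
    metagraph = net$metagraph
  )
}

#' Degree-proportional opacity for one node kind
#'
#' Drug squares in an indications network are drawn with opacity
#' proportional to degree so shared drugs appear darker. For every node of
#' `kind`, opacity = degree / max degree among that kind; isolated nodes
#' get 0 and a maximum-degree node gets 1.
#'
#' @param net A [hetnet()].
#' @param kind A node kind present in the network's metagraph.
#' @return A tibble with columns `id`, `degree`, `opacity` (empty if no
#'   nodes of that kind).
#' @export
degree_opacity <- function(net, kind) {
  stopifnot(inherits(net, "hetnet"))
  ids <- net$nodes$id[net$nodes$kind == kind]
  if (!length(ids)) {
    return(tibble(id = character(), degree = integer(), opacity = double()))
  }
  g <- as_igraph(net, simplify = TRUE)
  deg <- igraph::degree(g)[ids]
  mx <- max(deg)
  tibble(
    id = ids,
    degree = as.integer(deg),
    opacity = if (mx > 0) as.double(deg) / mx else 0
  ) |>
    arrange(id)
}
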