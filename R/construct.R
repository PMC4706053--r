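#' Build a hetnet by seed-and-expand traversal
#'
#' Networks start from seeds of one of three kinds (phenotype, gene or
#' drug). First-tier edge kinds are evaluated against the seed set: every
#' stored edge of a requested kind incident to a seed joins the network
#' together with its far endpoint. Second-tier kinds are then evaluated the
#' same way against the grown node set, which is how miRNAs, side effects
#' and protein interactions are layered onto a disease-gene core.
#'
#' @param store A [resource_store()].
#' @param seed_kind One of `"phenotype"`, `"gene"`, `"drug"`.
#' @param seeds Character vector of seed node ids (all must be registered
#'   under `seed_kind`). Seeds with no incident edges stay as isolated
#'   nodes.
#' @param tier1 Character vector of edge kinds expanded from the seeds.
#' @param tier2 Character vector of edge kinds expanded from the
#'   tier-1-grown node set. Default none.
#' @param tier2_closure Also keep tier-2-kind edges whose two endpoints were
#'   both added during expansion (e.g. protein interactions among the newly
#'   attached partners), so the added layer is internally connected.
#'   Default TRUE.
#' @param resources Optional character vector restricting edge tables that
#'   carry a `resource` column (e.g. `"gwas"`, `"ctd"`, `"omim"`) to those
#'   sources. NULL keeps everything.
#' @return A [hetnet()].
#' @export
build_hetnet <- function(store, seed_kind, seeds, tier1,
                         tier2 = character(), tier2_closure = TRUE,
                         resources = NULL) {
  stopifnot(inherits(store, "resource_store"))
  if (!seed_kind %in% c("phenotype", "gene", "drug")) {
    abort("seed_kind must be one of phenotype, gene, drug",
          class = "hetnet_parameter_error")
  }
  seeds <- unique(as.character(seeds))
  reg <- store$nodes$id[store$nodes$kind == seed_kind]
  unknown <- setdiff(seeds, reg)
  if (length(unknown)) {
    abort(paste0("seed id(s) not registered as ", seed_kind, ": ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "hetnet_lookup_error")
  }
  all_kinds <- store$metagraph$edge_kinds$kind
  bad <- setdiff(c(tier1, tier2), all_kinds)
  if (length(bad)) {
    abort(paste0("requested edge kind(s) not in metagraph: ",
                 paste(bad, collapse = ", ")),
          class = "hetnet_type_error")
  }

  kind_of <- setNames(store$nodes$kind, store$nodes$id)
  eps <- mg_endpoints(store$metagraph)

  store_edges <- function(k) {
    et <- store$edges[[k]]
    if (is.null(et)) {
      return(tibble(source = character(), target = character()))
    }
    if (!is.null(resources) && "resource" %in% names(et)) {
      et <- filter(et, resource %in% !!resources)
    }
    et
  }
  incident <- function(k, ids) {
    et <- store_edges(k)
    filter(et, source %in% ids | target %in% ids)
  }
  warn_unreachable <- function(kinds, present_kinds, phase) {
    for (k in kinds) {
      if (!any(eps[[k]] %in% present_kinds)) {
        warn(paste0(phase, " edge kind '", k,
                    "' touches no node kind present in the network"))
      }
    }
  }

  warn_unreachable(tier1, seed_kind, "tier-1")
  tier1_edges <- map(setNames(tier1, tier1), incident, ids = seeds)
  grown <- unique(c(seeds,
                    unlist(map(tier1_edges,
                               function(e) c(e$source, e$target)),
                           use.names = FALSE)))

  warn_unreachable(tier2, unique(unname(kind_of[grown])), "tier-2")
  tier2_edges <- map(setNames(tier2, tier2), incident, ids = grown)
  final_ids <- unique(c(grown,
                        unlist(map(tier2_edges,
                                   function(e) c(e$source, e$target)),
                               use.names = FALSE)))
  if (tier2_closure) {
    tier2_edges <- map(setNames(tier2, tier2), function(k) {
      store_edges(k) |> filter(source %in% final_ids, target %in% final_ids)
    })
  }

  net <- hetnet(nodes = filter(store$nodes, id %in% final_ids),
                metagraph = store$metagraph)
  for (k in tier1) {
    e <- tier1_edges[[k]]
    if (nrow(e)) net <- add_edges(net, mutate(e, kind = k))
  }
  for (k in tier2) {
    e <- tier2_edges[[k]]
    if (nrow(e)) net <- add_edges(net, mutate(e, kind = k))
  }
  net
}

#' Restrict a hetnet to genes shared by at least k phenotypes
#'
#' Extracts the sub-interactome associated with multiple diseases: genes
#' linked (by phenotype-gene edges) to at least `k` distinct phenotype
#' nodes are kept, together with all phenotype nodes they link to and every
#' edge whose two endpoints are kept — including protein-protein edges
#' between the retained genes. All other node kinds are dropped.
#'
#' @param net A [hetnet()] containing phenotype-gene edges.
#' @param k Minimum number of distinct phenotypes per retained gene
#'   (`k >= 1`).
#' @return The restricted [hetnet()].
#' @export
subnetwork_min_disease_degree <- function(net, k) {
  stopifnot(inherits(net, "hetnet"))
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    abort("k must be a single integer >= 1", class = "hetnet_parameter_error")
  }
  pg <- filter(net$edges, kind == "phenotype-gene")
  kind_of <- setNames(net$nodes$kind, net$nodes$id)
  pairs <- bind_rows(
    tibble(gene = pg$source, phen = pg$target),
    tibble(gene = pg$target, phen = pg$source)
  ) |>
    filter(kind_of[gene] == "gene", kind_of[phen] == "phenotype") |>
    distinct()
  keep_genes <- pairs |> count(gene) |> filter(n >= k) |> pull(gene)
  keep_phens <- unique(pairs$phen[pairs$gene %in% keep_genes])
  keep <- c(keep_genes, keep_phens)
  hetnet(
    nodes = filter(net$nodes, id %in% keep),
    edges = filter(net$edges, source %in% keep, target %in% keep),
    metagraph = net$metagraph
  )
}
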