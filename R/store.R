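#' Construct an in-memory resource store
#'
#' The store holds the post-filter, post-identifier-mapping resource data:
#' one node registry (all known nodes per kind) and one edge table per edge
#' kind. [build_hetnet()] queries it by seed-and-expand traversal.
#'
#' @param nodes Data frame with columns `id`, `kind`, optional `label`.
#' @param edges Named list of data frames, one per edge kind (names must be
#'   metagraph edge kinds), each with columns `source`, `target` plus
#'   attribute columns (e.g. `p_value`, `resource`, `frequency`).
#' @param metagraph The governing [metagraph].
#' @return An object of class `resource_store`.
#' @export
resource_store <- function(nodes, edges, metagraph = default_metagraph()) {
  nodes <- as_tibble(nodes)
  if (!all(c("id", "kind") %in% names(nodes))) {
    abort("store nodes need columns id, kind", class = "hetnet_schema_error")
  }
  nodes$id <- as.character(nodes$id)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  nodes <- distinct(nodes, id, kind, .keep_all = TRUE)
  bad <- setdiff(names(edges), metagraph$edge_kinds$kind)
  if (length(bad)) {
    abort(paste0("edge table(s) named after unknown edge kind(s): ",
                 paste(bad, collapse = ", ")),
          class = "hetnet_type_error")
  }
  edges <- map(edges, as_tibble)
  for (k in names(edges)) {
    if (!all(c("source", "target") %in% names(edges[[k]]))) {
      abort(paste0("edge table '", k, "' needs columns source, target"),
            class = "hetnet_schema_error")
    }
    unknown <- setdiff(unique(c(edges[[k]]$source, edges[[k]]$target)),
                       nodes$id)
    if (length(unknown)) {
      abort(paste0("edge table '", k, "' references unregistered id(s): ",
                   paste(head(unknown, 5), collapse = ", ")),
            class = "hetnet_missing_node")
    }
  }
  structure(list(nodes = nodes, edges = edges, metagraph = metagraph),
            class = "resource_store")
}

#' @export
print.resource_store <- function(x, ...) {
  cat(sprintf("<resource_store> %d registered nodes, %d edge tables\n",
              nrow(x$nodes), length(x$edges)))
  for (k in names(x$edges)) {
    cat(sprintf("  %-20s %d rows\n", k, nrow(x$edges[[k]])))
  }
  invisible(x)
}

#' Materialize the whole store as one hetnet
#'
#' @param store A [resource_store()].
#' @return A [hetnet()] containing every registered node and every stored
#'   edge.
#' @export
store_hetnet <- function(store) {
  stopifnot(inherits(store, "resource_store"))
  net <- hetnet(nodes = store$nodes, metagraph = store$metagraph)
  for (k in names(store$edges)) {
    et <- store$edges[[k]]
    if (nrow(et)) net <- add_edges(net, mutate(et, kind = k))
  }
  net
}

# map prefixed phenotype ids ("DOID:x", "OMIM:x", "MESH:x", "EFO:x") to
# canonical ids via the xref map; ambiguous rows are dropped with a warning
canonical_phenotype <- function(ids, xm) {
  pref <- sub(":.*$", "", ids)
  bare <- sub("^[^:]*:", "", ids)
  vocab <- dplyr::case_match(pref, "DOID" ~ "DO", "OMIM" ~ "OMIM",
                             "MESH" ~ "MeSH", "EFO" ~ "EFO",
                             .default = NA_character_)
  if (anyNA(vocab)) {
    abort(paste0("unrecognized phenotype id prefix in: ",
                 paste(head(unique(ids[is.na(vocab)]), 5), collapse = ", ")),
          class = "idmap_format_error")
  }
  src <- ifelse(vocab == "DO", ids, bare)
  res <- map_phenotype(xm, vocab, src)
  out <- res$canonical_id
  if (any(res$match == "ambiguous")) {
    warn(paste0("dropping ", sum(res$match == "ambiguous"),
                " phenotype id(s) with ambiguous cross-references"))
  }
  out
}

# resolve gene symbol column to "HGNC:<n>" ids; unresolved rows dropped
canonical_gene <- function(symbols, at) {
  res <- resolve_gene(at, symbols)
  n_bad <- sum(!res$match %in% c("current", "alias"))
  if (n_bad) {
    warn(paste0("dropping ", n_bad,
                " gene symbol(s) that are unresolvable or ambiguous"))
  }
  ifelse(res$match %in% c("current", "alias"),
         paste0("HGNC:", res$hgnc_id), NA_character_)
}

#' Load a resource directory into a store
#'
#' Runs the full ingestion pipeline described by a YAML configuration:
#' reads the disease / tissue / side-effect ontologies (rooting the tissue
#' ontology, by default at whole body, BTO:0001489), builds the gene alias
#' table and phenotype cross-reference map, applies the evidence and
#' p-value filters, merges GWAS loci into per-locus associations, infers
#' phenotype-tissue and side-effect-tissue edges by downward ontology
#' propagation of the manual high-level maps, resolves every identifier to
#' its canonical namespace, and registers all nodes.
#'
#' @param config Path to a YAML file (as written by [generate_fixtures()]),
#'   or an equivalent list. Relative paths resolve against the config file's
#'   directory.
#' @return A [resource_store()].
#' @export
load_resources <- function(config) {
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  } else {
    base <- config$base_dir %||% "."
  }
  res <- config$resources
  pth <- function(name) {
    p <- res[[name]]
    if (is.null(p)) abort(paste0("config lists no resource '", name, "'"),
                          class = "hetnet_schema_error")
    if (!grepl("^/", p)) p <- file.path(base, p)
    p
  }
  filters <- config$filters %||% list()
  p_thr <- filters$gwas_p_threshold %||% 1e-7
  gwas_one_based <- isTRUE((config$dialects %||% list())$gwas_one_based)
  tissue_root <- config$tissue_root %||% "BTO:0001489"

  disease_ont <- read_obo(pth("disease_obo"))
  tissue_ont <- read_obo(pth("tissue_obo"))
  if (tissue_root %in% tissue_ont$terms$id) {
    tissue_ont <- root_at(tissue_ont, tissue_root)
  }
  se_ont <- read_obo(pth("side_effect_obo"))

  at <- alias_table(readr::read_tsv(pth("aliases"), show_col_types = FALSE,
                                    progress = FALSE))
  xm <- xref_map(readr::read_tsv(pth("xrefs"), show_col_types = FALSE,
                                 progress = FALSE,
                                 col_types = readr::cols(.default = "c")))

  live <- function(ont) filter(ont$terms, !obsolete)
  nodes <- bind_rows(
    live(disease_ont) |> transmute(id, kind = "phenotype", label = name),
    at$records |> filter(status == "current") |>
      transmute(id = paste0("HGNC:", hgnc_id), kind = "gene",
                label = symbol),
    live(tissue_ont) |> transmute(id, kind = "tissue", label = name),
    live(se_ont) |> transmute(id, kind = "side_effect", label = name)
  )

  # GWAS: p filter, locus merge, one association per merged locus
  gwas <- read_resource_table(pth("gwas"), "gwas",
                              one_based = gwas_one_based) |>
    filter_gwas_pvalue(threshold = p_thr) |>
    merge_loci()
  gwas_edges <- tibble(
    source = canonical_phenotype(gwas$disease_id, xm),
    target = canonical_gene(gwas$primary_gene, at),
    p_value = gwas$p_value, resource = "gwas"
  )
  ctd <- read_resource_table(pth("ctd_dg"), "ctd_dg") |> filter_ctd_direct()
  ctd_edges <- tibble(
    source = canonical_phenotype(ctd$disease_id, xm),
    target = canonical_gene(ctd$gene, at), resource = "ctd"
  )
  omim <- read_resource_table(pth("omim"), "omim")
  omim_edges <- tibble(
    source = canonical_phenotype(omim$disease_id, xm),
    target = canonical_gene(omim$gene, at), resource = "omim"
  )
  pg <- bind_rows(gwas_edges, ctd_edges, omim_edges) |>
    filter(!is.na(source), !is.na(target))

  dg <- read_resource_table(pth("drug_gene"), "drug_gene")
  dg_edges <- tibble(source = dg$drug_id,
                     target = canonical_gene(dg$gene, at)) |>
    filter(!is.na(target))
  dd <- read_resource_table(pth("drug_disease"), "drug_disease")
  dd_edges <- tibble(source = dd$drug_id,
                     target = canonical_phenotype(dd$disease_id, xm)) |>
    filter(!is.na(target))
  dse <- read_resource_table(pth("drug_side_effect"), "drug_side_effect")
  dse_edges <- tibble(source = dse$drug_id, target = dse$se_id,
                      frequency = dse$frequency)
  gt <- read_resource_table(pth("gene_tissue"), "gene_tissue")
  gt_edges <- tibble(source = canonical_gene(gt$gene, at),
                     target = gt$tissue_id, expression = gt$expression) |>
    filter(!is.na(source), target %in% nodes$id)
  mg <- read_resource_table(pth("mirna_gene"), "mirna_gene")
  mg_edges <- tibble(source = mg$mirna,
                     target = canonical_gene(mg$gene, at)) |>
    filter(!is.na(target))
  ppi <- read_resource_table(pth("ppi"), "ppi")
  ppi_edges <- tibble(source = canonical_gene(ppi$gene_a, at),
                      target = canonical_gene(ppi$gene_b, at)) |>
    filter(!is.na(source), !is.na(target))

  # ontology inference: manual high-level maps propagated down is_a chains
  pt_manual <- readr::read_tsv(pth("disease_tissue_map"),
                               show_col_types = FALSE, progress = FALSE)
  pt <- propagate_annotations(disease_ont, pt_manual) |>
    filter(tissue_id %in% nodes$id,
           term_id %in% nodes$id[nodes$kind == "phenotype"])
  pt_edges <- tibble(source = pt$term_id, target = pt$tissue_id)
  st_manual <- readr::read_tsv(pth("side_effect_tissue_map"),
                               show_col_types = FALSE, progress = FALSE)
  st <- propagate_annotations(se_ont, st_manual) |>
    filter(tissue_id %in% nodes$id,
           term_id %in% nodes$id[nodes$kind == "side_effect"])
  st_edges <- tibble(source = st$term_id, target = st$tissue_id)

  # drugs, miRNAs and passthrough phenotypes are registered from the data
  drug_ids <- sort(unique(c(dg_edges$source, dd_edges$source,
                            dse_edges$source)))
  mirna_ids <- sort(unique(mg_edges$source))
  passthrough <- setdiff(unique(c(pg$source, dd_edges$target)),
                         nodes$id)
  nodes <- bind_rows(
    nodes,
    tibble(id = drug_ids, kind = "drug", label = drug_ids),
    tibble(id = mirna_ids, kind = "mirna", label = mirna_ids),
    tibble(id = passthrough, kind = "phenotype", label = passthrough)
  )

  resource_store(
    nodes = nodes,
    edges = list(
      "phenotype-gene" = pg,
      "phenotype-tissue" = pt_edges,
      "gene-tissue" = gt_edges,
      "drug-phenotype" = dd_edges,
      "drug-gene" = dg_edges,
      "drug-side_effect" = dse_edges,
      "side_effect-tissue" = st_edges,
      "gene-gene" = ppi_edges,
      "mirna-gene" = mg_edges
    )
  )
}
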