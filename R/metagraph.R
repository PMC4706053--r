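#' Node kinds of the default metagraph
#'
#' The six entity kinds a hetnet built by this package can contain:
#' phenotypes (diseases), genes (proteins), miRNAs, tissues, drugs and drug
#' side effects.
#'
#' @return A character vector of the six node-kind names.
#' @export
node_kinds <- function() {
  c("phenotype", "gene", "mirna", "tissue", "drug", "side_effect")
}

#' Construct a metagraph
#'
#' A metagraph is the schema-level graph whose nodes are entity kinds and
#' whose edges are the permitted interaction kinds. Instance networks
#' ([hetnet()]) type-check every edge against it. Metagraphs may be cyclic
#' and may contain self-kind edge kinds (e.g. protein-protein).
#'
#' @param node_kinds Character vector of unique node-kind names.
#' @param edge_kinds A data frame with columns `kind`, `kind_a`, `kind_b`:
#'   the edge-kind name and its two endpoint kinds (order immaterial).
#' @return An object of class `metagraph`.
#' @seealso [default_metagraph()]
#' @export
metagraph <- function(node_kinds, edge_kinds) {
  node_kinds <- as.character(node_kinds)
  if (anyDuplicated(node_kinds)) {
    abort("node kinds must be unique", class = "hetnet_error")
  }
  edge_kinds <- as_tibble(edge_kinds)
  need <- c("kind", "kind_a", "kind_b")
  if (!all(need %in% names(edge_kinds))) {
    abort("edge_kinds needs columns kind, kind_a, kind_b",
          class = "hetnet_schema_error")
  }
  edge_kinds <- edge_kinds[need]
  if (anyDuplicated(edge_kinds$kind)) {
    abort("edge kinds must be unique", class = "hetnet_error")
  }
  bad <- setdiff(c(edge_kinds$kind_a, edge_kinds$kind_b), node_kinds)
  if (length(bad)) {
    abort(paste0("edge-kind endpoints not registered as node kinds: ",
                 paste(unique(bad), collapse = ", ")),
          class = "hetnet_type_error")
  }
  structure(list(node_kinds = node_kinds, edge_kinds = edge_kinds),
            class = "metagraph")
}

#' The default six-kind / nine-kind metagraph
#'
#' Six node kinds (phenotype, gene, mirna, tissue, drug, side_effect) and
#' nine permitted edge kinds: phenotype-gene, phenotype-tissue, gene-tissue,
#' drug-phenotype, drug-gene, drug-side_effect, side_effect-tissue,
#' gene-gene (protein-protein, a self-kind edge) and mirna-gene.
#'
#' @return A `metagraph`.
#' @examples
#' mg <- default_metagraph()
#' length(mg$node_kinds)   # 6
#' nrow(mg$edge_kinds)     # 9
#' @export
default_metagraph <- function() {
  metagraph(
    node_kinds(),
    tibble(
      kind = c("phenotype-gene", "phenotype-tissue", "gene-tissue",
               "drug-phenotype", "drug-gene", "drug-side_effect",
               "side_effect-tissue", "gene-gene", "mirna-gene"),
      kind_a = c("phenotype", "phenotype", "gene", "drug", "drug", "drug",
                 "side_effect", "gene", "mirna"),
      kind_b = c("gene", "tissue", "tissue", "phenotype", "gene",
                 "side_effect", "tissue", "gene", "gene")
    )
  )
}

#' @export
print.metagraph <- function(x, ...) {
  cat("<metagraph> ", length(x$node_kinds), " node kinds, ",
      nrow(x$edge_kinds), " edge kinds\n", sep = "")
  cat("node kinds:", paste(x$node_kinds, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$edge_kinds))) {
    cat(sprintf("  %-20s %s -- %s\n", x$edge_kinds$kind[i],
                x$edge_kinds$kind_a[i], x$edge_kinds$kind_b[i]))
  }
  invisible(x)
}

# unordered endpoint-kind lookup: named list kind -> sorted c(kind_a, kind_b)
mg_endpoints <- function(mg) {
  setNames(
    map(seq_len(nrow(mg$edge_kinds)), function(i) {
      sort(c(mg$edge_kinds$kind_a[i], mg$edge_kinds$kind_b[i]))
    }),
    mg$edge_kinds$kind
  )
}

# the edge kind(s) linking two node kinds (unordered); character(0) if none
mg_kinds_between <- function(mg, kind_x, kind_y) {
  want <- sort(c(kind_x, kind_y))
  eps <- mg_endpoints(mg)
  names(eps)[map_lgl(eps, identical, want)]
}
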