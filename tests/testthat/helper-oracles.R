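# Independent brute-force oracles and random-instance generators. These are
# deliberately naive (matrix closures, all-pairs scans, per-base coverage)
# and never call the code paths they check.

# ---- ontology oracles ----------------------------------------------------

# random DAG ontology as OBO text + its adjacency; term i may have parents
# only among terms 1..i-1, so acyclicity holds by construction
random_dag_obo <- function(n_terms, p_parent = 0.8, p_second = 0.3) {
  ids <- sprintf("T%04d", seq_len(n_terms))
  parent_edges <- list()
  for (i in seq_len(n_terms)[-1]) {
    if (stats::runif(1) < p_parent) {
      ps <- ids[sample.int(i - 1, 1)]
      if (i > 2 && stats::runif(1) < p_second) {
        ps <- unique(c(ps, ids[sample.int(i - 1, 1)]))
      }
      parent_edges[[length(parent_edges) + 1]] <-
        data.frame(id = ids[i], parent = ps)
    }
  }
  parents <- if (length(parent_edges)) do.call(rbind, parent_edges)
    else data.frame(id = character(), parent = character())
  lines <- character()
  for (i in seq_len(n_terms)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: term ", i))
    for (p in parents$parent[parents$id == ids[i]]) {
      lines <- c(lines, paste0("is_a: ", p))
    }
    lines <- c(lines, "")
  }
  list(ids = ids, parents = parents, obo = lines)
}

# boolean-matrix transitive closure of the child relation (parent -> child)
oracle_closure_matrix <- function(ids, parents) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(parents)) {
    adj[cbind(parents$parent, parents$id)] <- TRUE  # parent row -> child col
  }
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# per-term propagation by explicit recursive ancestor walk and union
oracle_propagate <- function(ids, parents, manual) {
  pof <- split(parents$parent, parents$id)
  mof <- split(manual$tissue_id, manual$term_id)
  anc <- function(t, seen = character()) {
    for (p in setdiff(pof[[t]], seen)) {
      seen <- anc(p, c(seen, p))
    }
    seen
  }
  out <- list()
  for (t in ids) {
    tis <- sort(unique(unlist(mof[c(t, anc(t))], use.names = FALSE)))
    if (length(tis)) out[[t]] <- tis
  }
  out
}

# ---- interval oracles ----------------------------------------------------

# simple sort-and-sweep merge of one group's intervals (strict overlap)
oracle_sweep <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  res <- NULL
  for (i in seq_along(start)[-1]) {
    if (start[i] < me) {
      me <- max(me, end[i])
    } else {
      res <- rbind(res, c(ms, me))
      ms <- start[i]; me <- end[i]
    }
  }
  rbind(res, c(ms, me))
}

# per-base union length (0-based half-open coordinates)
oracle_union_length <- function(start, end) {
  covered <- logical(max(end))
  for (i in seq_along(start)) covered[(start[i] + 1):end[i]] <- TRUE
  sum(covered)
}

random_locus_table <- function(n_rows, n_diseases = 3, n_chroms = 2,
                               span = 1000) {
  start <- sample.int(span, n_rows, replace = TRUE) - 1L
  width <- sample(5:120, n_rows, replace = TRUE)
  tibble::tibble(
    disease_id = sprintf("DOID:%d", sample.int(n_diseases, n_rows,
                                               replace = TRUE)),
    chrom = as.character(sample.int(n_chroms, n_rows, replace = TRUE)),
    start = start, end = start + width,
    reported_gene = sprintf("G%03d", sample.int(50, n_rows, replace = TRUE)),
    p_value = 10^stats::runif(n_rows, -12, -2)
  )
}

# ---- graph oracles -------------------------------------------------------

random_bipartite_net <- function(n_d, n_g, n_e) {
  d <- sprintf("D%03d", seq_len(n_d))
  g <- sprintf("G%03d", seq_len(n_g))
  pairs <- unique(data.frame(
    source = sample(d, n_e, replace = TRUE),
    target = sample(g, n_e, replace = TRUE)))
  hetnet(
    nodes = rbind(data.frame(id = d, kind = "phenotype"),
                  data.frame(id = g, kind = "gene")),
    edges = cbind(pairs, kind = "phenotype-gene")
  )
}

# all-pairs shared-neighbor counts by explicit set intersection
oracle_projection <- function(net, min_shared) {
  e <- net$edges[net$edges$kind == "phenotype-gene", ]
  kind_of <- stats::setNames(net$nodes$kind, net$nodes$id)
  ph <- ifelse(kind_of[e$source] == "phenotype", e$source, e$target)
  gn <- ifelse(kind_of[e$source] == "phenotype", e$target, e$source)
  genes_of <- split(gn, ph)
  ds <- sort(net$nodes$id[net$nodes$kind == "phenotype"])
  out <- NULL
  for (i in seq_along(ds)) {
    for (j in seq_along(ds)) {
      if (i >= j) next
      w <- length(intersect(genes_of[[ds[i]]], genes_of[[ds[j]]]))
      if (w >= min_shared) {
        out <- rbind(out, data.frame(source = ds[i], target = ds[j],
                                     weight = w))
      }
    }
  }
  out
}

# connected components by naive label flooding over an edge list
oracle_components <- function(ids, src, dst) {
  lab <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(src)) {
      a <- src[i]; b <- dst[i]
      m <- min(lab[[a]], lab[[b]])
      if (lab[[a]] != m || lab[[b]] != m) {
        lab[[a]] <- m; lab[[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(ids, lab[ids])
}

# all-pairs shortest paths by Floyd-Warshall on a dense matrix
oracle_distances <- function(ids, src, dst) {
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  for (i in seq_along(src)) {
    if (src[i] != dst[i]) {
      d[src[i], dst[i]] <- 1
      d[dst[i], src[i]] <- 1
    }
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# random typed hetnet exercising several kinds, attrs and a self-loop
random_hetnet <- function(n_per_kind = 6, n_edges = 25) {
  mk <- function(kind, prefix) {
    data.frame(id = sprintf("%s%02d", prefix, seq_len(n_per_kind)),
               kind = kind)
  }
  nodes <- rbind(mk("phenotype", "DOID:"), mk("gene", "HGNC:"),
                 mk("drug", "DB"), mk("tissue", "BTO:"))
  mg <- default_metagraph()
  picks <- c("phenotype-gene", "drug-phenotype", "drug-gene", "gene-gene",
             "gene-tissue", "phenotype-tissue")
  rows <- list()
  for (i in seq_len(n_edges)) {
    k <- sample(picks, 1)
    ka <- mg$edge_kinds$kind_a[mg$edge_kinds$kind == k]
    kb <- mg$edge_kinds$kind_b[mg$edge_kinds$kind == k]
    rows[[i]] <- data.frame(
      source = sample(nodes$id[nodes$kind == ka], 1),
      target = sample(nodes$id[nodes$kind == kb], 1),
      kind = k,
      weight = sample(c(NA, 1:5), 1),
      p_value = ifelse(stats::runif(1) < 0.5, stats::runif(1), NA)
    )
  }
  hetnet(nodes = nodes, edges = do.call(rbind, rows))
}

# multiset signatures for round-trip comparisons
edge_signature <- function(net) {
  sort(paste(net$edges$source, net$edges$kind, net$edges$target, sep = "\t"))
}
node_signature <- function(net) {
  sort(paste(net$nodes$id, net$nodes$kind, sep = "\t"))
}
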