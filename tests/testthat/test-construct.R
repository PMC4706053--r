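# small deterministic store used across construction tests
demo_store <- function() {
  nodes <- tibble::tibble(
    id = c("D1", "D2", "G1", "G2", "G9", "DB1", "T1", "M1", "SE1"),
    kind = c("phenotype", "phenotype", "gene", "gene", "gene", "drug",
             "tissue", "mirna", "side_effect"))
  resource_store(nodes, list(
    "phenotype-gene" = tibble::tibble(source = c("D1", "D2"),
                                      target = c("G1", "G9")),
    "gene-gene" = tibble::tibble(source = c("G1", "G2"),
                                 target = c("G2", "G9")),
    "drug-phenotype" = tibble::tibble(source = "DB1", target = "D1"),
    "drug-side_effect" = tibble::tibble(source = "DB1", target = "SE1"),
    "mirna-gene" = tibble::tibble(source = "M1", target = "G9"),
    "phenotype-tissue" = tibble::tibble(source = "D2", target = "T1")
  ))
}

test_that("tier-1 expansion joins only edges incident to the seeds", {
  store <- demo_store()
  net <- build_hetnet(store, "phenotype", "D1", tier1 = "phenotype-gene")
  expect_setequal(net$nodes$id, c("D1", "G1"))
  expect_equal(nrow(net$edges), 1)
})

test_that("tier-2 attaches first-degree neighbors of the grown set", {
  store <- demo_store()
  net <- build_hetnet(store, "phenotype", "D1",
                      tier1 = "phenotype-gene", tier2 = "gene-gene")
  expect_setequal(net$nodes$id, c("D1", "G1", "G2"))
  expect_setequal(net$edges$kind, c("phenotype-gene", "gene-gene"))
  # closure keeps interactions among the newly attached partners
  tri <- resource_store(
    tibble::tibble(id = c("D1", "G1", "G2", "G3"),
                   kind = c("phenotype", "gene", "gene", "gene")),
    list("phenotype-gene" = tibble::tibble(source = "D1", target = "G1"),
         "gene-gene" = tibble::tibble(source = c("G1", "G1", "G2"),
                                      target = c("G2", "G3", "G3"))))
  with_closure <- build_hetnet(tri, "phenotype", "D1",
                               tier1 = "phenotype-gene",
                               tier2 = "gene-gene")
  expect_equal(sum(with_closure$edges$kind == "gene-gene"), 3)
  without <- build_hetnet(tri, "phenotype", "D1",
                          tier1 = "phenotype-gene", tier2 = "gene-gene",
                          tier2_closure = FALSE)
  expect_equal(sum(without$edges$kind == "gene-gene"), 2)
  expect_setequal(without$nodes$id, with_closure$nodes$id)
})

test_that("seeds with no incident edges remain isolated nodes", {
  store <- demo_store()
  net <- build_hetnet(store, "drug", "DB1", tier1 = "drug-gene")
  expect_equal(net$nodes$id, "DB1")
  expect_equal(nrow(net$edges), 0)
})

test_that("construction errors and warnings are specific", {
  store <- demo_store()
  expect_error(build_hetnet(store, "tissue", "T1", "gene-tissue"),
               class = "hetnet_parameter_error")
  expect_error(build_hetnet(store, "phenotype", "D99", "phenotype-gene"),
               class = "hetnet_lookup_error")
  expect_error(build_hetnet(store, "phenotype", "D1", "not-a-kind"),
               class = "hetnet_type_error")
  # a tier-1 kind touching no present node kind warns, not errors
  expect_warning(build_hetnet(store, "phenotype", "D1", "mirna-gene"),
                 "touches no node kind")
})

# independent two-phase set-algebra oracle over the full store
oracle_build <- function(store, seeds, tier1, tier2, closure = TRUE) {
  inc <- function(k, ids) {
    e <- store$edges[[k]]
    if (is.null(e)) return(e[0, ])
    e[e$source %in% ids | e$target %in% ids, ]
  }
  t1 <- lapply(tier1, inc, ids = seeds)
  grown <- unique(c(seeds, unlist(lapply(t1, function(e)
    c(e$source, e$target)))))
  t2 <- lapply(tier2, inc, ids = grown)
  final <- unique(c(grown, unlist(lapply(t2, function(e)
    c(e$source, e$target)))))
  if (closure) {
    t2 <- lapply(tier2, function(k) {
      e <- store$edges[[k]]
      if (is.null(e)) return(NULL)
      e[e$source %in% final & e$target %in% final, ]
    })
  }
  sig <- function(es, kinds) {
    unlist(mapply(function(e, k) {
      if (is.null(e) || !nrow(e)) return(character())
      paste(pmin(e$source, e$target), k, pmax(e$source, e$target))
    }, es, kinds, SIMPLIFY = FALSE))
  }
  list(nodes = sort(final),
       edges = sort(unique(c(sig(t1, tier1), sig(t2, tier2)))))
}

test_that("random builds equal the two-phase incidence oracle", {
  set.seed(51)
  for (rep in 1:15) {
    net_src <- random_hetnet(n_per_kind = 8, n_edges = 60)
    store <- resource_store(
      net_src$nodes,
      split(net_src$edges[c("source", "target")], net_src$edges$kind))
    seeds <- sample(store$nodes$id[store$nodes$kind == "phenotype"],
                    sample(1:3, 1))
    tier1 <- sample(c("phenotype-gene", "drug-phenotype",
                      "phenotype-tissue"), 2)
    tier2 <- sample(c("gene-gene", "drug-gene", "gene-tissue"), 2)
    got <- suppressWarnings(
      build_hetnet(store, "phenotype", seeds, tier1, tier2))
    want <- oracle_build(store, seeds, tier1, tier2)
    expect_setequal(got$nodes$id, want$nodes)
    expect_setequal(paste(got$edges$source, got$edges$kind,
                          got$edges$target), want$edges)
    # closure property: both endpoints of every edge are in the network
    expect_true(all(c(got$edges$source, got$edges$target) %in%
                      got$nodes$id))
  }
})

test_that("enlarging the request never shrinks the result", {
  set.seed(52)
  net_src <- random_hetnet(n_per_kind = 8, n_edges = 70)
  store <- resource_store(
    net_src$nodes,
    split(net_src$edges[c("source", "target")], net_src$edges$kind))
  seeds <- store$nodes$id[store$nodes$kind == "phenotype"][1:3]
  small <- build_hetnet(store, "phenotype", seeds, "phenotype-gene")
  bigger <- build_hetnet(store, "phenotype", seeds,
                         c("phenotype-gene", "drug-phenotype"),
                         tier2 = "gene-gene")
  expect_true(all(small$nodes$id %in% bigger$nodes$id))
  expect_true(all(paste(small$edges$source, small$edges$kind,
                        small$edges$target) %in%
                    paste(bigger$edges$source, bigger$edges$kind,
                          bigger$edges$target)))
  # determinism: identical request twice gives identical networks
  again <- build_hetnet(store, "phenotype", seeds,
                        c("phenotype-gene", "drug-phenotype"),
                        tier2 = "gene-gene")
  expect_identical(bigger$edges, again$edges)
  expect_identical(bigger$nodes, again$nodes)
})

test_that("min-disease-degree subnetwork keeps shared genes only", {
  nodes <- tibble::tibble(
    id = c("D1", "D2", "Gshared", "Gpriv", "Goff", "DB1"),
    kind = c("phenotype", "phenotype", "gene", "gene", "gene", "drug"))
  net <- hetnet(nodes, tibble::tibble(
    source = c("D1", "D2", "D1", "Gshared", "DB1"),
    target = c("Gshared", "Gshared", "Gpriv", "Gpriv", "D1"),
    kind = c("phenotype-gene", "phenotype-gene", "phenotype-gene",
             "gene-gene", "drug-phenotype")))
  sub <- subnetwork_min_disease_degree(net, 2)
  expect_setequal(sub$nodes$id, c("D1", "D2", "Gshared"))
  # drug node and the PPI to a dropped gene are gone
  expect_setequal(sub$edges$kind, "phenotype-gene")
  # k = 1 keeps any gene with a disease link (Goff has none)
  sub1 <- subnetwork_min_disease_degree(net, 1)
  expect_setequal(sub1$nodes$id, c("D1", "D2", "Gshared", "Gpriv"))
  # PPI between two kept genes is retained
  gg <- sub1$edges[sub1$edges$kind == "gene-gene", ]
  expect_equal(nrow(gg), 1)
  expect_error(subnetwork_min_disease_degree(net, 0),
               class = "hetnet_parameter_error")
})

test_that("retained genes equal the per-gene distinct-disease oracle", {
  set.seed(53)
  for (rep in 1:10) {
    net <- random_bipartite_net(sample(3:10, 1), sample(5:25, 1),
                                sample(10:60, 1))
    k <- sample(1:3, 1)
    sub <- subnetwork_min_disease_degree(net, k)
    # oracle: count distinct diseases per gene by scanning the edge list
    e <- net$edges
    gene_end <- ifelse(startsWith(e$source, "G"), e$source, e$target)
    dis_end <- ifelse(startsWith(e$source, "G"), e$target, e$source)
    per_gene <- tapply(dis_end, gene_end, function(x) length(unique(x)))
    want_genes <- names(per_gene)[per_gene >= k]
    expect_setequal(sub$nodes$id[sub$nodes$kind == "gene"], want_genes)
  }
})
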