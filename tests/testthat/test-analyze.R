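test_that("two diseases sharing three genes connect at min_shared 3", {
  nodes <- tibble::tibble(
    id = c("D1", "D2", "D3", "G1", "G2", "G3", "G4"),
    kind = c(rep("phenotype", 3), rep("gene", 4)))
  edges <- tibble::tibble(
    source = c("D1", "D1", "D1", "D2", "D2", "D2", "D3"),
    target = c("G1", "G2", "G3", "G1", "G2", "G3", "G4"),
    kind = "phenotype-gene")
  net <- hetnet(nodes, edges)
  sim <- similarity_projection(net, "phenotype", "gene", min_shared = 3)
  expect_equal(nrow(sim$edges), 1)
  expect_equal(sim$edges$weight, 3L)
  expect_setequal(c(sim$edges$source, sim$edges$target), c("D1", "D2"))
  # all phenotype nodes survive, connected or not
  expect_setequal(sim$nodes$id, c("D1", "D2", "D3"))
  # a single projected node yields one node and no edges
  single <- hetnet(nodes[c(1, 4), ], edges[1, ])
  s <- similarity_projection(single, "phenotype", "gene", 1)
  expect_equal(nrow(s$nodes), 1)
  expect_equal(nrow(s$edges), 0)
  expect_error(similarity_projection(net, "phenotype", "side_effect", 1),
               class = "hetnet_type_error")
})

test_that("projection equals the all-pairs intersection oracle", {
  set.seed(61)
  for (rep in 1:12) {
    net <- random_bipartite_net(sample(3:20, 1), sample(5:60, 1),
                                sample(10:150, 1))
    prev <- NULL
    for (th in 1:3) {
      sim <- similarity_projection(net, "phenotype", "gene", th)
      want <- oracle_projection(net, th)
      got <- sim$edges[c("source", "target", "weight")]
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_setequal(paste(got$source, got$target, got$weight),
                        paste(want$source, want$target, want$weight))
      }
      # raising the threshold never adds edges
      if (!is.null(prev)) {
        expect_true(all(paste(got$source, got$target) %in% prev))
      }
      prev <- paste(got$source, got$target)
      # no self-edges, canonical symmetric storage
      expect_true(all(got$source < got$target))
    }
  }
})

test_that("topology report reproduces the printed N/E worked example", {
  net <- sample_disease_gene_net(82, 1465, 2010, seed = 99)
  rep <- topology_report(net)
  expect_equal(rep$n_nodes, 1547)
  expect_equal(rep$n_edges, 2010)
  expect_equal(rep$ne_ratio, 0.77)
  # empty network: zero counts, absent ratio
  e <- topology_report(hetnet())
  expect_equal(e$n_nodes, 0)
  expect_true(is.na(e$ne_ratio))
})

test_that("components, degrees and path lengths match dense oracles", {
  set.seed(62)
  for (rep in 1:8) {
    net <- random_hetnet(n_per_kind = sample(4:8, 1),
                         n_edges = sample(10:50, 1))
    rpt <- topology_report(net)
    # oracle on the simplified edge list (drop loops, collapse multi-edges)
    e <- unique(net$edges[net$edges$source != net$edges$target,
                          c("source", "target")])
    comps <- oracle_components(net$nodes$id, e$source, e$target)
    expect_equal(sort(as.integer(lengths(comps)), decreasing = TRUE),
                 rpt$component_sizes)
    expect_equal(sum(rpt$component_sizes), rpt$n_nodes)
    # degree distribution sums to twice the simple edge count
    expect_equal(sum(rpt$degree_distribution$degree *
                       rpt$degree_distribution$n_nodes),
                 2 * rpt$n_edges_simple)
    deg <- table(factor(c(e$source, e$target), levels = net$nodes$id))
    expect_equal(
      rpt$degree_distribution,
      tibble::tibble(degree = as.integer(names(table(as.integer(deg)))),
                     n_nodes = as.integer(table(as.integer(deg)))))
    # shortest paths on the largest component vs Floyd-Warshall
    big <- comps[[which.max(lengths(comps))]]
    eb <- e[e$source %in% big & e$target %in% big, ]
    d <- oracle_distances(big, eb$source, eb$target)
    hist_want <- table(d[upper.tri(d)][is.finite(d[upper.tri(d)]) &
                                         d[upper.tri(d)] > 0])
    if (length(hist_want)) {
      expect_equal(rpt$path_length_distribution$n_pairs,
                   as.double(hist_want))
      expect_equal(rpt$path_length_distribution$distance,
                   as.integer(names(hist_want)))
    } else {
      expect_equal(nrow(rpt$path_length_distribution), 0)
    }
  }
})

test_that("neighborhood connectivity is mean neighbor degree by degree", {
  # path A-B-C: deg(A)=deg(C)=1, deg(B)=2
  net <- hetnet(
    tibble::tibble(id = c("A", "B", "C"), kind = "gene"),
    tibble::tibble(source = c("A", "B"), target = c("B", "C"),
                   kind = "gene-gene"))
  nc <- topology_report(net)$neighborhood_connectivity
  expect_equal(nc$mean_neighbor_degree[nc$degree == 1], 2)
  expect_equal(nc$mean_neighbor_degree[nc$degree == 2], 1)
})

test_that("largest component extraction matches the size oracle", {
  set.seed(63)
  for (rep in 1:8) {
    net <- random_hetnet(n_per_kind = sample(4:8, 1),
                         n_edges = sample(8:40, 1))
    e <- unique(net$edges[net$edges$source != net$edges$target,
                          c("source", "target")])
    comps <- oracle_components(net$nodes$id, e$source, e$target)
    lc <- largest_component(net)
    expect_equal(nrow(lc$nodes), max(lengths(comps)))
    # result is one of the maximum components, induced edges only
    expect_true(all(c(lc$edges$source, lc$edges$target) %in% lc$nodes$id))
  }
  # tie-break: two equal components, smallest lexicographic member wins
  net <- hetnet(
    tibble::tibble(id = c("A", "B", "Y", "Z"), kind = "gene"),
    tibble::tibble(source = c("A", "Y"), target = c("B", "Z"),
                   kind = "gene-gene"))
  expect_setequal(largest_component(net)$nodes$id, c("A", "B"))
  # connected network: identity
  con <- hetnet(tibble::tibble(id = c("A", "B"), kind = "gene"),
                tibble::tibble(source = "A", target = "B",
                               kind = "gene-gene"))
  expect_equal(largest_component(con)$nodes$id, con$nodes$id)
  expect_equal(nrow(largest_component(hetnet())$nodes), 0)
})

test_that("degree opacity is degree over the kind's maximum", {
  net <- hetnet(
    tibble::tibble(id = c("DB1", "DB2", "DB3", "D1", "D2", "D3", "D4"),
                   kind = rep(c("drug", "phenotype"), c(3, 4))),
    tibble::tibble(
      source = c("DB1", "DB1", "DB1", "DB1", "DB2", "DB2"),
      target = c("D1", "D2", "D3", "D4", "D1", "D2"),
      kind = "drug-phenotype"))
  op <- degree_opacity(net, "drug")
  expect_equal(op$opacity[op$id == "DB1"], 1.0)
  expect_equal(op$opacity[op$id == "DB2"], 0.5)
  expect_equal(op$opacity[op$id == "DB3"], 0.0)
  # all-equal degrees give all 1
  eq <- degree_opacity(net, "phenotype")
  expect_true(all(eq$opacity[eq$degree == max(eq$degree)] == 1))
  expect_equal(nrow(degree_opacity(net, "mirna")), 0)
  # direct recomputation oracle on a random network
  set.seed(64)
  rnet <- random_hetnet(6, 30)
  opg <- degree_opacity(rnet, "gene")
  e <- unique(rnet$edges[rnet$edges$source != rnet$edges$target,
                         c("source", "target")])
  deg <- table(factor(c(e$source, e$target), levels = rnet$nodes$id))
  gd <- as.integer(deg[opg$id])
  expect_equal(opg$opacity, if (max(gd) > 0) gd / max(gd) else gd * 0)
})

test_that("report serialization and summary methods are consistent", {
  net <- sample_disease_gene_net(20, 50, 80, seed = 7)
  rpt <- topology_report(net)
  gl <- glance(rpt)
  expect_equal(gl$n_nodes, 70)
  expect_equal(gl$ne_ratio, round(70 / 80, 2))
  js <- jsonlite::fromJSON(report_json(rpt))
  expect_equal(js$n_nodes, 70)
  expect_equal(js$ne_ratio, rpt$ne_ratio)
  td <- tidy(rpt)
  expect_true(all(c("degree", "n_nodes") %in% names(td)))
})
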