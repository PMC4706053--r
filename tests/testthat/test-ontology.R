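chain_obo <- c("[Term]", "id: A", "name: a", "is_a: B", "",
               "[Term]", "id: B", "name: b", "is_a: C", "",
               "[Term]", "id: C", "name: c")

test_that("OBO parsing recovers terms, parents, obsolescence and xrefs", {
  ont <- read_obo(chain_obo)
  expect_equal(nrow(ont$terms), 3)
  expect_equal(ont$parents$parent[ont$parents$id == "A"], "B")
  expect_equal(ont$parents$parent[ont$parents$id == "B"], "C")

  ont2 <- read_obo(c("[Term]", "id: X", "name: gone", "is_obsolete: true",
                     "", "[Term]", "id: Y", "name: here",
                     "xref: OMIM:123456"))
  expect_true(ont2$terms$obsolete[ont2$terms$id == "X"])
  expect_false(ont2$terms$obsolete[ont2$terms$id == "Y"])
  expect_equal(ont2$xrefs$xref, "OMIM:123456")

  # trailing is_a comments are stripped; unknown tags ignored
  ont3 <- read_obo(c("[Term]", "id: P", "name: p",
                     "def: \"something\" []", "",
                     "[Term]", "id: Q", "name: q", "is_a: P ! the parent"))
  expect_equal(ont3$parents$parent, "P")
})

test_that("OBO parse errors name dangling targets and reject cycles", {
  expect_error(read_obo(c("[Term]", "id: A", "is_a: NOPE")),
               "NOPE", class = "obo_parse_error")
  expect_error(read_obo(c("[Term]", "id: A", "is_a: B", "",
                          "[Term]", "id: B", "is_a: A")),
               class = "obo_cycle_error")
})

test_that("parsing a random DAG recovers the generator's adjacency", {
  set.seed(11)
  for (rep in 1:10) {
    dag <- random_dag_obo(sample(5:60, 1))
    ont <- read_obo(dag$obo)
    expect_setequal(ont$terms$id, dag$ids)
    got <- paste(ont$parents$id, ont$parents$parent)
    want <- paste(dag$parents$id, dag$parents$parent)
    expect_setequal(got, want)
  }
})

test_that("descendants and ancestors match the matrix-closure oracle", {
  set.seed(12)
  for (rep in 1:15) {
    dag <- random_dag_obo(sample(5:80, 1))
    ont <- read_obo(dag$obo)
    reach <- oracle_closure_matrix(dag$ids, dag$parents)
    for (t in sample(dag$ids, min(8, length(dag$ids)))) {
      expect_setequal(ont_descendants(ont, t),
                      dag$ids[reach[t, ]])
      expect_setequal(ont_ancestors(ont, t),
                      dag$ids[reach[, t]])
    }
  }
  # fixed tiny cases: chain and leaf
  ont <- read_obo(chain_obo)
  expect_setequal(ont_descendants(ont, "C"), c("A", "B"))
  expect_equal(ont_descendants(ont, "A"), character())
  expect_error(ont_descendants(ont, "Z"), class = "ontology_lookup_error")
})

test_that("rooting keeps exactly the reverse-reachable set", {
  ont <- read_obo(c("[Term]", "id: whole_body", "name: whole body", "",
                    "[Term]", "id: muscle", "is_a: whole_body", "",
                    "[Term]", "id: plant_tissue", "name: plant"))
  r <- root_at(ont, "whole_body")
  expect_setequal(r$terms$id, c("whole_body", "muscle"))
  expect_equal(r$root, "whole_body")

  # rooting at a leaf keeps only the leaf
  leaf <- root_at(ont, "muscle")
  expect_equal(leaf$terms$id, "muscle")
  expect_equal(nrow(leaf$parents), 0)

  expect_error(root_at(ont, "missing"), class = "ontology_lookup_error")

  set.seed(13)
  for (rep in 1:10) {
    dag <- random_dag_obo(sample(5:60, 1))
    ont <- read_obo(dag$obo)
    reach <- oracle_closure_matrix(dag$ids, dag$parents)
    r_id <- sample(dag$ids, 1)
    rooted <- root_at(ont, r_id)
    expect_setequal(rooted$terms$id, c(r_id, dag$ids[reach[r_id, ]]))
    expect_lte(nrow(rooted$terms), nrow(ont$terms))
    # every retained term reaches the root upward
    for (t in rooted$terms$id) {
      expect_true(t == r_id || r_id %in% ont_ancestors(rooted, t))
    }
  }
})

test_that("the connective-tissue worked example propagates to children", {
  ont <- read_obo(c("[Term]", "id: DOID:65", "name: connective tissue disease",
                    "", "[Term]", "id: DOID:123", "is_a: DOID:65"))
  manual <- data.frame(term_id = "DOID:65", tissue_id = "BTO:0000421")
  prop <- propagate_annotations(ont, manual)
  expect_equal(prop$tissue_id[prop$term_id == "DOID:123"], "BTO:0000421")
  # manual entry preserved verbatim
  expect_equal(prop$tissue_id[prop$term_id == "DOID:65"], "BTO:0000421")
})

test_that("propagation matches the ancestor-walk oracle on random DAGs", {
  set.seed(14)
  for (rep in 1:15) {
    dag <- random_dag_obo(sample(6:80, 1))
    ont <- read_obo(dag$obo)
    n_manual <- sample(1:4, 1)
    manual <- data.frame(
      term_id = sample(dag$ids, n_manual),
      tissue_id = sprintf("BTO:%03d", sample.int(6, n_manual,
                                                 replace = TRUE)))
    got <- propagate_annotations(ont, manual)
    want <- oracle_propagate(dag$ids, dag$parents, manual)
    got_l <- split(got$tissue_id, got$term_id)
    expect_equal(lapply(got_l, sort), want[names(got_l)])
    expect_setequal(names(got_l), names(want))
  }
})

test_that("propagation edge cases: empty map, unknown keys, diamond union", {
  ont <- read_obo(chain_obo)
  expect_equal(nrow(propagate_annotations(
    ont, data.frame(term_id = character(), tissue_id = character()))), 0)
  expect_error(
    propagate_annotations(ont, data.frame(term_id = "ZZ",
                                          tissue_id = "BTO:1")),
    "ZZ", class = "ontology_lookup_error")
  # diamond: two annotated ancestors, child takes the union
  diamond <- read_obo(c("[Term]", "id: top", "",
                        "[Term]", "id: L", "is_a: top", "",
                        "[Term]", "id: R", "is_a: top", "",
                        "[Term]", "id: bottom", "is_a: L", "is_a: R"))
  prop <- propagate_annotations(
    diamond, data.frame(term_id = c("L", "R"),
                        tissue_id = c("BTO:1", "BTO:2")))
  expect_setequal(prop$tissue_id[prop$term_id == "bottom"],
                  c("BTO:1", "BTO:2"))
  # downward only: top gains nothing
  expect_false("top" %in% prop$term_id)
})

test_that("propagation is idempotent and monotone down the hierarchy", {
  set.seed(15)
  for (rep in 1:8) {
    dag <- random_dag_obo(sample(6:50, 1))
    ont <- read_obo(dag$obo)
    manual <- data.frame(
      term_id = sample(dag$ids, 3),
      tissue_id = sprintf("BTO:%03d", sample.int(5, 3, replace = TRUE)))
    once <- propagate_annotations(ont, manual)
    twice <- propagate_annotations(ont, once |>
                                     dplyr::rename(term_id = term_id,
                                                   tissue_id = tissue_id))
    expect_equal(once, twice)
    # child annotation set contains each annotated parent's set
    ann <- split(once$tissue_id, once$term_id)
    for (i in seq_len(nrow(ont$parents))) {
      p <- ont$parents$parent[i]
      ch <- ont$parents$id[i]
      if (!is.null(ann[[p]])) {
        expect_true(all(ann[[p]] %in% ann[[ch]]))
      }
    }
  }
})

test_that("obsolete terms gain no inferred annotations", {
  ont <- read_obo(c("[Term]", "id: root", "",
                    "[Term]", "id: dead", "is_a: root",
                    "is_obsolete: true"))
  prop <- propagate_annotations(
    ont, data.frame(term_id = "root", tissue_id = "BTO:9"))
  expect_false("dead" %in% prop$term_id)
})
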