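#' Specification for the synthetic resource directory
#'
#' Describes the shape of a complete synthetic resource set: three OBO
#' ontologies (disease, tissue, side effect), gene alias and phenotype
#' cross-reference tables, manual high-level tissue maps and the nine edge
#' tables. A single integer seed controls all randomness. Defaults give a
#' small but fully featured data set: every filter has rows on both sides,
#' the GWAS table contains overlapping loci, and the disease ontology
#' always embeds connective tissue disease (DOID:65) with two descendant
#' terms manually mapped to connective tissue (BTO:0000421), so the
#' canonical propagation example is always exercised.
#'
#' @param seed RNG seed (integer).
#' @param n_phenotype,n_tissue,n_side_effect Ontology sizes (non-obsolete
#'   terms; the tissue count is the animal portion under whole body).
#' @param n_gene,n_mirna,n_drug Entity counts.
#' @param n_obsolete Obsolete terms appended to the disease and side-effect
#'   ontologies.
#' @param p_extra_parent Probability that an ontology term receives a second
#'   parent (making the hierarchy a DAG rather than a tree).
#' @param frac_outdated,frac_synonym Fractions of genes that also carry an
#'   outdated symbol / a synonym in the alias table.
#' @param frac_xref Fraction of disease terms cross-referenced to OMIM and
#'   MeSH.
#' @param n_efo_map Disease terms additionally mapped from EFO (these ids
#'   are what the GWAS table uses).
#' @param n_gwas GWAS rows (pre-filter); coordinates are kept below
#'   `gwas_span` so ground truth can use a per-base union.
#' @param gwas_span,gwas_min_width,gwas_max_width Locus coordinate ranges.
#' @param gwas_log10p_range Range of log10 p-values (uniform), straddling
#'   the default 1e-7 threshold.
#' @param n_ctd_dg CTD disease-gene rows.
#' @param ctd_direct_frac Fraction of CTD rows with direct
#'   "marker/mechanism" evidence (the rest are "therapeutic").
#' @param frac_unmapped_mesh Fraction of CTD rows whose MeSH disease id has
#'   no DO cross-reference (these become passthrough phenotype nodes).
#' @param n_omim,n_drug_gene,n_drug_disease,n_drug_side_effect,n_gene_tissue,n_mirna_gene,n_ppi
#'   Row counts of the remaining edge tables.
#' @param n_disease_tissue_manual,n_se_tissue_manual High-level terms
#'   manually mapped to tissues.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_phenotype = 40, n_tissue = 25, n_side_effect = 18,
                         n_gene = 150, n_mirna = 12, n_drug = 20,
                         n_obsolete = 3, p_extra_parent = 0.15,
                         frac_outdated = 0.2, frac_synonym = 0.2,
                         frac_xref = 0.5, n_efo_map = 10,
                         n_gwas = 120, gwas_span = 4500,
                         gwas_min_width = 50, gwas_max_width = 300,
                         gwas_log10p_range = c(-12, -4),
                         n_ctd_dg = 100, ctd_direct_frac = 0.6,
                         frac_unmapped_mesh = 0.25,
                         n_omim = 60, n_drug_gene = 50, n_drug_disease = 60,
                         n_drug_side_effect = 40, n_gene_tissue = 200,
                         n_mirna_gene = 40, n_ppi = 250,
                         n_disease_tissue_manual = 6,
                         n_se_tissue_manual = 5) {
  spec <- as.list(environment())
  counts <- spec[grep("^n_", names(spec))]
  if (any(unlist(counts) < 0)) {
    abort("fixture counts must be >= 0", class = "hetnet_parameter_error")
  }
  probs <- spec[c("p_extra_parent", "frac_outdated", "frac_synonym",
                  "frac_xref", "ctd_direct_frac", "frac_unmapped_mesh")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    abort("fixture probabilities must lie in [0, 1]",
          class = "hetnet_parameter_error")
  }
  if (spec$n_phenotype < 4 || spec$n_tissue < 3) {
    abort("need n_phenotype >= 4 and n_tissue >= 3 to embed the worked
           propagation example", class = "hetnet_parameter_error")
  }
  structure(spec, class = "fixture_spec")
}

# ---- generator-internal brute-force helpers (ground truth only) ----------

# ancestor set by naive recursive walk over a parent list
bf_ancestors <- function(parents_of, term) {
  out <- character()
  walk_up <- function(t) {
    for (p in parents_of[[t]] %||% character()) {
      if (!p %in% out) {
        out <<- c(out, p)
        walk_up(p)
      }
    }
  }
  walk_up(term)
  out
}

# downward propagation closure via per-term ancestor walks
bf_propagation <- function(terms, parents_of, manual_of, obsolete_ids) {
  res <- list()
  for (t in terms) {
    tissues <- unique(unlist(
      manual_of[c(t, bf_ancestors(parents_of, t))], use.names = FALSE))
    if (t %in% obsolete_ids) tissues <- manual_of[[t]] %||% character()
    if (length(tissues)) res[[t]] <- sort(tissues)
  }
  res
}

# merged loci by per-base coverage; returns per (disease, chrom) runs with
# primary gene chosen by min p then lexicographic symbol
bf_merge_loci <- function(rows) {
  out <- list()
  for (grp in split(rows, paste(rows$disease_id, rows$chrom, sep = "\r"))) {
    span <- max(grp$end)
    covered <- logical(span)
    for (i in seq_len(nrow(grp))) {
      covered[(grp$start[i] + 1):grp$end[i]] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    for (j in which(r$values)) {
      s <- starts[j]; e <- ends[j]
      members <- grp[grp$start >= s & grp$end <= e, ]
      best_p <- min(members$p_value)
      gene <- sort(members$hgnc_symbol_resolved[members$p_value == best_p])[1]
      out[[length(out) + 1]] <- tibble(
        disease_id = grp$disease_id[1], chrom = grp$chrom[1],
        start = s, end = e, primary_gene = gene, p_value = best_p)
    }
  }
  if (!length(out)) {
    return(tibble(disease_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  primary_gene = character(), p_value = double()))
  }
  arrange(list_rbind(out), disease_id, chrom, start)
}

# undirected canonical pair strings for dedup tallies
bf_pairs <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

obo_lines <- function(ont, header = "format-version: 1.2") {
  lines <- header
  pof <- split(ont$parents$parent, ont$parents$id)
  xof <- split(ont$xrefs$xref, ont$xrefs$id)
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    lines <- c(lines, "", "[Term]", paste0("id: ", id),
               paste0("name: ", ont$terms$name[i]))
    for (p in pof[[id]] %||% character()) {
      lines <- c(lines, paste0("is_a: ", p, " ! parent term"))
    }
    for (x in xof[[id]] %||% character()) {
      lines <- c(lines, paste0("xref: ", x))
    }
    if (ont$terms$obsolete[i]) lines <- c(lines, "is_obsolete: true")
  }
  lines
}

# random rooted DAG ontology: term 1 is the root; term i>1 gets one parent
# among earlier terms and possibly a second
gen_ont_tbl <- function(ids, names, p_extra_parent, forced = NULL) {
  n <- length(ids)
  parents <- list()
  for (i in 2:n) {
    if (!is.null(forced) && ids[i] %in% names(forced)) {
      ps <- forced[[ids[i]]]
    } else {
      ps <- ids[sample.int(i - 1, 1)]
      if (stats::runif(1) < p_extra_parent && i > 2) {
        extra <- ids[sample.int(i - 1, 1)]
        if (!extra %in% ps) ps <- c(ps, extra)
      }
    }
    parents[[length(parents) + 1]] <- tibble(id = ids[i], parent = ps)
  }
  list(
    terms = tibble(id = ids, name = names, obsolete = FALSE),
    parents = list_rbind(parents),
    xrefs = tibble(id = character(), xref = character())
  )
}

#' Generate the synthetic resource directory
#'
#' Writes every input the ingestion pipeline consumes — three OBO files,
#' the manual tissue maps, alias and cross-reference tables, the nine edge
#' tables and a ready-to-use `resources.yaml` — plus `manifest.json`
#' recording the file roster and a ground-truth block. All ground-truth
#' numbers (filter survivor counts, the propagation closure, merged-locus
#' tables, expected node/edge counts of the canonical full build, expected
#' similarity-projection edge counts) are computed inside the generator by
#' naive brute force (per-row scans, recursive ancestor walks, per-base
#' interval coverage), independently of the package's analysis code, so
#' they can serve as an oracle for end-to-end tests.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return The manifest, invisibly (a list with `seed`, `files`,
#'   `ground_truth`).
#' @export
generate_fixtures <- function(spec = fixture_spec(), dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)

  # ---- disease ontology (DOID-like), with the embedded worked example ----
  n_d <- spec$n_phenotype
  d_ids <- c("DOID:4", "DOID:65",
             sprintf("DOID:%d", sample(1000:99999, n_d - 2)))
  d_names <- c("disease", "connective tissue disease",
               sprintf("disease term %d", seq_len(n_d - 2)))
  forced <- list("DOID:65" = "DOID:4")
  forced[[d_ids[3]]] <- "DOID:65"   # two descendants of DOID:65
  forced[[d_ids[4]]] <- "DOID:65"
  dis <- gen_ont_tbl(d_ids, d_names, spec$p_extra_parent, forced)
  if (spec$n_obsolete > 0) {
    obs <- tibble(id = sprintf("DOID:obs%02d", seq_len(spec$n_obsolete)),
                  name = sprintf("obsolete disease %d",
                                 seq_len(spec$n_obsolete)),
                  obsolete = TRUE)
    dis$terms <- bind_rows(dis$terms, obs)
  }
  live_d <- dis$terms$id[!dis$terms$obsolete]

  # cross-references: a fraction of live terms get OMIM and MeSH xrefs
  n_x <- round(spec$frac_xref * length(live_d))
  xref_terms <- sample(live_d, n_x)
  omim_ids <- sprintf("%06d", sample(100000:999999, n_x))
  mesh_ids <- sprintf("D%06d", sample(1:99999, n_x))
  dis$xrefs <- bind_rows(
    tibble(id = xref_terms, xref = paste0("OMIM:", omim_ids)),
    tibble(id = xref_terms, xref = paste0("MESH:", mesh_ids))
  )
  efo_terms <- sample(live_d, min(spec$n_efo_map, length(live_d)))
  efo_ids <- sprintf("EFO:%07d", sample(1:9999999, length(efo_terms)))
  xref_tbl <- bind_rows(
    tibble(vocab = "OMIM", source_id = omim_ids, do_id = xref_terms),
    tibble(vocab = "MeSH", source_id = mesh_ids, do_id = xref_terms),
    tibble(vocab = "EFO", source_id = sub("^EFO:", "", efo_ids),
           do_id = efo_terms)
  )

  # ---- tissue ontology: animal part under whole body + plant branch ------
  n_t <- spec$n_tissue
  t_ids <- c("BTO:0001489", "BTO:0000421",
             sprintf("BTO:%07d", sample(setdiff(1000:8999999, 1489),
                                        n_t - 2)))
  t_names <- c("whole body", "connective tissue",
               sprintf("tissue %d", seq_len(n_t - 2)))
  tis <- gen_ont_tbl(t_ids, t_names, spec$p_extra_parent,
                     forced = list("BTO:0000421" = "BTO:0001489"))
  plant_ids <- sprintf("BTO:9%06d", seq_len(4))
  tis$terms <- bind_rows(
    tis$terms,
    tibble(id = plant_ids,
           name = c("plant tissue", sprintf("plant part %d", 1:3)),
           obsolete = FALSE))
  tis$parents <- bind_rows(
    tis$parents, tibble(id = plant_ids[-1], parent = plant_ids[1]))
  animal_t <- t_ids                        # reachable from whole body

  # ---- side-effect ontology (UMLS-style ids) -----------------------------
  n_s <- spec$n_side_effect
  s_ids <- sprintf("C%07d", sample(1:9999999, n_s))
  se <- gen_ont_tbl(s_ids, sprintf("side effect %d", seq_len(n_s)),
                    spec$p_extra_parent)
  if (spec$n_obsolete > 0) {
    se$terms <- bind_rows(
      se$terms,
      tibble(id = sprintf("C999990%d", seq_len(spec$n_obsolete)),
             name = sprintf("obsolete effect %d", seq_len(spec$n_obsolete)),
             obsolete = TRUE))
  }
  live_s <- se$terms$id[!se$terms$obsolete]

  # ---- genes and aliases -------------------------------------------------
  n_g <- spec$n_gene
  hgnc <- sort(sample(1:90000, n_g))
  symbols <- sprintf("GN%04d", seq_len(n_g))
  alias_tbl <- tibble(symbol = symbols, hgnc_id = hgnc, status = "current")
  has_old <- stats::runif(n_g) < spec$frac_outdated
  has_syn <- stats::runif(n_g) < spec$frac_synonym
  alias_tbl <- bind_rows(
    alias_tbl,
    tibble(symbol = paste0("OLD_", symbols[has_old]),
           hgnc_id = hgnc[has_old], status = "outdated"),
    tibble(symbol = paste0("SYN_", symbols[has_syn]),
           hgnc_id = hgnc[has_syn], status = "synonym")
  )
  # per-gene: the symbol an edge table is allowed to use, plus the truth
  usable <- tibble(
    symbol = c(symbols, paste0("OLD_", symbols[has_old]),
               paste0("SYN_", symbols[has_syn])),
    hgnc_id = c(hgnc, hgnc[has_old], hgnc[has_syn])
  )
  pick_gene_symbols <- function(n) {
    i <- sample.int(nrow(usable), n, replace = TRUE)
    usable[i, ]
  }
  gene_node <- function(hgnc_id) paste0("HGNC:", hgnc_id)

  # ---- drugs and miRNAs --------------------------------------------------
  drug_ids <- sprintf("DB%05d", sample(1:99999, spec$n_drug))
  mirna_ids <- sprintf("hsa-miR-%d", sample(10:9999, spec$n_mirna))

  # ---- manual tissue maps ------------------------------------------------
  with_children_d <- unique(dis$parents$parent)
  hi_d <- intersect(with_children_d, live_d)
  manual_d_terms <- unique(c("DOID:65",
                             sample(hi_d, min(spec$n_disease_tissue_manual,
                                              length(hi_d)))))
  manual_d <- bind_rows(
    tibble(term_id = "DOID:65", tissue_id = "BTO:0000421"),
    list_rbind(map(setdiff(manual_d_terms, "DOID:65"), function(t) {
      tibble(term_id = t,
             tissue_id = sample(animal_t, sample(1:2, 1)))
    }))
  ) |> distinct()
  hi_s <- intersect(unique(se$parents$parent), live_s)
  manual_s_terms <- sample(hi_s, min(spec$n_se_tissue_manual, length(hi_s)))
  manual_s <- list_rbind(map(manual_s_terms, function(t) {
    tibble(term_id = t, tissue_id = sample(animal_t, sample(1:2, 1)))
  })) %||% tibble(term_id = character(), tissue_id = character())

  # ---- GWAS table (EFO disease ids, overlapping loci) --------------------
  gw_n <- spec$n_gwas
  gw_dis <- sample(efo_ids, gw_n, replace = TRUE)
  gw_chrom <- sample(c("1", "2", "3"), gw_n, replace = TRUE)
  gw_start <- sample.int(spec$gwas_span, gw_n, replace = TRUE) - 1L
  gw_width <- sample(seq(spec$gwas_min_width, spec$gwas_max_width), gw_n,
                     replace = TRUE)
  gw_genes <- pick_gene_symbols(gw_n)
  gw_p <- 10^stats::runif(gw_n, spec$gwas_log10p_range[1],
                          spec$gwas_log10p_range[2])
  gwas_tbl <- tibble(
    disease_id = gw_dis, chrom = gw_chrom, start = gw_start,
    end = gw_start + gw_width, reported_gene = gw_genes$symbol,
    p_value = gw_p
  )

  # ---- CTD disease-gene (MeSH ids; some unmapped; mixed evidence) --------
  ctd_n <- spec$n_ctd_dg
  unmapped_pool <- sprintf("D9%05d", sample(1:99999, 10))
  use_unmapped <- stats::runif(ctd_n) < spec$frac_unmapped_mesh
  ctd_dis <- ifelse(use_unmapped,
                    paste0("MESH:", sample(unmapped_pool, ctd_n,
                                           replace = TRUE)),
                    paste0("MESH:", sample(mesh_ids, ctd_n, replace = TRUE)))
  ctd_genes <- pick_gene_symbols(ctd_n)
  ctd_ev <- ifelse(stats::runif(ctd_n) < spec$ctd_direct_frac,
                   "marker/mechanism", "therapeutic")
  ctd_tbl <- tibble(disease_id = ctd_dis, gene = ctd_genes$symbol,
                    evidence = ctd_ev)

  # ---- OMIM, drug and remaining tables -----------------------------------
  om_n <- spec$n_omim
  om_dis <- paste0("OMIM:", sample(omim_ids, om_n, replace = TRUE))
  om_genes <- pick_gene_symbols(om_n)
  omim_tbl <- tibble(disease_id = om_dis, gene = om_genes$symbol)

  dg_genes <- pick_gene_symbols(spec$n_drug_gene)
  drug_gene_tbl <- tibble(
    drug_id = sample(drug_ids, spec$n_drug_gene, replace = TRUE),
    gene = dg_genes$symbol)
  drug_disease_tbl <- tibble(
    drug_id = sample(drug_ids, spec$n_drug_disease, replace = TRUE),
    disease_id = sample(live_d, spec$n_drug_disease, replace = TRUE))
  drug_se_tbl <- tibble(
    drug_id = sample(drug_ids, spec$n_drug_side_effect, replace = TRUE),
    se_id = sample(live_s, spec$n_drug_side_effect, replace = TRUE),
    frequency = round(stats::runif(spec$n_drug_side_effect), 3))
  gt_genes <- pick_gene_symbols(spec$n_gene_tissue)
  gene_tissue_tbl <- tibble(
    gene = gt_genes$symbol,
    tissue_id = sample(animal_t, spec$n_gene_tissue, replace = TRUE),
    expression = round(stats::rlnorm(spec$n_gene_tissue, 3, 1), 2))
  mg_genes <- pick_gene_symbols(spec$n_mirna_gene)
  mirna_gene_tbl <- tibble(
    mirna = sample(mirna_ids, spec$n_mirna_gene, replace = TRUE),
    gene = mg_genes$symbol)
  ppi_a <- pick_gene_symbols(spec$n_ppi)
  ppi_b <- pick_gene_symbols(spec$n_ppi)
  ppi_tbl <- tibble(gene_a = ppi_a$symbol, gene_b = ppi_b$symbol)

  # ---- write files -------------------------------------------------------
  files <- list(
    disease_obo = "disease.obo", tissue_obo = "tissue.obo",
    side_effect_obo = "side_effect.obo",
    disease_tissue_map = "disease_tissue.tsv",
    side_effect_tissue_map = "side_effect_tissue.tsv",
    aliases = "aliases.tsv", xrefs = "xrefs.tsv",
    gwas = "gwas.tsv", ctd_dg = "ctd_dg.tsv", omim = "omim.tsv",
    drug_gene = "drug_gene.tsv", drug_disease = "drug_disease.tsv",
    drug_side_effect = "drug_side_effect.tsv",
    gene_tissue = "gene_tissue.tsv", mirna_gene = "mirna_gene.tsv",
    ppi = "ppi.tsv"
  )
  p <- function(f) file.path(dir, f)
  writeLines(obo_lines(dis), p(files$disease_obo))
  writeLines(obo_lines(tis), p(files$tissue_obo))
  writeLines(obo_lines(se), p(files$side_effect_obo))
  readr::write_tsv(manual_d, p(files$disease_tissue_map), progress = FALSE)
  readr::write_tsv(manual_s, p(files$side_effect_tissue_map),
                   progress = FALSE)
  readr::write_tsv(alias_tbl, p(files$aliases), progress = FALSE)
  readr::write_tsv(xref_tbl, p(files$xrefs), progress = FALSE)
  readr::write_tsv(gwas_tbl, p(files$gwas), progress = FALSE)
  readr::write_tsv(ctd_tbl, p(files$ctd_dg), progress = FALSE)
  readr::write_tsv(omim_tbl, p(files$omim), progress = FALSE)
  readr::write_tsv(drug_gene_tbl, p(files$drug_gene), progress = FALSE)
  readr::write_tsv(drug_disease_tbl, p(files$drug_disease),
                   progress = FALSE)
  readr::write_tsv(drug_se_tbl, p(files$drug_side_effect), progress = FALSE)
  readr::write_tsv(gene_tissue_tbl, p(files$gene_tissue), progress = FALSE)
  readr::write_tsv(mirna_gene_tbl, p(files$mirna_gene), progress = FALSE)
  readr::write_tsv(ppi_tbl, p(files$ppi), progress = FALSE)
  config <- list(
    resources = files,
    filters = list(gwas_p_threshold = 1e-7, min_shared = 3),
    dialects = list(gwas_one_based = FALSE),
    tissue_root = "BTO:0001489"
  )
  yaml::write_yaml(config, p("resources.yaml"))

  # ---- ground truth by brute force ---------------------------------------
  symbol2hgnc <- setNames(usable$hgnc_id, usable$symbol)
  efo2do <- setNames(efo_terms, efo_ids)
  mesh2do <- setNames(xref_terms, paste0("MESH:", mesh_ids))
  omim2do <- setNames(xref_terms, paste0("OMIM:", omim_ids))
  map_dis <- function(ids) {
    out <- character(length(ids))
    for (i in seq_along(ids)) {
      id <- ids[i]
      out[i] <- if (id %in% names(efo2do)) efo2do[[id]]
        else if (id %in% names(mesh2do)) mesh2do[[id]]
        else if (id %in% names(omim2do)) omim2do[[id]]
        else id                       # DOID or unmapped passthrough
    }
    out
  }

  gwas_pass <- gwas_tbl[gwas_tbl$p_value <= 1e-7, ]
  gwas_pass$hgnc_symbol_resolved <- sprintf(
    "HGNC:%d", symbol2hgnc[gwas_pass$reported_gene])
  merged <- bf_merge_loci(gwas_pass)
  gwas_pg <- unique(bf_pairs(map_dis(merged$disease_id),
                             merged$primary_gene))

  ctd_direct <- ctd_tbl[ctd_tbl$evidence == "marker/mechanism", ]
  ctd_pg <- unique(bf_pairs(map_dis(ctd_direct$disease_id),
                            sprintf("HGNC:%d",
                                    symbol2hgnc[ctd_direct$gene])))
  omim_pg <- unique(bf_pairs(map_dis(omim_tbl$disease_id),
                             sprintf("HGNC:%d",
                                     symbol2hgnc[omim_tbl$gene])))
  pg_pairs <- unique(c(gwas_pg, ctd_pg, omim_pg))

  parents_d <- split(dis$parents$parent, dis$parents$id)
  manual_d_of <- split(manual_d$tissue_id, manual_d$term_id)
  obsolete_d <- dis$terms$id[dis$terms$obsolete]
  prop_d <- bf_propagation(dis$terms$id, parents_d, manual_d_of, obsolete_d)
  prop_d <- prop_d[setdiff(names(prop_d), obsolete_d)]
  pt_pairs <- sort(unlist(imap(prop_d, function(ts, t) {
    paste(t, ts, sep = "\r")
  }), use.names = FALSE))

  parents_s <- split(se$parents$parent, se$parents$id)
  manual_s_of <- split(manual_s$tissue_id, manual_s$term_id)
  obsolete_s <- se$terms$id[se$terms$obsolete]
  prop_s <- bf_propagation(se$terms$id, parents_s, manual_s_of, obsolete_s)
  prop_s <- prop_s[setdiff(names(prop_s), obsolete_s)]
  st_pairs <- sort(unlist(imap(prop_s, function(ts, t) {
    paste(t, ts, sep = "\r")
  }), use.names = FALSE))

  dd_pairs <- unique(bf_pairs(drug_disease_tbl$drug_id,
                              drug_disease_tbl$disease_id))
  dg_pairs <- unique(bf_pairs(
    drug_gene_tbl$drug_id,
    sprintf("HGNC:%d", symbol2hgnc[drug_gene_tbl$gene])))
  dse_pairs <- unique(bf_pairs(drug_se_tbl$drug_id, drug_se_tbl$se_id))
  gt_pairs <- unique(bf_pairs(
    sprintf("HGNC:%d", symbol2hgnc[gene_tissue_tbl$gene]),
    gene_tissue_tbl$tissue_id))
  mgp <- unique(bf_pairs(
    mirna_gene_tbl$mirna,
    sprintf("HGNC:%d", symbol2hgnc[mirna_gene_tbl$gene])))
  ppi_pairs <- unique(bf_pairs(
    sprintf("HGNC:%d", symbol2hgnc[ppi_tbl$gene_a]),
    sprintf("HGNC:%d", symbol2hgnc[ppi_tbl$gene_b])))

  passthrough <- setdiff(
    map_dis(c(ctd_direct$disease_id, omim_tbl$disease_id,
              merged$disease_id)),
    live_d)
  phen_registry <- unique(c(live_d, passthrough))
  tissue_registry <- animal_t
  gene_registry <- sprintf("HGNC:%d", hgnc)
  used_drugs <- unique(c(drug_gene_tbl$drug_id, drug_disease_tbl$drug_id,
                         drug_se_tbl$drug_id))
  used_mirnas <- unique(mirna_gene_tbl$mirna)

  # full build: phenotype seeds; tier1 pg/dd/pt; tier2 the rest, closed
  split_pairs <- function(ps) {
    m <- stringr::str_split_fixed(ps, "\r", 2)
    tibble(a = m[, 1], b = m[, 2])
  }
  tier1_tbl <- list("phenotype-gene" = split_pairs(pg_pairs),
                    "drug-phenotype" = split_pairs(dd_pairs),
                    "phenotype-tissue" = split_pairs(pt_pairs))
  tier2_tbl <- list("gene-gene" = split_pairs(ppi_pairs),
                    "mirna-gene" = split_pairs(mgp),
                    "drug-side_effect" = split_pairs(dse_pairs),
                    "gene-tissue" = split_pairs(gt_pairs),
                    "side_effect-tissue" = split_pairs(st_pairs))
  seeds <- phen_registry
  inc1 <- map(tier1_tbl, function(tb) tb[tb$a %in% seeds | tb$b %in% seeds, ])
  grown <- unique(c(seeds, unlist(map(inc1, function(tb) c(tb$a, tb$b)),
                                  use.names = FALSE)))
  inc2 <- map(tier2_tbl, function(tb) tb[tb$a %in% grown | tb$b %in% grown, ])
  final_ids <- unique(c(grown, unlist(map(inc2, function(tb) c(tb$a, tb$b)),
                                      use.names = FALSE)))
  closed2 <- map(tier2_tbl, function(tb) {
    tb[tb$a %in% final_ids & tb$b %in% final_ids, ]
  })
  kind_of <- c(
    setNames(rep("phenotype", length(phen_registry)), phen_registry),
    setNames(rep("gene", length(gene_registry)), gene_registry),
    setNames(rep("tissue", length(tissue_registry)), tissue_registry),
    setNames(rep("side_effect", length(live_s)), live_s),
    setNames(rep("drug", length(used_drugs)), used_drugs),
    setNames(rep("mirna", length(used_mirnas)), used_mirnas)
  )
  build_edge_counts <- c(map_int(inc1, nrow), map_int(closed2, nrow))
  build_node_counts <- table(unname(kind_of[final_ids]))

  # disease-disease similarity over the built phenotype-gene layer
  pg_built <- inc1[["phenotype-gene"]]
  ph_end <- ifelse(pg_built$a %in% phen_registry, pg_built$a, pg_built$b)
  gn_end <- ifelse(pg_built$a %in% phen_registry, pg_built$b, pg_built$a)
  dis_of <- split(gn_end, ph_end)
  dnodes <- sort(intersect(final_ids, phen_registry))
  sim_counts <- c(`1` = 0L, `2` = 0L, `3` = 0L)
  if (length(dnodes) > 1) {
    for (i in seq_len(length(dnodes) - 1)) {
      for (j in (i + 1):length(dnodes)) {
        w <- length(intersect(dis_of[[dnodes[i]]] %||% character(),
                              dis_of[[dnodes[j]]] %||% character()))
        for (th in 1:3) {
          if (w >= th) sim_counts[[th]] <- sim_counts[[th]] + 1L
        }
      }
    }
  }

  manifest <- list(
    seed = spec$seed,
    files = c(files, list(config = "resources.yaml",
                          manifest = "manifest.json")),
    ground_truth = list(
      node_counts = list(
        phenotype = length(phen_registry), gene = length(gene_registry),
        tissue = length(tissue_registry), side_effect = length(live_s),
        drug = length(used_drugs), mirna = length(used_mirnas)),
      ctd_rows_total = nrow(ctd_tbl),
      ctd_direct_rows = nrow(ctd_direct),
      gwas_rows_total = nrow(gwas_tbl),
      gwas_pass_rows = nrow(gwas_pass),
      gwas_merged_loci = nrow(merged),
      gwas_union_length = sum(merged$end - merged$start),
      phenotype_tissue_pairs = gsub("\r", "|", pt_pairs),
      side_effect_tissue_pairs = gsub("\r", "|", st_pairs),
      edge_pair_counts = list(
        "phenotype-gene" = length(pg_pairs),
        "phenotype-tissue" = length(pt_pairs),
        "gene-tissue" = length(gt_pairs),
        "drug-phenotype" = length(dd_pairs),
        "drug-gene" = length(dg_pairs),
        "drug-side_effect" = length(dse_pairs),
        "side_effect-tissue" = length(st_pairs),
        "gene-gene" = length(ppi_pairs),
        "mirna-gene" = length(mgp)),
      full_build = list(
        n_nodes = length(final_ids),
        n_edges = sum(build_edge_counts),
        node_counts = as.list(build_node_counts),
        edge_counts = as.list(build_edge_counts)),
      similarity_edges = as.list(sim_counts)
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Sample a connected-style disease-gene bipartite hetnet of exact size
#'
#' Draws a random bipartite phenotype-gene hetnet with exactly the
#' requested node and edge counts, every node incident to at least one
#' edge. Used to reconstruct case-study-shaped networks (e.g. 82 diseases +
#' 1465 genes joined by 2010 associations) whose N/E ratio is then read off
#' a [topology_report()].
#'
#' @param n_disease,n_gene Node counts.
#' @param n_edges Edge count; must be at least `max(n_disease, n_gene)` and
#'   at most `n_disease * n_gene`.
#' @param seed Optional RNG seed.
#' @return A [hetnet()].
#' @export
sample_disease_gene_net <- function(n_disease, n_gene, n_edges,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_edges < max(n_disease, n_gene) || n_edges > n_disease * n_gene) {
    abort("n_edges incompatible with covering both node sets",
          class = "hetnet_parameter_error")
  }
  d <- sprintf("D%04d", seq_len(n_disease))
  g <- sprintf("G%04d", seq_len(n_gene))
  # cover every gene, then every disease, then fill with fresh random pairs
  pairs <- unique(c(
    paste(sample(d, n_gene, replace = TRUE), g, sep = "\r"),
    paste(d, sample(g, n_disease, replace = TRUE), sep = "\r")
  ))
  while (length(pairs) < n_edges) {
    need <- n_edges - length(pairs)
    extra <- paste(sample(d, need, replace = TRUE),
                   sample(g, need, replace = TRUE), sep = "\r")
    pairs <- unique(c(pairs, extra))
  }
  pairs <- pairs[seq_len(n_edges)]
  m <- stringr::str_split_fixed(pairs, "\r", 2)
  hetnet(
    nodes = bind_rows(tibble(id = d, kind = "phenotype"),
                      tibble(id = g, kind = "gene")),
    edges = tibble(source = m[, 1], target = m[, 2],
                   kind = "phenotype-gene")
  )
}
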