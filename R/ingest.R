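# Tab-separated resource-table schemas. Column names are fixed per resource;
# extra columns pass through untouched.
resource_schemas <- list(
  gwas = c("disease_id", "chrom", "start", "end", "reported_gene", "p_value"),
  ctd_dg = c("disease_id", "gene", "evidence"),
  omim = c("disease_id", "gene"),
  drug_gene = c("drug_id", "gene"),
  drug_disease = c("drug_id", "disease_id"),
  drug_side_effect = c("drug_id", "se_id", "frequency"),
  gene_tissue = c("gene", "tissue_id", "expression"),
  mirna_gene = c("mirna", "gene"),
  ppi = c("gene_a", "gene_b")
)

#' Read a resource edge table
#'
#' Reads one of the tab-separated resource extracts (GWAS associations, CTD
#' disease-gene, OMIM, drug-gene, drug-disease, drug-side-effect,
#' gene-tissue, miRNA-gene, protein-protein) and checks its required
#' columns. GWAS coordinates are 0-based half-open internally; a 1-based
#' source dialect is converted at read time.
#'
#' @param path Path to a TSV file.
#' @param resource One of `names(hetnetr:::resource_schemas)`.
#' @param one_based For `resource = "gwas"`: input start coordinates are
#'   1-based inclusive and are shifted to 0-based half-open. Default FALSE.
#' @return A tibble with at least the resource's required columns.
#' @export
read_resource_table <- function(path, resource, one_based = FALSE) {
  if (!resource %in% names(resource_schemas)) {
    abort(paste0("unknown resource '", resource, "'"),
          class = "hetnet_schema_error")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- resource_schemas[[resource]]
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(paste0("resource '", resource, "' is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "hetnet_schema_error")
  }
  if (resource == "gwas" && one_based) {
    tbl$start <- tbl$start - 1L
  }
  tbl
}

#' Keep only CTD rows with direct "marker/mechanism" evidence
#'
#' The curated disease-gene extract carries an evidence code per row; only
#' relationships with direct evidence of `"marker/mechanism"` are treated as
#' phenotype-gene associations (therapeutic and inferred rows are dropped).
#' Row order is preserved.
#'
#' @param table A data frame with an `evidence` column.
#' @return The filtered tibble.
#' @export
filter_ctd_direct <- function(table) {
  table <- as_tibble(table)
  if (!"evidence" %in% names(table)) {
    abort("table has no evidence column", class = "hetnet_schema_error")
  }
  filter(table, evidence == "marker/mechanism")
}

#' Keep GWAS rows at or below a p-value threshold
#'
#' @param table A data frame with a `p_value` column.
#' @param threshold Inclusive p-value cutoff; rows with
#'   `p_value <= threshold` survive. Default `1e-7`, the genome-wide
#'   threshold used in the disease-gene case study.
#' @return The filtered tibble, row order preserved.
#' @export
filter_gwas_pvalue <- function(table, threshold = 1e-7) {
  table <- as_tibble(table)
  if (!"p_value" %in% names(table)) {
    abort("table has no p_value column", class = "hetnet_schema_error")
  }
  p <- table$p_value
  if (!is.numeric(p)) {
    suppressWarnings(pn <- as.numeric(p))
    bad <- which(is.na(pn) & !is.na(p))
    if (length(bad)) {
      abort(paste0("non-numeric p_value in row(s): ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "hetnet_parse_error")
    }
    p <- pn
  }
  if (any(!is.na(p) & (p <= 0 | p > 1))) {
    abort("p_value must lie in (0, 1]", class = "hetnet_parse_error")
  }
  table[!is.na(p) & p <= threshold, ]
}

#' Merge overlapping GWAS loci into one association per locus
#'
#' Within each (disease, chromosome) group, genomic intervals sharing at
#' least one base are unioned into maximal merged loci; abutting intervals
#' (zero shared bases, 0-based half-open) are kept separate. Each merged
#' locus carries a single primary gene: the author-reported gene of its
#' lowest-p constituent row (ties broken by the lexicographically smallest
#' symbol), so each disease gains one association per locus rather than one
#' per SNP.
#'
#' @param loci Data frame with columns `disease_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `reported_gene`, `p_value`.
#' @return A tibble with one row per merged locus: `disease_id`, `chrom`,
#'   `start`, `end`, `primary_gene`, `p_value` (the minimum), `n_merged`.
#'   Sorted by disease, chromosome and start; intervals within a group are
#'   pairwise disjoint.
#' @export
merge_loci <- function(loci) {
  loci <- as_tibble(loci)
  need <- c("disease_id", "chrom", "start", "end", "reported_gene", "p_value")
  missing <- setdiff(need, names(loci))
  if (length(missing)) {
    abort(paste0("loci are missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "hetnet_schema_error")
  }
  if (!nrow(loci)) {
    return(tibble(disease_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  primary_gene = character(), p_value = double(),
                  n_merged = integer()))
  }
  if (any(loci$start < 0) || any(loci$start >= loci$end)) {
    abort("locus coordinates must satisfy 0 <= start < end",
          class = "hetnet_coordinate_error")
  }

  merge_group <- function(df) {
    df <- arrange(df, start, end, reported_gene)
    runs <- integer(nrow(df))
    run <- 1L
    cur_end <- df$end[1]
    runs[1] <- run
    for (i in seq_len(nrow(df))[-1]) {
      if (df$start[i] < cur_end) {         # >=1 shared base; abutting splits
        cur_end <- max(cur_end, df$end[i])
      } else {
        run <- run + 1L
        cur_end <- df$end[i]
      }
      runs[i] <- run
    }
    df$.run <- runs
    df |>
      group_by(.run) |>
      summarise(
        start = min(start), end = max(end),
        primary_gene = min(reported_gene[p_value == min(p_value)]),
        p_value = min(p_value),
        n_merged = dplyr::n(),
        .groups = "drop"
      ) |>
      select(-".run")
  }

  loci |>
    group_by(disease_id, chrom) |>
    group_modify(function(df, key) merge_group(df)) |>
    ungroup() |>
    select(disease_id, chrom, start, end, primary_gene, p_value, n_merged) |>
    arrange(disease_id, chrom, start)
}
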