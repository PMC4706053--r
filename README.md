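# hetnetr

Heterogeneous biological networks ("hetnets") for the study of complex
traits: `hetnetr` integrates phenotypes (diseases), genes, miRNAs, tissues,
drugs and drug side effects into one typed network, and provides the
surrounding machinery a systems-biology analysis needs — ontology-driven
inference of tissue links, cross-vocabulary identifier resolution,
evidence filters, seed-and-expand network construction, bipartite
similarity projection and topology reporting. It is aimed at researchers
who want disease-gene-drug integration as a scriptable library and CLI
rather than a GUI application.

## The data model

A **metagraph** fixes the schema: six node kinds and nine permitted edge
kinds

```
phenotype-gene      phenotype-tissue    gene-tissue
drug-phenotype      drug-gene           drug-side_effect
side_effect-tissue  gene-gene (PPI)     mirna-gene
```

and every instance network (**hetnet**) type-checks its nodes and
undirected edges against it. The metagraph is cyclic, so construction
starts from a chosen node kind (disease, gene or drug) and expands in two
tiers: tier-1 edge kinds attach neighbors of the seeds, tier-2 kinds
attach neighbors of the grown set (e.g. first-degree protein interactions
of the disease-associated genes).

Three computations are central:

* **Ontology inference.** Manual mappings of high-level disease or
  side-effect terms onto BRENDA tissues (e.g. connective tissue disease
  DOID:65 → connective tissue BTO:0000421) are propagated down `is_a`
  chains so every descendant term inherits the union of its ancestors'
  tissues: `ann(t) = ⋃ manual(a), a ∈ {t} ∪ ancestors(t)`.
* **GWAS locus merging.** Per disease and chromosome, reported loci that
  share at least one base are unioned into a single locus whose primary
  gene is the author-reported gene of the lowest-p constituent, giving one
  association per locus instead of one per SNP (rows are first filtered at
  p ≤ 1e-7).
* **Similarity projection.** A bipartite layer (disease-gene) is projected
  onto one side: diseases *a*, *b* are connected iff
  `|N(a) ∩ N(b)| ≥ min_shared`, with the shared-neighbor count as integer
  edge weight ("more than 2 shared genes" is `min_shared = 3`).

Topology reports give node/edge counts and the N/E ratio (nodes over
edges, half-up to 2 decimals), component sizes, degree distribution,
neighborhood connectivity and shortest-path-length distribution of the
largest component.

## Worked example

```r
library(hetnetr)

# generate a complete synthetic resource directory (3 OBO ontologies,
# alias/xref tables, 9 edge tables, YAML config) and ingest it
dir <- tempfile()
generate_fixtures(fixture_spec(seed = 7), dir)
store <- load_resources(file.path(dir, "resources.yaml"))

# disease-seeded network: direct layers first, then second-tier layers
net <- build_hetnet(
  store, "phenotype",
  seeds = store$nodes$id[store$nodes$kind == "phenotype"],
  tier1 = c("phenotype-gene", "drug-phenotype", "phenotype-tissue"),
  tier2 = c("gene-gene", "mirna-gene", "drug-side_effect",
            "gene-tissue", "side_effect-tissue"))
net
#> <hetnet> 263 nodes, 887 edges
#>   node  phenotype            48
#>   node  gene                 142
#>   node  mirna                12
#>   node  tissue               25
#>   node  drug                 20
#>   node  side_effect          16
#>   edge  phenotype-gene       195
#>   edge  phenotype-tissue     86
#>   edge  gene-tissue          194
#>   edge  drug-phenotype       57
#>   edge  drug-side_effect     37
#>   edge  side_effect-tissue   41
#>   edge  gene-gene            239
#>   edge  mirna-gene           38

# disease-disease similarity: connected iff > 2 shared genes
sim <- similarity_projection(net, "phenotype", "gene", min_shared = 3)
glance(sim)
#> # A tibble: 1 × 4
#>   n_nodes n_edges n_node_kinds n_edge_kinds
#>     <int>   <int>        <int>        <int>
#> 1      48       2            1            1

topology_report(net)
#> <topology_report> 263 nodes, 887 edges (N/E 0.3)
#>   components: 263
#>   largest component: 263 nodes
```

The printed N/E ratio contrasts topologies: polygenic GWAS-style networks
have many genes per disease (low ratio, diseases central), monogenic
OMIM-style networks approach one gene per disease (ratio near 1, diseases
peripheral). Exports (`write_sif()`, `write_graphml()`) interoperate with
Cytoscape and igraph; `autoplot()` methods draw composition, topology and
weight-spectrum figures; the same operations are scriptable through the
`exec/hetnet` CLI (`build`, `project`, `report`, `fixtures` subcommands).

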