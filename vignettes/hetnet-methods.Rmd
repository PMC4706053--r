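---
title: "Building and analysing trait hetnets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing trait hetnets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetnetr)
```

## The model

`hetnetr` represents biology as a typed heterogeneous network. The schema
is a *metagraph*: six entity kinds (phenotype, gene, miRNA, tissue, drug,
side effect) and nine permitted interaction kinds, including the self-kind
protein–protein edge. The metagraph is cyclic — disease connects to gene,
gene to drug, drug back to disease — so there is no canonical traversal
order; instead, networks are built from a *starting node kind* (disease,
gene or drug) in two expansion tiers. Instance networks are plain tibbles
(a node table and an edge table) wrapped in a `hetnet` S3 object, and
every edge insertion type-checks endpoints against the metagraph.

Edges are undirected. None of the integrated relations carries a natural
direction at this level of abstraction (an association, an interaction, an
indication), so the canonical storage key is the lexicographically ordered
id pair plus the edge kind. Re-inserting an edge merges attribute columns
with a later-wins-per-column rule: deterministic, and the natural
behaviour when the same association arrives from two resources (the GWAS
row contributes a p-value, the curated row contributes nothing new).
Self-loops (homodimer PPIs) are legal and stored once. A consequence worth
stating: two resources reporting the same disease–gene pair yield *one*
edge, so per-kind edge counts are counts of distinct associations, not of
source rows.

## Identifier resolution

Integration lives or dies on identifiers. Genes are keyed by the integer
portion of their HGNC id; an alias table maps current symbols, outdated
symbols and synonyms to that integer. Resolution precedence is: current
symbol, then unique alias; an alias shared by several genes returns an
explicit *ambiguous* outcome and the pipeline drops the row with a
warning, because silently picking one target would fabricate an
association. Matching is case-sensitive (HGNC symbols are
case-significant); a case-insensitive fallback exists behind a flag,
default off.

Phenotypes are unified onto the disease ontology (DO). OMIM, MeSH and EFO
identifiers map through a cross-reference table; identifiers with no
cross-reference pass through namespaced (`MESH:D012345`) and become their
own nodes — unmapped terms stay distinct rather than disappearing. A
source id cross-referenced to several DO terms is surfaced as ambiguous
with all candidates, never merged by guesswork. The EFO mapping is an
input table, not code: curation changes should not require a release.

## Ontology inference of tissue links

Phenotype–tissue and side-effect–tissue edges are not read from any
resource; they are inferred. Curators map a handful of *high-level* terms
to affected tissues (connective tissue disease DOID:65 → connective
tissue BTO:0000421), and the package propagates each mapping down the
`is_a` hierarchy: a term's annotation set is the union of the manual
annotations of itself and all its ancestors. Both ontologies use the
identical code path.

Design choices here, with reasons:

* **`is_a` only.** `part_of` and other relations are ignored; subsumption
  is the only relation under which "affects tissue T" is safely heritable.
* **Downward only.** An annotated term tells us nothing reliable about its
  *more general* ancestors, so they gain nothing.
* **Obsolete terms** are parsed and flagged but excluded from inferred
  annotations and from node registries; they are placeholders, not
  entities.
* The tissue ontology is rooted at whole body (BTO:0001489) before use,
  which discards the non-animal branches; rooting keeps exactly the
  reverse-reachable set of the root.

Propagation is computed in one topological pass (ancestors before
descendants), which makes it idempotent: applying it to its own output is
a no-op, a property the tests assert alongside equality with a
brute-force per-term ancestor-walk oracle on random DAGs.

## Ingestion filters and locus merging

Two inclusion rules are applied at read time. Curated disease–gene rows
survive only with direct `"marker/mechanism"` evidence — therapeutic
rows describe treatment, not aetiology. GWAS rows survive at
`p_value <= 1e-7` (inclusive: genome-wide convention admits boundary
hits), the threshold being config-overridable.

Surviving GWAS rows are then collapsed from SNP-level to locus-level:
within each (disease, chromosome) group, intervals sharing at least one
base are unioned into maximal merged loci. Coordinates are 0-based
half-open internally (a 1-based source dialect is converted at read time),
and *abutting* intervals — `[100,200)` and `[200,300)` — do **not** merge:
they share zero bases, and "overlapping" is read strictly. Each merged
locus contributes one association whose primary gene is the
author-reported gene of the lowest-p constituent; an exact p tie (possible
with truncated published p-values) breaks to the lexicographically
smallest symbol so results never depend on row order. The interval union
here is the simple sweep; the published locus-combination procedures have
finer variants, and anything beyond plain interval union is out of scope
and documented as such.

## Construction semantics

`build_hetnet()` takes seeds of one kind plus two sets of edge kinds.
Tier-1 kinds are evaluated against the *seed set*: every stored edge of a
requested kind incident to a seed joins, with its far endpoint. Tier-2
kinds are evaluated the same way against the tier-1-grown node set. Two
deliberate refinements:

* Seeds with no incident edges stay in the result as isolated nodes — the
  user asked for them.
* With `tier2_closure = TRUE` (default), tier-2-kind edges *among* newly
  added nodes are also kept. Without it, the protein-interaction layer
  around a disease-gene core would be a star forest; with it, the layer is
  the induced interactome, which is what one inspects for densely
  connected components.

Both phases are computed per kind against a fixed frontier (not
sequentially kind-by-kind), so results are independent of the order in
which edge kinds are listed; node and edge tables are sorted on output,
making identical requests byte-identical. Second-tier expansion is scoped
to nodes already in the network — side-effect edges attach to drugs the
network contains, not to all drugs.

`subnetwork_min_disease_degree(net, k)` restricts to the
multi-disease-associated interactome: genes with at least `k` distinct
phenotype neighbours, the phenotypes they link to, and all edges among the
kept nodes (PPIs between kept genes included; other node kinds dropped).

## Projection and topology

`similarity_projection()` converts a bipartite layer into a homogeneous
weighted graph; the weight is the exact shared-neighbour count and an edge
exists iff the weight reaches `min_shared`. The API takes the minimum
count rather than a strict-greater bound to avoid off-by-one ambiguity —
"more than 2 shared genes" is `min_shared = 3`. Raising the threshold can
only remove edges (asserted as a property test).

`topology_report()` computes counts on the hetnet as stored and the graph
statistics (degrees, components, neighbourhood connectivity = mean
neighbour degree aggregated by degree, unweighted shortest-path histogram
of the largest component) on the simplified graph: self-loops ignored,
parallel edges of different kinds collapsed. Both full-network and
largest-component sizes are exposed, since summary statistics are
sometimes quoted for one and sometimes for the other. The N/E ratio is
rounded half-up to two decimals (`round()`'s round-half-even would turn
2265/2228 = 1.0166 into an implementation-dependent spelling); half-up is
also the convention consumers expect from printed two-decimal ratios.
Degree-proportional opacity (`degree_opacity()`) normalises each node's
degree by the maximum within its kind, so a maximum-degree drug gets 1 and
isolated nodes get 0.

## Interchange formats

SIF output is tab-delimited (`source<TAB>kind<TAB>target`, isolated nodes
as bare ids) with a node-kind/label sidecar TSV; it round-trips the typed
node and edge multisets exactly but cannot carry arbitrary edge
attributes — GraphML is the attribute-preserving format. GraphML files
are written through igraph; integer attribute columns are cast to double
on write (the integer missing-value sentinel does not survive
serialization) and whole-numbered columns are restored to integer on
read, so projection weights come back as the integers they are. Output
ordering is sorted everywhere, so exports are diffable.

## The synthetic resource generator

`generate_fixtures()` writes a complete resource directory — disease,
tissue and side-effect ontologies (OBO), manual tissue maps, alias and
cross-reference tables, all nine edge tables and a ready-to-run YAML
config — from a single seeded specification. It emulates the *structure*
of the real resources: a DAG-shaped disease ontology with cross-references
and an embedded worked example (DOID:65 with two descendants, mapped to
BTO:0000421); a tissue ontology with an animal part under whole body and
a non-animal branch that rooting must discard; aliases with outdated
symbols and synonyms that edge tables sometimes use in place of current
symbols; GWAS tables with overlapping loci and p-values straddling the
threshold; curated tables with mixed evidence codes and a fraction of
unmapped MeSH ids that must become passthrough nodes.

Default sizes (40 disease terms, 150 genes, 25 tissues, 120 GWAS rows,
100 curated rows, 250 PPIs, …) are chosen so that every filter has rows
on both sides and every code path is exercised while the full end-to-end
suite runs in seconds; test blocks that need other shapes (e.g. a
1000-row evidence-mix tally) pass their own spec. The generator records
ground truth in a manifest — filter survivor counts, the full propagation
closure, merged-locus tables, expected node/edge counts of the canonical
full build and expected similarity-projection edge counts — computed by
its own naive brute force (per-row scans, recursive ancestor walks,
per-base interval coverage on deliberately small coordinates), never by
calling the functions under test.

What the fixtures do *not* emulate: the degree distributions, sizes and
redundancy of the real public databases. Passing tests therefore
demonstrate correctness of the algorithms and the pipeline plumbing, not
robustness to the scale or curation noise of production resources.

## Numerical and degenerate-input conventions

* Empty networks are legal everywhere; the N/E ratio is reported as
  missing when there are no edges.
* Ties: largest-component ties break to the component containing the
  lexicographically smallest id; primary-gene ties to the smallest
  symbol; attribute merges to the latest write.
* All randomness in the generator flows from one integer seed; repeated
  runs are byte-identical.
* Problem sizes used by the test suite: propagation is checked against a
  closure oracle on 200 random DAGs of up to 200 terms; projection against
  an all-pairs oracle on 100 bipartite graphs up to 50 × 200 nodes at
  thresholds 1–3; locus merging against sweep and per-base oracles on 200
  random interval sets; format round-trips on 50 random networks.

## Known limitations

* OBO parsing covers the tag subset the integrated vocabularies need
  (`id`, `name`, `is_a`, `xref`, `is_obsolete`); OWL, logical definitions
  and non-`is_a` relations are out of scope.
* Locus merging implements plain interval union, as discussed above.
* Expansion stops at two tiers; there is no recursive multi-hop growth or
  query language.
* The similarity projection weight is a raw shared-neighbour count;
  normalised similarity measures (Jaccard, cosine) are not provided.
* Centralities beyond degree-based statistics are intentionally absent;
  exported GraphML loads directly into igraph or Cytoscape where those
  are standard.
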