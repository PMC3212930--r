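---
title: "Literature-derived MeSH enrichment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-derived MeSH enrichment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshenrich)
```

## The problem and the model

Gene-set over-representation analysis asks whether a query set of genes
(typically the differentially expressed genes of an experiment) overlaps
a functional category more than chance would allow. `meshenrich` uses the
Medical Subject Headings (MeSH) hierarchy as the category system and the
biomedical literature as the annotation: a gene belongs to a MeSH
category when at least one PubMed article is simultaneously indexed under
that MeSH descriptor and linked to that gene in an NCBI
gene2pubmed-style table. The association database is the inner join of
two link tables on PubMed ID: (descriptor, article) from a mesh2pubmed
table and (gene, article) from gene2pubmed. The number of distinct
articles supporting a (gene, term) pair is that gene's *citation count*
in that category — per category, deliberately, not the gene's global
literature footprint, because a heavily studied gene (say TP53) should
not pass a stringency filter in every category it brushes against.

The test statistic is the upper-tail hypergeometric probability
$P(X \ge k)$ of observing at least $k$ category genes among $n$ query
genes drawn without replacement from a universe of $N$ genes containing
$K$ category members. The upper tail is the over-representation
convention; $k = 0$ returns exactly 1. Summation runs over log-scale
binomial coefficients (`lchoose`), exponentiated around the largest term,
so categories of tens of thousands of genes do not overflow. Raw
p-values are reported by default; the tool's purpose is ranked
exploration of categories rather than family-wise inference, so
multiple-testing correction is opt-in (`fdr = TRUE` adds a
Benjamini–Hochberg column).

## Assumptions

The model assumes the background universe is the set of genes that
*could* have appeared in the query. Two conventions are common: all genes
with any literature annotation (the database), or all genes measured on
the platform. The default is the database universe; `background =`
restricts $N$, $K$ and $n$ consistently when the platform gene list is
available and is the better choice whenever the query came from an
array. The test further assumes exchangeability of genes within the
universe — literature annotation is in reality heavily biased toward
well-studied genes, which is exactly why the citation-stringency filters
exist: they trade sensitivity for robustness against categories whose
membership is dominated by single-article mentions.

## Parameters that matter

* `min_depth` (default 3): a MeSH term enters the database only if at
  least one of its tree numbers has ≥ 3 dot-separated components, the
  top-level letter code counting as one. Near-root headings
  ("Diseases", "Anatomy") would otherwise absorb most of the universe
  and always test significant. A term qualifies if *any* of its tree
  positions is deep enough; depth is a property of the descriptor, not
  of the position. The implicit category root is not counted as a
  component — this is a declared convention, exposed precisely so users
  who read "parent nodes" differently can change it.
* Stringency mode (`unfiltered`, `gt_avg`, `gt_stdev`): inequality is
  strict in both filtered modes, matching the labels "&gt;Avg" and
  "&gt;StDev". The standard deviation is the sample form (n − 1
  divisor), defined as 0 for single-gene categories so the `gt_stdev`
  threshold is always finite. Filtering redefines category membership
  before testing, so both $K$ and $k$ shrink together; the nesting
  `gt_stdev ⊆ gt_avg ⊆ unfiltered` is guaranteed because sd ≥ 0.
* Query size limit (default 500): a warning, not a rejection — several
  operations are meaningful on a whole-array gene list, but enrichment
  p-values lose interpretability as $n$ approaches $N$.

## Expression display

Expression input is a CSV of probe identifiers and log2 intensities;
values are assumed already log-transformed and normalized upstream (no
RMA/quantile step is applied here). Z-score normalization is per probe
across samples — $(x - \bar x)/s$ with the sample sd — because the
display question is "how does this gene move across conditions", not
"which genes are bright in this sample". Rows with zero variance become
zeros and are flagged rather than erroring, keeping clipped probes
visible in heatmaps; missing cells are excluded from the row mean/sd and
stay missing. Probes are never collapsed to genes: a GeneID measured by
three probes contributes three rows, and gene-level queries return all
of them. Heatmap row/column ordering uses hierarchical clustering with
Euclidean distance and average linkage, the de-facto default of the R
heatmap functions this display imitates; every image is accompanied by a
TSV of the exact numbers plotted so the rendering is auditable.

## Synthetic fixtures: what they emulate and what they do not

The generator emits every input dialect the package parses — MeSH trees
file, mesh2pubmed, gene2pubmed, homologene.data, gene2go, interactions,
pathway and expression tables — with planted structure recorded in a
JSON truth file. Default study conditions, chosen once as a small but
non-trivial literature: 300 genes, 40 terms, tree depths uniform on 1–5
under four top-level branches, 5–25 member genes per background
category, citation counts 1 + Poisson(1) per (gene, term) pair, query
size 20. The planted-signal condition is a 30-gene category from which
80% of the query is drawn. Each (gene, term, citation) is realised as a
distinct PubMed ID shared between the two link tables, so the join
reconstructs memberships and citation counts exactly and every file
round-trips through its parser warning-free. One global seed drives a
named pseudo-random stream per file type, so regenerating one file never
perturbs the others.

These fixtures are structural, not biological: real MeSH co-annotation
is correlated across related terms, citation counts are heavy-tailed
far beyond Poisson, and real queries are contaminated by annotation
bias. Passing the planted-recovery and calibration checks therefore
demonstrates algorithmic correctness, not that any particular biological
discovery is reliable.

## Numerical and calibration notes

* The hypergeometric implementation is validated two ways: exhaustively
  against subset enumeration (every valid $(N,K,n,k)$ with $N \le 12$,
  tolerance $10^{-12}$) and against the survival function of the
  hypergeometric distribution on random larger configurations.
* Null calibration is checked as an upper bound: across 200 random
  queries on an unplanted corpus, the fraction of category tests with
  $p \le 0.05$ must not exceed $0.05 + 3\,\mathrm{SE}$. Because the
  hypergeometric is discrete, attainable p-values near 0.05 are sparse
  and the observed fraction sits well below the nominal level (about
  0.02 under the default conditions); the test is conservative, never
  anti-conservative.
* Result ordering is a total order — p-value, then descending overlap,
  then term name — so repeated runs are byte-identical.
* Ties, degenerate inputs: single-gene categories have sd 0; empty join
  results warn and return empty rather than failing; queries entirely
  outside the universe are fatal with the unmapped genes named.
* Problem sizes in the validation suite (300-gene corpora, 100-seed
  recovery sweeps, 200 null queries, enumeration to $N = 12$) were
  picked so the complete suite re-runs from scratch in a few minutes on
  a single CPU while keeping the binomial error of the measured rates
  small relative to the thresholds being checked.

## Interfaces and deliberate exclusions

Interactions are undirected; $(a,b)$ and $(b,a)$ merge keyed by the
sorted pair with sources concatenated, and self-loops are dropped with a
count (they carry no pairwise information and break layout in external
viewers). Networks are exported as an edge TSV plus GraphML for standard
graph tools rather than an embedded interactive viewer. KEGG membership
comes from a user-supplied table — no live API calls, for offline
reproducibility and licensing reasons — and pathway diagrams are linked
by identifier, not rendered. The database store is plain TSV plus a JSON
manifest rather than a relational server; floating-point statistics are
written with 17 significant digits so a save/load round trip is
bit-exact. There is no live NCBI/PubMed querying anywhere: all
annotation arrives as files, which is what makes every result of the
package reproducible from a directory snapshot.

## Known limitations

Annotation bias is the dominant caveat: literature-derived categories
over-represent well-studied genes, and no stringency filter fully
removes that. Case-insensitive descriptor matching can in principle
merge distinct descriptors differing only in case (none exist in real
MeSH). The depth filter is a heuristic proxy for term specificity; MeSH
depth is not uniform across branches. And the hypergeometric model
treats categories independently, ignoring the MeSH hierarchy's nesting —
a parent and child category sharing genes will both score.
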