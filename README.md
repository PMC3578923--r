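# pathosim

Ontology-based pathophenotypic similarity networks for disease-causing
genes.

Disease-gene networks built by linking genes that share a named disease
inherit the historical quirks of disease nomenclature: a gene causing a
single private disease is an isolated node no matter how similar its clinical
picture is to other genes'. `pathosim` instead describes each gene by its
**pathophenotypic space** — the set of phenotype-ontology terms annotated to
it, usually the union of the clinical features of its diseases — and connects
genes by the semantic similarity of those term sets. Around that core it
provides the full analysis protocol: unipartite projections of disease-gene
tables, a four-class gene classification, edge-intersection statistics with
hypergeometric significance against degree-preserving nulls, resampled
Mann-Whitney topology tests, ROC validation of similarity scores against
biomolecular interactomes, and disease-module extraction — plus a
synthetic-data generator so everything is testable without external
databases.

## The model

For a term $t$, $IC(t) = -\ln p(t)$, where $p(t)$ is the fraction of
annotated genes whose ancestor-closed annotation set contains $t$. The
similarity of two terms is the information content of their most informative
common ancestor (Resnik). The similarity of two genes with specific term
sets $T_1, T_2$ is the symmetrized best-match average

$$\mathrm{sim}(g_1,g_2) = \frac12\left[
  \frac{1}{|T_1|}\sum_{t_1 \in T_1}\max_{t_2 \in T_2}\mathrm{sim}(t_1,t_2) +
  \frac{1}{|T_2|}\sum_{t_2 \in T_2}\max_{t_1 \in T_1}\mathrm{sim}(t_1,t_2)
\right].$$

All positive gene-pair scores are computed and the network keeps the top
slice above an empirical percentile cutoff (98th by default — the top 2 %).
Networks are compared by edge intersection: with $N$ union nodes,
$M = N(N-1)/2$ possible edges, $R$ reference and $Q$ query edges and
$\hat{o}R$ shared edges, the report carries $E(\hat{o}R) = QR/M$, the mutual
coverage percentages, the Jaccard coefficient
$\hat{o}R/(Q+R-\hat{o}R)$ and the upper-tail hypergeometric probability
$P(X \ge \hat{o}R)$.

## Worked example

Everything runs on synthetic data with planted ground truth:

```r
library(pathosim)

spec <- synthetic_spec(seed = 7)       # 120-term ontology, 30 genes
dag  <- generate_ontology(spec)
dis  <- generate_diseasome(spec)
ann  <- generate_annotations(dis, dag, spec)

pruned <- prune_excluded(dag, ann)     # drop non-phenotypic branches
prop   <- propagate_annotations(pruned$dag, pruned$annotations)
ic     <- compute_ic(pruned$dag, prop)

simnet <- all_pairs_network(pruned$annotations, ic, pruned$dag)
thr    <- percentile_threshold(simnet, 98)
glance(thr)
#> # A tibble: 1 × 5
#>   percentile cutoff_score n_input n_retained retained_fraction
#> 1         98         1.48     369          8            0.0217
```

369 gene pairs have positive similarity; the 98th-percentile cutoff (score
1.48 nats) keeps the 8 most similar pairs, 2.2 % of the distribution. The
thresholded network can then be compared with the classical unipartite
projection of the same diseasome:

```r
cmp <- compare_networks(project_unipartite(dis), as_gene_network(thr$retained))
tidy(cmp)
#>    statistic                  value
#>  1 n_nodes_union          16
#>  3 n_edges_query           8
#>  4 n_edges_reference      19
#>  5 observed_intersection   6
#>  7 expected_intersection   1.27
#> 10 jaccard                 0.286
#> 11 p_value                 0.000169
```

Six of the eight top similarity pairs are also co-disease pairs — far above
the 1.27 expected by chance (hypergeometric p = 1.7e-4), because high
similarity here is driven by shared diseases; the remaining two are the
"emergent" pairs the similarity view adds. `classify_genes()`,
`resampled_mannwhitney()`, `averaged_auc_experiment()` and
`extract_module()` continue the protocol; `run_pipeline()` chains every
stage from files on disk to a directory of TSV reports. Result objects have
`tidy()`/`glance()` and `autoplot()` methods.

## Scope notes

Identifier mapping between database namespaces is out of scope (IDs are
opaque strings), as are disease-disease projections and full OBO 1.4 parsing
(only `is_a` is read). Published network sizes depend on 2012-era database
snapshots and are deliberately not targets; see the methods vignette
(`vignettes/pathophenotype-networks.Rmd`) for the model, the interpretive
choices and the limits of the synthetic corpus.
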