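---
title: "Pathophenotypic similarity gene networks: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathophenotypic similarity gene networks: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathosim)
```

## The problem

Disease databases record which genes cause which diseases. Projecting that
bipartite table onto genes (link two genes when they share a disease) produces
a disease-causing gene network, but it inherits every idiosyncrasy of how
clinicians have carved pathology into named entities: a gene associated with a
single private disease is an isolated node, however similar its clinical
picture is to other genes'. `pathosim` implements the alternative: describe
every gene by its *pathophenotypic space* — the set of phenotype-ontology
terms annotated to it, typically the union of the clinical features of its
diseases — and connect genes by the *semantic similarity* of those term sets.
The resulting similarity network can then be compared against unipartite
disease projections and against biomolecular interactomes (physical, metabolic,
functional), validated by ROC analysis, and mined for disease modules.

## The similarity model

**Information content.** For an ontology term $t$, let $p(t)$ be the fraction
of annotated genes whose *propagated* annotation set (direct terms plus all
their ancestors) contains $t$. Then

$$IC(t) = -\ln p(t).$$

The root is annotated to every gene after propagation, so $IC(\text{root}) = 0$,
and IC never decreases from a term to its descendants. Propagation before
counting is an interpretive choice: frequencies computed on direct annotations
alone would violate the monotonicity that the most-informative-common-ancestor
construction presumes. The denominator is the number of annotated genes (a
per-gene probability), not the number of term-gene pairs, so that
$p(\text{root}) = 1$ exactly.

**Term similarity (Resnik).** For terms $t_1, t_2$,
$\mathrm{sim}(t_1, t_2) = \max_{a \in S(t_1,t_2)} IC(a)$, where $S$ is the set
of shared ancestors (each term counting as its own ancestor). Ties in the
maximum need no tie-break because only the IC value is returned.

**Gene similarity (best-match average).** For genes $g_1, g_2$ with specific
term sets $T_1, T_2$:

$$\mathrm{sim}(g_1 \to g_2) = \frac{1}{|T_1|} \sum_{t_1 \in T_1}
  \max_{t_2 \in T_2} \mathrm{sim}(t_1, t_2),$$

which is not symmetric; the network score is the symmetric version
$\tfrac12[\mathrm{sim}(g_1 \to g_2) + \mathrm{sim}(g_2 \to g_1)]$, interpreted
as the arithmetic mean of the two one-sided values (the convention of the
ontology's own authors). A maximum-over-all-pairs variant (`funsim_max()`) is
provided for functional-similarity corpora. Scores are computed on each gene's
**most specific** terms (ancestors dominated by a descendant are dropped);
the full propagated sets are used only for IC counting. Both choices follow
the observation that ancestor terms carry no extra information once a
descendant is present, while frequencies must be counted on closed sets.

**Branch exclusion.** Ontology branches that do not describe phenotypic
abnormalities (inheritance mode, onset/clinical course) are pruned before any
computation: a term survives only if it can reach the root without passing
through an excluded branch root, so multi-parent terms straddling a kept and
an excluded branch survive. Genes emptied by pruning are kept in the corpus
bookkeeping but flagged and skipped by the similarity stage — fabricating
similarities for them would be worse than omitting them.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `percentile` | 98 | Score percentile; retains the top 2 % of positive pairs. 99.5 for dense corpora (functional similarity). |
| `n_runs` | 1000 | Resampling runs per subset in the Mann-Whitney protocol. |
| `roc_reps` | 20 | Independent false-positive randomizations averaged into the mean AUC. |
| `n_swaps` | `10 * |E|` | Double-edge swap attempts in the degree-preserving null. |
| `bandwidth` | 0.01 | Gaussian kernel bandwidth for score-density plots. |

The percentile threshold is empirical (type-7 quantile of the positive-score
distribution); all pairs scoring at or above the cutoff are retained, so ties
at the boundary survive together — the retained count is deterministic and
order-independent, at the price of occasionally exceeding the nominal share.
Only pairs with score strictly greater than zero enter the distribution;
zero-similarity pairs (root-only sharing) are not edges. Lowering the
percentile never removes a retained pair. Where a trusted positive set exists,
`optimize_threshold()` scans all distinct scores and maximizes Youden's
J instead; the criterion is deliberately simple and configurable, since no
standard procedure exists for picking a semantic-similarity cutoff.

## Network comparison

`compare_networks()` reports, for a reference network with $R$ edges and a
query with $Q$ edges on a node union of size $N$ (so $M = N(N-1)/2$ possible
edges): the observed edge intersection, the union, the expected intersection
$QR/M$, the mutual coverage percentages, the Jaccard coefficient, and the
upper-tail hypergeometric probability of observing at least that many shared
edges when $Q$ edges are drawn from $M$ of which $R$ are reference edges
(inclusive tail, $P(X \ge \hat{o}R)$). Isolated nodes are excluded first —
they are not structural components — and `restrict_to_common_nodes()` filters
both networks to their shared node set before comparing networks of very
different sizes. `comparison_from_counts()` computes the same derived
statistics directly from printed summary counts, which is how the package's
acceptance checks audit published comparison tables. The null model for
significance claims is `randomize_preserving_degrees()`: repeated double-edge
swaps with rejection of self-loops and duplicates, which preserves every
node's degree exactly; $10|E|$ attempts mix adequately at the scales used
here.

## Topology statistics

The resampled Mann-Whitney protocol compares a gene subset's values (degree,
term count, mean incident similarity) against repeated same-size random
samples of the population, without replacement, and reports the mean of the
per-run two-sided p-values. Two interpretive choices are documented here
because the procedure admits variants: sampling is without replacement from
the full population *including* the subset (the subset is part of the
pathophenome it is compared against), and the alternative is two-sided with
the normal approximation and continuity correction. A statistical caveat
follows from the design: for a fixed subset the per-run p-values are
correlated through the subset, so the 1000-run mean converges to
$E[p \mid \text{subset}]$ — a quantity that varies between subsets with a
spread near 0.1 — rather than to 0.5. Calibration statements about the
protocol are therefore made on averages over independent null subsets (the
test suite uses 100 draws), not on a single subset's mean p-value.

## ROC validation

`build_validation_set()` labels similarity-network edges found in a real
interactome as true positives and edges found in a degree-preserving
randomization of that interactome as false positives, excluding any pair that
is a real interactome edge (a real interaction is never a false positive).
Randomization repeats until the false-positive pool matches the true-positive
count, then truncates 1:1 — the simplest reading of keeping the two classes
proportional. `roc_auc()` sweeps every distinct score as a threshold and
integrates by the trapezoid rule; the AUC equals the normalized Mann-Whitney
U statistic, which the tests exploit as an independent identity (and
cross-check against pROC). `averaged_auc_experiment()` repeats the whole
procedure with independent randomizations and averages the AUCs;
`compare_auc_sets()` compares two interactomes' replicate AUCs by a two-sided
Mann-Whitney test (the comparison test is unnamed in the source protocol;
Mann-Whitney on replicates is our interpretation).

## The synthetic corpus

The generators exist so that every downstream stage is testable with known
ground truth, offline:

* `generate_ontology()` grows a rooted DAG shaped like a phenotype ontology:
  one root, one phenotypic-abnormality branch holding most terms, a
  configurable number of excluded branches off the root, `HP:%07d` IDs,
  occasional second parents (a true DAG, not a tree). Defaults: 120 terms,
  depth 6, fan-out 5, two excluded branches.
* `generate_diseasome()` plants exact class counts for the four
  association classes (MD-MG, MD-PG, PD-MG, PD-PG — disease genicity crossed
  with gene tropy): private diseases for one-to-one genes, two private
  monogenic diseases per MD-PG gene, PD-MG genes grouped 2–4 per shared
  disease, PD-PG genes chained through pairwise shared diseases. Counts that
  cannot be realized exactly (a lone PD-MG gene with no pleiotropic partner;
  a lone PD-PG gene without two PD-MG partners) raise errors rather than
  silently approximating. An optional flag additionally pairs MD-PG genes
  through shared polygenic diseases, reproducing the overlap between the two
  pleiotropic classes.
* `generate_annotations()` gives each disease a *coherent* term set: a random
  focus term plus terms from its subtree (2–6 per disease by default), padded
  randomly when the subtree is small; genes inherit the union of their
  diseases' sets. Coherence matters: with uniformly random disease terms in a
  small vocabulary, genes with more terms overlap more by chance and mean
  similarity *rises* with term count; with clustered disease profiles,
  pleiotropic genes carry multi-cluster profiles whose one-sided averages are
  diluted, reproducing the empirically observed anticorrelation between
  annotation richness and mean similarity inside the thresholded network.
* `generate_interactome()` realizes a degree sequence (Erdős–Gallai checked,
  stub matching with rejection and restart) or an edge-count target around a
  set of planted edges copied from the similarity network, giving ROC
  experiments a known signal whose strength is the planted fraction.

Each generator draws from its own seed stream (an offset of the spec seed),
so stages regenerate independently and a fixed spec yields byte-identical
outputs. What the corpus does *not* emulate: realistic ontology depth
(real phenotype ontologies have ~10⁴ terms; the default here has 120),
annotation biases of literature curation, identifier mapping noise, or
database-version drift. Passing tests therefore demonstrate correctness of
the machinery and qualitative reproduction of the protocol's behaviors, not
quantitative reproduction of any database snapshot — published network sizes
depend on 2012-era source data and are out of scope by design.

## Numerical choices and degenerate inputs

* Natural logarithm throughout; IC is in nats.
* Empirical percentile = type-7 quantile (R's default), ties retained.
* Hypergeometric tail via `phyper(lower.tail = FALSE)`; a log10 column
  supplements the raw p-value where the tail underflows double precision
  (observed below ~1e-308 in published-scale comparisons).
* Edge identity is the unordered node pair; weights never enter intersection
  counts. Self-loops and duplicate edges are dropped on construction.
* A single-edge graph randomizes to itself (no legal swap); `n_swaps = 0` is
  a no-op; a non-graphical degree sequence is an error, as is a planted edge
  set exceeding a node's degree budget.
* Genes with empty post-pruning annotation sets are excluded from similarity
  but retained (flagged) in bookkeeping; zero annotated genes is an error for
  IC; fewer than two usable genes is an error for the network builder.
* Module extraction generalizes the manual removal of a dense unrelated
  cluster around one seed to a declarative exclude list; no automatic dense
  cluster detector is attempted because no quantitative definition exists for
  it in the source protocol.

## Problem sizes used by the test suite

The suite and the acceptance script run on corpora of 30–42 genes, 50–250
ontology terms, interactomes of 40–300 edges, 100-subset null calibrations at
1000 Mann-Whitney runs each, and 5–20 ROC replicates — sizes chosen so the
statistical checks have adequate power while the whole suite completes in
about a minute on one CPU. The published-table audits are exact arithmetic
and run in milliseconds.

## A worked example

```{r example, eval = FALSE}
library(pathosim)

spec <- synthetic_spec(seed = 7)
dag  <- generate_ontology(spec)
dis  <- generate_diseasome(spec)
ann  <- generate_annotations(dis, dag, spec)

pruned <- prune_excluded(dag, ann)
prop   <- propagate_annotations(pruned$dag, pruned$annotations)
ic     <- compute_ic(pruned$dag, prop)

simnet <- all_pairs_network(pruned$annotations, ic, pruned$dag)
thr    <- percentile_threshold(simnet, 98)
glance(thr)

proj <- project_unipartite(dis)
compare_networks(proj, as_gene_network(thr$retained))
```

## Known limitations

Only `is_a` edges are parsed (no other relationship types, no obsolete-term
replacement); Lin and Jiang–Conrath term similarities are not implemented;
disease–disease projections are out of scope; identifier normalization
between database namespaces is the caller's responsibility — all IDs are
opaque strings. The Youden-J threshold scan stands in for an unpublished
supplementary classification procedure and is flagged as such in its
documentation.
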