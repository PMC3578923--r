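# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's internals (no dag$anc): ancestors are recomputed from the
# raw edge list by iterated joins, similarities by explicit double loops.

# toy DAG:          root
#                  /    \
#                 a      b
#               /  \      \
#             a1    a2     b1
#                     \   /
#                      c        (c has two parents: a2 and b1)
toy_dag <- function() {
  ontology_dag(
    terms = c("root", "a", "b", "a1", "a2", "b1", "c"),
    edges = tibble::tibble(
      child  = c("a", "b", "a1", "a2", "b1", "c", "c"),
      parent = c("root", "root", "a", "a", "b", "a2", "b1")
    )
  )
}

# corpus on the toy DAG: 4 genes with hand-chosen direct annotations
toy_corpus <- function() {
  ann <- tibble::tibble(
    gene_id = c("g1", "g2", "g2", "g3", "g4"),
    term_id = c("a1", "a1", "a2", "c", "b1")
  )
  dag <- toy_dag()
  prop <- propagate_annotations(dag, ann)
  list(dag = dag, direct = ann, propagated = prop,
       ic = compute_ic(dag, prop))
}

# ancestor closure by iterated joins over the raw edge list (self included)
oracle_ancestors <- function(edges, term) {
  anc <- term
  repeat {
    more <- unique(edges$parent[edges$child %in% anc])
    new <- setdiff(more, anc)
    if (length(new) == 0) return(anc)
    anc <- c(anc, new)
  }
}

oracle_resnik <- function(dag, ic, t1, t2) {
  shared <- intersect(oracle_ancestors(dag$edges, t1),
                      oracle_ancestors(dag$edges, t2))
  vals <- ic$ic[ic$term_id %in% shared]
  if (length(vals) == 0) 0 else max(vals)
}

oracle_one_sided <- function(dag, ic, s1, s2) {
  mean(vapply(s1, function(t1) {
    max(vapply(s2, function(t2) oracle_resnik(dag, ic, t1, t2), numeric(1)))
  }, numeric(1)))
}

# Kahn's algorithm: returns TRUE iff the child->parent edge set is acyclic
oracle_is_acyclic <- function(terms, edges) {
  indeg <- stats::setNames(rep(0L, length(terms)), terms)
  cnt <- table(edges$parent)
  indeg[names(cnt)] <- as.integer(cnt)
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  edges_left <- edges
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- edges_left$parent[edges_left$child == v]
    edges_left <- edges_left[edges_left$child != v, ]
    for (p in out) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0) queue <- c(queue, p)
    }
  }
  seen == length(terms)
}

sorted_edge_keys <- function(net) {
  ed <- as_gene_network(net)$edges
  sort(paste(ed$gene_a, ed$gene_b))
}

# small reproducible similarity corpus built by the synthetic generators
synthetic_corpus <- function(seed = 42, ...) {
  spec <- synthetic_spec(seed = seed, ...)
  dag <- generate_ontology(spec)
  dis <- generate_diseasome(spec)
  ann <- generate_annotations(dis, dag, spec)
  pr <- prune_excluded(dag, ann)
  prop <- propagate_annotations(pr$dag, pr$annotations)
  ic <- compute_ic(pr$dag, prop)
  list(spec = spec, dag = pr$dag, diseasome = dis, direct = pr$annotations,
       propagated = prop, ic = ic)
}
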