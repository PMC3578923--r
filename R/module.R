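# Disease-module extraction around seed genes, shared-pathophenotype
# reports, and overlay/subtraction of interactome edges.

#' Extract a disease module around seed genes
#'
#' Retrieves every similarity edge touching at least one seed gene, after
#' dropping edges with an endpoint in an explicit exclude list (the
#' declarative replacement for manually removing a dense unrelated cluster,
#' e.g. one dragged in by a highly pleiotropic seed). Module members are the
#' endpoints of the retained edges plus the seeds themselves.
#'
#' @param simnet A `sim_edges` tibble (columns `gene_a`, `gene_b`, `score`).
#' @param seeds Character vector of seed gene IDs (non-empty).
#' @param exclude Character vector of gene IDs to drop entirely.
#' @return A `disease_module`: list with `seeds`, `members`, `edges`
#'   (similarity edges with scores), `excluded`.
#' @export
extract_module <- function(simnet, seeds, exclude = character()) {
  simnet <- tibble::as_tibble(simnet)
  if (length(seeds) == 0) stop("seeds must be non-empty", call. = FALSE)
  present <- intersect(seeds, unique(c(simnet$gene_a, simnet$gene_b)))
  if (length(present) == 0) {
    warning("no seed gene present in the similarity network", call. = FALSE)
  }
  keep <- (simnet$gene_a %in% seeds | simnet$gene_b %in% seeds) &
    !(simnet$gene_a %in% exclude) & !(simnet$gene_b %in% exclude)
  edges <- simnet[keep, ]
  members <- union(seeds, unique(c(edges$gene_a, edges$gene_b)))
  structure(
    list(seeds = seeds, members = members, edges = edges, excluded = exclude),
    class = "disease_module"
  )
}

#' @export
print.disease_module <- function(x, ...) {
  cat("<disease_module> ", length(x$seeds), " seed(s), ", length(x$members),
      " member(s), ", nrow(x$edges), " similarity edge(s)\n", sep = "")
  invisible(x)
}

#' Pathophenotypes shared by two genes
#'
#' Intersects the two genes' propagated annotation sets and reduces the
#' intersection to its most specific terms. Working on propagated sets lets
#' ancestor-level sharing count: two genes annotated with different specific
#' abnormalities of the same organ system still share the systemic term.
#'
#' @param g1,g2 Gene IDs.
#' @param annotations Propagated annotations (tibble `gene_id`, `term_id`),
#'   as from [propagate_annotations()].
#' @param dag An [ontology_dag()].
#' @return Character vector of shared term IDs at maximal specificity.
#' @export
shared_pathophenotypes <- function(g1, g2, annotations, dag) {
  annotations <- tibble::as_tibble(annotations)
  s1 <- annotations$term_id[annotations$gene_id == g1]
  s2 <- annotations$term_id[annotations$gene_id == g2]
  if (length(s1) == 0) stop("gene not annotated: ", g1, call. = FALSE)
  if (length(s2) == 0) stop("gene not annotated: ", g2, call. = FALSE)
  most_specific_terms(dag, intersect(s1, s2))
}

#' Overlay an interactome on similarity edges and subtract known networks
#'
#' Intersects the similarity edges with an interactome, then removes every
#' edge present in any of the networks to subtract (e.g. the unipartite
#' disease-gene projections) — leaving the pairs that are biomolecularly and
#' pathophenotypically related yet absent from the inferred disease
#' networks.
#'
#' @param simnet_edges A `sim_edges` tibble (scores preserved).
#' @param interactome A `gene_network` (or edge tibble).
#' @param subtract_nets List of `gene_network`s (or edge tibbles) whose
#'   edges are removed from the intersection. Default: none.
#' @return A tibble of surviving edges with their similarity scores.
#' @export
overlay_and_subtract <- function(simnet_edges, interactome,
                                 subtract_nets = list()) {
  simnet_edges <- tibble::as_tibble(simnet_edges)
  interactome <- as_gene_network(interactome)
  keys <- edge_key(simnet_edges)
  keep <- keys %in% edge_key(interactome$edges)
  for (net in subtract_nets) {
    keep <- keep & !(keys %in% edge_key(as_gene_network(net)$edges))
  }
  simnet_edges[keep, ]
}
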