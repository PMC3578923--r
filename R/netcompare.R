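# Edge-intersection statistics between two gene networks, with a
# hypergeometric significance model and a degree-preserving swap null.

#' Restrict two networks to their common nodes
#'
#' Before comparing networks of very different sizes, both are filtered to
#' the intersection of their node sets: only edges with both endpoints in the
#' shared node set survive, and nodes left without edges are dropped from
#' that network's node list. The two filtered networks can therefore report
#' different node counts.
#'
#' @param reference,query `gene_network`s (or edge tibbles).
#' @return A list with elements `reference` and `query` (filtered
#'   `gene_network`s).
#' @export
restrict_to_common_nodes <- function(reference, query) {
  reference <- as_gene_network(reference)
  query <- as_gene_network(query)
  common <- intersect(reference$nodes, query$nodes)
  if (length(common) == 0) stop("empty node intersection", call. = FALSE)
  filt <- function(net) {
    ed <- net$edges[net$edges$gene_a %in% common &
                      net$edges$gene_b %in% common, ]
    gene_network(ed)  # nodes = endpoints only; edge-less nodes dropped
  }
  list(reference = filt(reference), query = filt(query))
}

comparison_report <- function(N, Q, R, obs, label_reference = "reference",
                              label_query = "query") {
  M <- if (is.na(N)) NA_real_ else N * (N - 1) / 2
  union_edges <- Q + R - obs
  p_ok <- !is.na(M) && M >= 1 && R <= M && Q <= M
  p <- if (p_ok) {
    stats::phyper(obs - 1, R, M - R, Q, lower.tail = FALSE)
  } else {
    NA_real_
  }
  log10_p <- if (p_ok) {
    stats::phyper(obs - 1, R, M - R, Q, lower.tail = FALSE,
                  log.p = TRUE) / log(10)
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    reference = label_reference, query = label_query,
    n_nodes_union = as.numeric(N), max_edges = M,
    n_edges_query = Q, n_edges_reference = R,
    observed_intersection = obs, union_edges = union_edges,
    expected_intersection = if (!is.na(M) && M >= 1) Q * R / M else NA_real_,
    perc_query = if (Q > 0) 100 * obs / Q else NA_real_,
    perc_reference = if (R > 0) 100 * obs / R else NA_real_,
    jaccard = if (union_edges > 0) obs / union_edges else NA_real_,
    p_value = p, log10_p_value = log10_p
  )
  class(out) <- c("net_compare", class(out))
  out
}

#' Compare two gene networks by edge intersection
#'
#' Counts shared edges (unordered node pairs; weights ignored) between a
#' reference and a query network and derives the intersection statistics:
#' with `N` nodes in the union of the two node sets, `M = N(N-1)/2` possible
#' edges, `R` reference and `Q` query edges and `obs` shared edges —
#' expected intersection `E = Q*R/M`, the percentages `100*obs/Q` and
#' `100*obs/R`, the Jaccard coefficient `obs/(Q+R-obs)`, and the upper-tail
#' hypergeometric probability of drawing at least `obs` reference edges when
#' `Q` of the `M` possible edges are drawn without replacement
#' (`P(X >= obs)`, inclusive).
#'
#' Isolated nodes are not structural and are ignored: node counts come from
#' edge endpoints. Apply [restrict_to_common_nodes()] first when the two
#' networks differ a lot in size.
#'
#' @param reference,query `gene_network`s (or edge tibbles).
#' @param label_reference,label_query Names carried into the report.
#' @return A one-row `net_compare` tibble; see [comparison_from_counts()]
#'   for the column meanings. `log10_p_value` supplements `p_value` where
#'   the tail underflows double precision.
#' @export
compare_networks <- function(reference, query,
                             label_reference = "reference",
                             label_query = "query") {
  reference <- as_gene_network(reference)
  query <- as_gene_network(query)
  ref_nodes <- unique(c(reference$edges$gene_a, reference$edges$gene_b))
  qry_nodes <- unique(c(query$edges$gene_a, query$edges$gene_b))
  N <- length(union(ref_nodes, qry_nodes))
  R <- nrow(reference$edges)
  Q <- nrow(query$edges)
  obs <- length(intersect(edge_key(reference$edges), edge_key(query$edges)))
  comparison_report(N, Q, R, obs, label_reference, label_query)
}

#' Intersection statistics from summary counts
#'
#' Computes every derived quantity of [compare_networks()] directly from the
#' four counts that determine them, without the edge lists themselves —
#' useful to audit published intersection tables.
#'
#' @param n_nodes_union Nodes in the union of the two networks (`N`); may be
#'   `NA` when only edge-level statistics are wanted.
#' @param n_edges_query,n_edges_reference Edge counts `Q` and `R`.
#' @param observed_intersection Shared edge count.
#' @param ... Labels passed to the report.
#' @return A one-row `net_compare` tibble: union/max edge counts, expected
#'   intersection, mutual coverage percentages, Jaccard coefficient and
#'   hypergeometric p-value (`NA` where `N` is missing).
#' @export
comparison_from_counts <- function(n_nodes_union = NA, n_edges_query,
                                   n_edges_reference, observed_intersection,
                                   ...) {
  comparison_report(n_nodes_union, n_edges_query, n_edges_reference,
                    observed_intersection, ...)
}

#' Degree-preserving network randomization
#'
#' Randomizes a simple graph by repeated double-edge swaps: two edges
#' `a–b`, `c–d` are replaced by `a–d`, `c–b` (endpoints paired at random),
#' rejecting any swap that would create a self-loop or a duplicate edge.
#' Every node keeps its exact degree, so the randomized network serves as a
#' connectivity-preserving null model for intersection statistics and ROC
#' validation.
#'
#' @param net A `gene_network` (or edge tibble).
#' @param n_swaps Number of swap attempts; default `10 * |E|`, enough mixing
#'   at the scales used here. Must be non-negative.
#' @param seed Optional integer seed for reproducibility (local to this
#'   call; the global RNG state is restored).
#' @return A `gene_network` with the same node set and degree sequence.
#' @export
randomize_preserving_degrees <- function(net, n_swaps = NULL, seed = NULL) {
  net <- as_gene_network(net)
  m <- nrow(net$edges)
  if (is.null(n_swaps)) n_swaps <- 10L * m
  if (n_swaps < 0) stop("n_swaps must be >= 0", call. = FALSE)
  if (m < 2 || n_swaps == 0) return(net)

  run <- function() {
    a <- net$edges$gene_a; b <- net$edges$gene_b
    seen <- new.env(hash = TRUE, size = m * 2L)
    for (k in seq_len(m)) assign(paste(a[k], b[k], sep = "\r"), TRUE, seen)
    key <- function(x, y) paste(min(x, y), max(x, y), sep = "\r")
    for (s in seq_len(n_swaps)) {
      ij <- sample.int(m, 2)
      i <- ij[1]; j <- ij[2]
      # two rewirings are possible; pick one at random
      if (stats::runif(1) < 0.5) {
        na1 <- a[i]; nb1 <- b[j]; na2 <- a[j]; nb2 <- b[i]
      } else {
        na1 <- a[i]; nb1 <- a[j]; na2 <- b[i]; nb2 <- b[j]
      }
      if (na1 == nb1 || na2 == nb2) next
      k1 <- key(na1, nb1); k2 <- key(na2, nb2)
      if (k1 == k2) next
      if (exists(k1, seen, inherits = FALSE) ||
            exists(k2, seen, inherits = FALSE)) next
      rm(list = c(key(a[i], b[i]), key(a[j], b[j])), envir = seen)
      assign(k1, TRUE, seen); assign(k2, TRUE, seen)
      a[i] <- min(na1, nb1); b[i] <- max(na1, nb1)
      a[j] <- min(na2, nb2); b[j] <- max(na2, nb2)
    }
    gene_network(tibble::tibble(gene_a = a, gene_b = b), nodes = net$nodes)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
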