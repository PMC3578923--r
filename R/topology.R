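# Degree tables, the 1000-run resampled Mann-Whitney protocol, Spearman
# degree correlations, and per-gene annotation/similarity profiles.

#' Node degrees of a gene network
#'
#' @param net A `gene_network` (or edge tibble). Isolated nodes in the
#'   network's node list get degree 0.
#' @return A tibble with columns `gene_id`, `degree`.
#' @export
degree_table <- function(net) {
  net <- as_gene_network(net)
  counts <- table(c(net$edges$gene_a, net$edges$gene_b))
  deg <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  deg[names(counts)] <- as.integer(counts)
  tibble::tibble(gene_id = names(deg), degree = unname(deg)) |>
    dplyr::arrange(.data$gene_id)
}

#' Resampled Mann-Whitney test of a gene subset against its population
#'
#' Rather than a single subset-versus-rest test, the subset's values are
#' compared against repeated random samples of the population: each run
#' draws, without replacement, a sample of the same size as the subset from
#' the full population (the subset's own values are not excluded — the
#' subset is part of the pathophenome it is compared against), applies a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test of subset versus draw,
#' and the mean of the per-run p-values is reported. Under the null (subset
#' drawn from the same distribution) the per-run p-values are roughly
#' uniform, so the mean sits near 0.5; a planted shift drives it toward 0.
#'
#' @param subset_values Numeric values of the gene subset (non-empty).
#' @param population_values Numeric values of the whole population; must be
#'   at least as long as `subset_values`.
#' @param n_runs Number of resampling runs (default 1000).
#' @param seed Optional integer seed (local to this call).
#' @return A list with `mean_p`, `p_values` (length `n_runs`), `n_subset`,
#'   `n_population`, `n_runs`.
#' @export
resampled_mannwhitney <- function(subset_values, population_values,
                                  n_runs = 1000, seed = NULL) {
  subset_values <- as.numeric(subset_values)
  population_values <- as.numeric(population_values)
  if (length(subset_values) == 0) stop("empty subset", call. = FALSE)
  if (length(subset_values) > length(population_values)) {
    stop("subset larger than population", call. = FALSE)
  }
  n <- length(subset_values)
  run <- function() {
    vapply(seq_len(n_runs), function(i) {
      draw <- sample(population_values, n, replace = FALSE)
      stats::wilcox.test(subset_values, draw, exact = FALSE,
                         correct = TRUE)$p.value
    }, numeric(1))
  }
  ps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(mean_p = mean(ps), p_values = ps, n_subset = n,
       n_population = length(population_values), n_runs = n_runs)
}

#' Spearman rank correlation between two per-gene maps
#'
#' Correlates two named numeric vectors (e.g. degrees in two networks, or
#' annotation count versus mean similarity) over their shared genes.
#'
#' @param map_a,map_b Named numeric vectors (names are gene IDs), or
#'   two-column tibbles (`gene_id`, value).
#' @return A list with `rho`, `p_value`, `n` (shared genes).
#' @export
spearman_degree_correlation <- function(map_a, map_b) {
  as_map <- function(x) {
    if (is.data.frame(x)) stats::setNames(as.numeric(x[[2]]), x[[1]]) else x
  }
  map_a <- as_map(map_a); map_b <- as_map(map_b)
  shared <- intersect(names(map_a), names(map_b))
  if (length(shared) < 3) stop("need >= 3 shared genes", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(map_a[shared], map_b[shared], method = "spearman",
                    alternative = "two.sided", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}

#' Per-gene topology and annotation profiles
#'
#' One row per gene: its degree in each supplied network, the number of
#' specific terms in its direct annotation set (after reduction to most
#' specific terms), and the mean similarity score of its incident edges in
#' the similarity network (NA for genes without incident edges).
#'
#' @param annotations Direct annotations (tibble `gene_id`, `term_id`).
#' @param dag An [ontology_dag()].
#' @param simnet A `sim_edges` tibble (columns `gene_a`, `gene_b`, `score`).
#' @param nets Named list of `gene_network`s (or edge tibbles); one degree
#'   column `degree_<name>` is emitted per entry.
#' @return A tibble keyed by `gene_id` with columns `n_specific_terms`,
#'   `mean_similarity`, and the per-network degree columns.
#' @export
gene_profiles <- function(annotations, dag, simnet, nets = list()) {
  annotations <- dplyr::distinct(tibble::as_tibble(annotations))
  simnet <- tibble::as_tibble(simnet)

  spec_counts <- annotations |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_specific_terms = length(most_specific_terms(dag, .data$term_id))
    )

  incident <- dplyr::bind_rows(
    tibble::tibble(gene_id = simnet$gene_a, score = simnet$score),
    tibble::tibble(gene_id = simnet$gene_b, score = simnet$score)
  ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_similarity = mean(.data$score))

  out <- dplyr::full_join(spec_counts, incident, by = "gene_id")
  for (nm in names(nets)) {
    deg <- degree_table(nets[[nm]])
    names(deg)[2] <- paste0("degree_", nm)
    out <- dplyr::left_join(out, deg, by = "gene_id")
  }
  dplyr::arrange(out, .data$gene_id)
}
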