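# Gene-to-gene semantic similarity and similarity-network construction.
#
# Scores are computed on each gene's most specific term set; the propagated
# sets enter only the IC frequencies. All functions accept the IC table as a
# tibble (term_id, ic) from compute_ic().

ic_lookup <- function(ic) stats::setNames(ic$ic, ic$term_id)

# pairwise Resnik matrix for two term vectors, given the dag ancestor index
resnik_matrix <- function(dag, ic_vec, ts1, ts2) {
  out <- matrix(0, length(ts1), length(ts2), dimnames = list(ts1, ts2))
  for (i in seq_along(ts1)) {
    a1 <- dag$anc[[ts1[i]]]
    for (j in seq_along(ts2)) {
      shared <- intersect(a1, dag$anc[[ts2[j]]])
      shared <- shared[shared %in% names(ic_vec)]
      if (length(shared) > 0) out[i, j] <- max(ic_vec[shared])
    }
  }
  out
}

check_term_sets <- function(g1_terms, g2_terms, dag, ic_vec) {
  if (length(g1_terms) == 0 || length(g2_terms) == 0) {
    stop("gene term sets must be non-empty", call. = FALSE)
  }
  missing <- setdiff(c(g1_terms, g2_terms), names(dag$anc))
  if (length(missing) > 0) {
    stop("unknown term ID(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  missing_ic <- setdiff(c(g1_terms, g2_terms), names(ic_vec))
  if (length(missing_ic) > 0) {
    stop("term(s) without IC entry: ",
         paste(utils::head(missing_ic, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' One-sided best-match-average gene similarity
#'
#' For each term of the first gene, find its best Resnik match among the
#' second gene's terms, then average these |g1| best matches. Not symmetric
#' in general: the two genes' term sets play different roles.
#'
#' @param g1_terms,g2_terms Character vectors of term IDs (non-empty; reduce
#'   with [most_specific_terms()] first, as the network builder does).
#' @param ic IC table from [compute_ic()].
#' @param dag An [ontology_dag()].
#' @return A single non-negative score.
#' @export
sim_one_sided <- function(g1_terms, g2_terms, ic, dag) {
  ic_vec <- ic_lookup(ic)
  check_term_sets(g1_terms, g2_terms, dag, ic_vec)
  m <- resnik_matrix(dag, ic_vec, unique(g1_terms), unique(g2_terms))
  mean(apply(m, 1, max))
}

#' Symmetric best-match-average gene similarity
#'
#' The arithmetic mean of the two one-sided best-match averages
#' ([sim_one_sided()] in both directions): the symmetric measure proposed for
#' comparing phenotypic profiles annotated in HPO. This is the score used to
#' build the pathophenotypic similarity gene network.
#'
#' @inheritParams sim_one_sided
#' @return A single non-negative score, symmetric in its gene arguments.
#' @export
sim_symmetric <- function(g1_terms, g2_terms, ic, dag) {
  (sim_one_sided(g1_terms, g2_terms, ic, dag) +
     sim_one_sided(g2_terms, g1_terms, ic, dag)) / 2
}

#' Maximum-pair (funSim-max) gene similarity
#'
#' The maximum Resnik similarity over all term pairs between the two genes.
#' Used for functional similarity networks built from process annotations.
#'
#' @inheritParams sim_one_sided
#' @return A single non-negative score, symmetric in its gene arguments.
#' @export
funsim_max <- function(g1_terms, g2_terms, ic, dag) {
  ic_vec <- ic_lookup(ic)
  check_term_sets(g1_terms, g2_terms, dag, ic_vec)
  max(resnik_matrix(dag, ic_vec, unique(g1_terms), unique(g2_terms)))
}

#' All-pairs gene similarity network
#'
#' Scores every unordered pair of annotated genes and keeps the pairs with
#' similarity strictly greater than zero. Each gene's direct annotation set
#' is first reduced to its most specific terms; genes left with an empty set
#' (e.g. after branch pruning) are skipped.
#'
#' @param annotations Direct annotations (tibble `gene_id`, `term_id`),
#'   typically post-[prune_excluded()].
#' @param ic IC table from [compute_ic()] on the propagated sets.
#' @param dag An [ontology_dag()].
#' @param metric `"symmetric_avg"` (default; [sim_symmetric()]) or
#'   `"funsim_max"` ([funsim_max()]).
#' @return A `sim_edges` tibble with columns `gene_a`, `gene_b`, `score`
#'   (positive scores only, `gene_a < gene_b`, sorted by descending score)
#'   and attribute `metric`.
#' @export
all_pairs_network <- function(annotations, ic, dag,
                              metric = c("symmetric_avg", "funsim_max")) {
  metric <- match.arg(metric)
  stopifnot(inherits(dag, "onto_dag"))
  annotations <- dplyr::distinct(tibble::as_tibble(annotations))
  ic_vec <- ic_lookup(ic)

  sets <- annotations |>
    dplyr::filter(.data$term_id %in% names(ic_vec)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(terms = list(most_specific_terms(dag, .data$term_id)))
  sets <- sets[lengths(sets$terms) > 0, ]
  genes <- sets$gene_id
  if (length(genes) < 2) {
    stop("need at least 2 annotated genes with usable terms", call. = FALSE)
  }
  term_sets <- stats::setNames(sets$terms, genes)

  # one Resnik matrix over the union of specific terms, then best-match folds
  all_terms <- unique(unlist(term_sets, use.names = FALSE))
  tmat <- resnik_matrix(dag, ic_vec, all_terms, all_terms)

  pair_idx <- utils::combn(length(genes), 2)
  score_pair <- function(i, j) {
    ti <- term_sets[[i]]; tj <- term_sets[[j]]
    sub <- tmat[ti, tj, drop = FALSE]
    if (metric == "funsim_max") return(max(sub))
    (mean(apply(sub, 1, max)) + mean(apply(sub, 2, max))) / 2
  }
  scores <- vapply(seq_len(ncol(pair_idx)), function(k) {
    score_pair(pair_idx[1, k], pair_idx[2, k])
  }, numeric(1))

  ga <- genes[pair_idx[1, ]]; gb <- genes[pair_idx[2, ]]
  swap <- ga > gb
  out <- tibble::tibble(
    gene_a = ifelse(swap, gb, ga),
    gene_b = ifelse(swap, ga, gb),
    score = scores
  ) |>
    dplyr::filter(.data$score > 0) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_a, .data$gene_b)
  attr(out, "metric") <- metric
  class(out) <- c("sim_edges", class(out))
  out
}

#' Percentile threshold of a similarity network
#'
#' Keeps the top slice of the positive-score distribution: the cutoff is the
#' empirical `percentile`-th percentile of the scores and every pair scoring
#' at or above it is retained (ties at the cutoff all survive, so the
#' retained count can exceed the nominal share). The similarity network is
#' built at the 98th percentile (top 2 %); denser annotation corpora such as
#' process-level similarity call for 99.5 (top 0.5 %).
#'
#' @param edges A `sim_edges` tibble (columns `gene_a`, `gene_b`, `score`).
#' @param percentile Percentile in (0, 100); default 98.
#' @return A `threshold_result`: list with `percentile`, `cutoff_score`,
#'   `n_input`, `retained` (the retained `sim_edges` tibble).
#' @export
percentile_threshold <- function(edges, percentile = 98) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0) stop("empty edge list", call. = FALSE)
  if (!(percentile > 0 && percentile < 100)) {
    stop("percentile must be in (0, 100)", call. = FALSE)
  }
  cutoff <- unname(stats::quantile(edges$score, percentile / 100, type = 7))
  retained <- edges |>
    dplyr::filter(.data$score >= cutoff) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_a, .data$gene_b)
  structure(
    list(percentile = percentile, cutoff_score = cutoff,
         n_input = nrow(edges), retained = retained,
         all_scores = edges$score),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> percentile ", x$percentile, ", cutoff ",
      signif(x$cutoff_score, 6), ": retained ", nrow(x$retained), " of ",
      x$n_input, " pairs (",
      sprintf("%.2f%%", 100 * nrow(x$retained) / x$n_input), ")\n", sep = "")
  invisible(x)
}

#' Optimal score cutoff from known positive pairs
#'
#' Treats a reference set of known gene pairs as positives and every other
#' scored pair as a negative, scans all distinct scores as candidate cutoffs
#' and returns the one maximizing Youden's J (sensitivity + specificity - 1).
#' An alternative to the fixed percentile when a trusted positive set exists.
#'
#' @param edges A `sim_edges` tibble.
#' @param known_pairs Tibble with columns `gene_a`, `gene_b`: the positive
#'   pairs (order within a pair is ignored).
#' @param criterion Only `"youden"` is implemented.
#' @return A list with `cutoff`, `j` (Youden's J at the cutoff),
#'   `sensitivity`, `specificity`, and the scanned `candidates` tibble.
#' @export
optimize_threshold <- function(edges, known_pairs, criterion = "youden") {
  criterion <- match.arg(criterion)
  edges <- tibble::as_tibble(edges)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pos_keys <- unique(key(known_pairs$gene_a, known_pairs$gene_b))
  lab <- key(edges$gene_a, edges$gene_b) %in% pos_keys
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0) {
    stop("need both positive and negative pairs among the scored edges",
         call. = FALSE)
  }
  cand <- sort(unique(edges$score))
  stats_at <- function(cut) {
    pred <- edges$score >= cut
    sens <- sum(pred & lab) / n_pos
    spec <- sum(!pred & !lab) / n_neg
    c(sens = sens, spec = spec, j = sens + spec - 1)
  }
  grid <- t(vapply(cand, stats_at, numeric(3)))
  best <- which.max(grid[, "j"])
  list(cutoff = cand[best], j = unname(grid[best, "j"]),
       sensitivity = unname(grid[best, "sens"]),
       specificity = unname(grid[best, "spec"]),
       candidates = tibble::tibble(cutoff = cand,
                                   sensitivity = grid[, "sens"],
                                   specificity = grid[, "spec"],
                                   j = grid[, "j"]))
}

#' Kernel density of similarity scores
#'
#' Gaussian kernel density estimate of the score distribution, at a fixed
#' bandwidth (0.01 reproduces the density plot convention used for
#' inspecting the top-2 % clustering of similarities).
#'
#' @param edges A `sim_edges` tibble (>= 2 scores).
#' @param bandwidth Positive kernel bandwidth; default 0.01.
#' @return A tibble with columns `score`, `density`.
#' @export
score_density <- function(edges, bandwidth = 0.01) {
  edges <- tibble::as_tibble(edges)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  if (nrow(edges) < 2) stop("need >= 2 scores", call. = FALSE)
  d <- stats::density(edges$score, bw = bandwidth, kernel = "gaussian")
  tibble::tibble(score = d$x, density = d$y)
}
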