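# ROC validation: do similarity scores separate real biomolecular
# interactions from degree-preserving random ones?

#' Build a labeled score set for ROC validation
#'
#' True positives are the similarity-network edges also present in the
#' interactome, scored by their similarity. False positives are
#' similarity-network edges shared with a degree-preserving randomization of
#' the interactome, excluding any pair that is a real interactome edge (a
#' real interaction is never a false positive). Randomization is repeated
#' (fresh swaps each round) until at least as many false positives as true
#' positives have accumulated, then the false-positive set is truncated to
#' exactly the true-positive count (1:1 proportionality).
#'
#' @param simnet A `sim_edges` tibble (columns `gene_a`, `gene_b`, `score`).
#' @param interactome A `gene_network` (or edge tibble).
#' @param seed Optional integer seed (local to this call).
#' @param max_rounds Safety cap on randomization rounds (default 200).
#' @return A `labeled_scores` tibble with columns `gene_a`, `gene_b`,
#'   `score`, `label` (`"TP"`/`"FP"`), and attributes `n_tp`, `n_rounds`.
#' @export
build_validation_set <- function(simnet, interactome, seed = NULL,
                                 max_rounds = 200) {
  simnet <- tibble::as_tibble(simnet)
  interactome <- as_gene_network(interactome)
  sim_keys <- edge_key(simnet)
  int_keys <- edge_key(interactome$edges)

  tp <- simnet[sim_keys %in% int_keys, ]
  if (nrow(tp) == 0) stop("no true positives: similarity network and ",
                          "interactome share no edges", call. = FALSE)

  collect_fp <- function() {
    fp_keys <- character()
    rounds <- 0L
    while (length(fp_keys) < nrow(tp) && rounds < max_rounds) {
      rounds <- rounds + 1L
      rnd <- randomize_preserving_degrees(interactome)
      hit <- sim_keys %in% edge_key(rnd$edges) & !(sim_keys %in% int_keys)
      fp_keys <- union(fp_keys, sim_keys[hit])
    }
    if (length(fp_keys) < nrow(tp)) {
      stop("could not accumulate enough false positives after ",
           rounds, " randomization rounds", call. = FALSE)
    }
    # deterministic truncation to the TP count: keep first-found order
    list(keys = fp_keys[seq_len(nrow(tp))], rounds = rounds)
  }
  fp_res <- if (is.null(seed)) collect_fp() else withr::with_seed(seed, collect_fp())
  fp <- simnet[match(fp_res$keys, sim_keys), ]

  out <- dplyr::bind_rows(
    dplyr::mutate(tp[, c("gene_a", "gene_b", "score")], label = "TP"),
    dplyr::mutate(fp[, c("gene_a", "gene_b", "score")], label = "FP")
  )
  attr(out, "n_tp") <- nrow(tp)
  attr(out, "n_rounds") <- fp_res$rounds
  class(out) <- c("labeled_scores", class(out))
  out
}

#' ROC curve and area under it
#'
#' Sweeps every distinct score as a threshold (descending; "positive" means
#' score at or above threshold), records the false- and true-positive rates,
#' and integrates the curve by the trapezoid rule. The AUC equals the
#' probability that a random TP outscores a random FP (ties counting half),
#' i.e. the normalized Mann-Whitney U statistic.
#'
#' @param labeled A `labeled_scores` tibble (or any tibble with `score` and
#'   `label` in `{"TP","FP"}`), with at least one of each label.
#' @return A list of class `roc_result`: `curve` (tibble `threshold`, `fpr`,
#'   `tpr`, including the (0,0) and (1,1) anchor points) and `auc`.
#' @export
roc_auc <- function(labeled) {
  labeled <- tibble::as_tibble(labeled)
  pos <- labeled$score[labeled$label == "TP"]
  neg <- labeled$score[labeled$label == "FP"]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("need both TP and FP entries", call. = FALSE)
  }
  thr <- sort(unique(labeled$score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  curve <- tibble::tibble(
    threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr)
  )
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1) {
    curve <- dplyr::bind_rows(curve,
                              tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc,
                 n_tp = length(pos), n_fp = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC ", sprintf("%.4f", x$auc), " (", x$n_tp, " TP, ",
      x$n_fp, " FP)\n", sep = "")
  invisible(x)
}

#' Replicated ROC experiment against an interactome
#'
#' Repeats [build_validation_set()] + [roc_auc()] with independent
#' false-positive randomizations and averages the areas under the curves —
#' the averaged-AUC protocol used to rank interactomes by how well
#' similarity scores separate their interactions from chance.
#'
#' @param simnet A `sim_edges` tibble.
#' @param interactome A `gene_network` (or edge tibble).
#' @param n_reps Number of ROC replicates (default 20).
#' @param seed Optional integer seed; replicate r uses `seed + r` so the
#'   replicates are independent but jointly reproducible.
#' @return A list of class `roc_experiment`: `mean_auc`, `aucs` (length
#'   `n_reps`), `curves` (list of curve tibbles), `n_reps`.
#' @export
averaged_auc_experiment <- function(simnet, interactome, n_reps = 20,
                                    seed = NULL) {
  reps <- lapply(seq_len(n_reps), function(r) {
    rep_seed <- if (is.null(seed)) NULL else seed + r
    roc_auc(build_validation_set(simnet, interactome, seed = rep_seed))
  })
  structure(
    list(mean_auc = mean(vapply(reps, `[[`, numeric(1), "auc")),
         aucs = vapply(reps, `[[`, numeric(1), "auc"),
         curves = lapply(reps, `[[`, "curve"),
         n_reps = n_reps),
    class = "roc_experiment"
  )
}

#' @export
print.roc_experiment <- function(x, ...) {
  cat("<roc_experiment> mean AUC ", sprintf("%.4f", x$mean_auc), " over ",
      x$n_reps, " replicates (sd ", sprintf("%.4f", stats::sd(x$aucs)),
      ")\n", sep = "")
  invisible(x)
}

#' Compare two sets of replicate AUCs
#'
#' Two-sided Mann-Whitney test of one interactome's AUC replicates against
#' another's; used to ask whether two interactomes differ in how well
#' similarity separates their interactions from chance.
#'
#' @param aucs_a,aucs_b Numeric vectors of replicate AUCs (length >= 2).
#' @return The two-sided p-value; two identical constant vectors give 1.
#' @export
compare_auc_sets <- function(aucs_a, aucs_b) {
  if (length(aucs_a) < 2 || length(aucs_b) < 2) {
    stop("need >= 2 replicates per set", call. = FALSE)
  }
  if (length(unique(c(aucs_a, aucs_b))) == 1) return(1)
  suppressWarnings(
    stats::wilcox.test(aucs_a, aucs_b, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)$p.value
  )
}
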