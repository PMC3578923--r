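#' Construct an ontology DAG
#'
#' Builds a validated rooted directed acyclic graph of ontology terms linked
#' by `is_a` edges (child to parent). The root is the unique term without a
#' parent. Branches rooted at terms that carry no phenotypic meaning (for HPO:
#' "Mode of inheritance", "Clinical modifier" and the like) can be marked as
#' excluded; [prune_excluded()] removes them and everything reachable only
#' through them.
#'
#' @param terms A tibble with columns `term_id` and `name`, or a character
#'   vector of term IDs (names default to the IDs).
#' @param edges A tibble with columns `child` and `parent` (both term IDs).
#'   May have zero rows for a single-term ontology.
#' @param excluded_roots Character vector of term IDs marking the roots of
#'   excluded branches. Must be direct or indirect members of `terms`.
#' @return An object of class `onto_dag`: a list with elements `terms`
#'   (tibble), `edges` (tibble), `root` (term ID), `excluded_roots`, and a
#'   precomputed ancestor index used by the similarity functions.
#' @examples
#' dag <- ontology_dag(
#'   terms = c("HP:0000001", "HP:0000002", "HP:0000003"),
#'   edges = tibble::tibble(
#'     child  = c("HP:0000002", "HP:0000003"),
#'     parent = c("HP:0000001", "HP:0000002")
#'   )
#' )
#' dag$root
#' @export
ontology_dag <- function(terms, edges, excluded_roots = character()) {
  if (is.character(terms)) {
    terms <- tibble::tibble(term_id = terms, name = terms)
  }
  stopifnot(all(c("term_id", "name") %in% names(terms)))
  terms <- tibble::as_tibble(terms)[, c("term_id", "name")]
  if (anyDuplicated(terms$term_id)) {
    stop("duplicated term IDs in ontology", call. = FALSE)
  }
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(child = character(), parent = character())
  }
  stopifnot(all(c("child", "parent") %in% names(edges)))
  edges <- edges[, c("child", "parent")]

  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$term_id)
  if (length(unknown) > 0) {
    stop("is_a edge refers to unknown term ID(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = terms$term_id)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    involved <- unique(unlist(lapply(cyc, function(e) {
      igraph::ends(g, e)
    })))
    stop("ontology contains a cycle involving term(s): ",
         paste(utils::head(involved, 3), collapse = ", "), call. = FALSE)
  }
  roots <- terms$term_id[!(terms$term_id %in% edges$child)]
  if (length(roots) != 1) {
    stop("ontology must have exactly one root, found ", length(roots), ": ",
         paste(utils::head(roots, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(excluded_roots %in% terms$term_id)) {
    stop("excluded_roots contains unknown term ID(s)", call. = FALSE)
  }

  # ancestor closure (each term is its own ancestor), indexed once: the IC
  # propagation, MICA search and specific-term reduction all walk it.
  anc <- lapply(igraph::V(g), function(v) {
    names(igraph::subcomponent(g, v, mode = "out"))
  })
  names(anc) <- terms$term_id

  structure(
    list(terms = terms, edges = edges, root = roots,
         excluded_roots = excluded_roots, anc = anc),
    class = "onto_dag"
  )
}

#' @export
print.onto_dag <- function(x, ...) {
  cat("<onto_dag> ", nrow(x$terms), " terms, ", nrow(x$edges),
      " is_a edges, root ", x$root, sep = "")
  if (length(x$excluded_roots) > 0) {
    cat(", ", length(x$excluded_roots), " excluded branch root(s)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Ancestors of a set of terms
#'
#' @param dag An [ontology_dag()].
#' @param term_ids Character vector of term IDs.
#' @param include_self Count each term as its own ancestor (the convention
#'   used by the Resnik common-ancestor set)? Default `TRUE`.
#' @return Character vector of ancestor term IDs (unique, unordered).
#' @export
term_ancestors <- function(dag, term_ids, include_self = TRUE) {
  stopifnot(inherits(dag, "onto_dag"))
  missing <- setdiff(term_ids, names(dag$anc))
  if (length(missing) > 0) {
    stop("unknown term ID(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  out <- unique(unlist(dag$anc[term_ids], use.names = FALSE))
  if (!include_self) out <- setdiff(out, term_ids)
  out
}

#' Read a minimal-dialect OBO ontology
#'
#' Parses `[Term]` stanzas with `id:`, `name:` and `is_a:` keys (all other
#' keys and stanza types are ignored). `is_a` targets may carry the usual
#' `! name` comment suffix. Terms whose name matches one of
#' `excluded_branch_names` (case-insensitive) are recorded as excluded branch
#' roots for later pruning.
#'
#' @param path Path to an OBO file, or a character vector of its lines.
#' @param excluded_branch_names Character vector of branch names to flag as
#'   excluded (default: the non-phenotypic HPO branches "mode of inheritance"
#'   and "onset and clinical course").
#' @return An [ontology_dag()].
#' @export
load_ontology <- function(path,
                          excluded_branch_names = c("mode of inheritance",
                                                    "onset and clinical course")) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)

  in_term <- FALSE
  cur <- NULL
  ids <- character(); nms <- character()
  e_child <- character(); e_parent <- character()
  flush <- function() {
    if (!is.null(cur) && !is.na(cur$id)) {
      ids <<- c(ids, cur$id)
      nms <<- c(nms, if (is.na(cur$name)) cur$id else cur$name)
      if (length(cur$is_a) > 0) {
        e_child <<- c(e_child, rep(cur$id, length(cur$is_a)))
        e_parent <<- c(e_parent, cur$is_a)
      }
    }
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur <- list(id = NA_character_, name = NA_character_, is_a = character())
    } else if (grepl("^\\[", ln)) {
      flush(); in_term <- FALSE; cur <- NULL
    } else if (in_term && grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^name:", ln)) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      target <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$is_a <- c(cur$is_a, target)
    }
  }
  flush()
  if (length(ids) == 0) stop("no [Term] stanzas found", call. = FALSE)

  terms <- tibble::tibble(term_id = ids, name = nms)
  edges <- tibble::tibble(child = e_child, parent = e_parent)
  excl <- terms$term_id[tolower(terms$name) %in% tolower(excluded_branch_names)]
  ontology_dag(terms, edges, excluded_roots = excl)
}

#' Read a long-format gene-to-term annotation table
#'
#' Expects two tab-separated columns, `gene_id` and `term_id`, in the layout
#' of HPO's gene-to-phenotype exports. Lines starting with `#` are comments.
#' Extra columns are ignored; duplicate rows are dropped.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_id`, `term_id`.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) stop("annotation file needs >= 2 columns", call. = FALSE)
  df <- drop_header_row(df, c("gene_id", "term_id"))
  dplyr::distinct(tibble::tibble(gene_id = df[[1]], term_id = df[[2]]))
}

#' Remove excluded ontology branches from a DAG and its annotations
#'
#' A term is dropped when every path from it to the root passes through an
#' excluded branch root; terms that keep at least one clean path survive
#' (multi-parent terms straddling an excluded and a kept branch are kept).
#' Dropped terms are also removed from the annotation table. Genes whose
#' annotation set becomes empty are retained in the output with zero rows and
#' reported in the `emptied_genes` attribute so that the similarity stage can
#' skip them without losing corpus bookkeeping.
#'
#' @param dag An [ontology_dag()] with `excluded_roots` set (possibly empty).
#' @param annotations Tibble with columns `gene_id`, `term_id` (direct
#'   annotations).
#' @return A list with elements `dag` (pruned [ontology_dag()]) and
#'   `annotations` (pruned tibble, with attribute `emptied_genes`).
#' @export
prune_excluded <- function(dag, annotations) {
  stopifnot(inherits(dag, "onto_dag"))
  annotations <- tibble::as_tibble(annotations)
  if (length(dag$excluded_roots) == 0) {
    attr(annotations, "emptied_genes") <- character()
    return(list(dag = dag, annotations = annotations))
  }

  # a term survives iff it reaches the root without visiting an excluded root
  keep_edges <- dag$edges[!(dag$edges$parent %in% dag$excluded_roots) &
                            !(dag$edges$child %in% dag$excluded_roots), ]
  g <- igraph::graph_from_data_frame(
    keep_edges, directed = TRUE,
    vertices = setdiff(dag$terms$term_id, dag$excluded_roots)
  )
  reach <- names(igraph::subcomponent(g, dag$root, mode = "in"))
  kept <- dag$terms[dag$terms$term_id %in% reach, ]
  kept_edges <- dag$edges[dag$edges$child %in% reach &
                            dag$edges$parent %in% reach, ]
  new_dag <- ontology_dag(kept, kept_edges, excluded_roots = character())

  genes_before <- unique(annotations$gene_id)
  pruned <- annotations[annotations$term_id %in% reach, ]
  emptied <- setdiff(genes_before, unique(pruned$gene_id))
  attr(pruned, "emptied_genes") <- emptied
  list(dag = new_dag, annotations = pruned)
}

#' Propagate direct annotations up the ontology
#'
#' Expands each gene's direct term set with all ancestors of its terms (the
#' "true-path rule"). Frequency-based information content is computed on these
#' propagated sets so that the root is annotated to every gene and IC is
#' monotone along `is_a` edges.
#'
#' @param dag An [ontology_dag()].
#' @param annotations Tibble with columns `gene_id`, `term_id`.
#' @return Tibble with columns `gene_id`, `term_id` — the propagated
#'   (ancestor-closed) annotation sets.
#' @export
propagate_annotations <- function(dag, annotations) {
  stopifnot(inherits(dag, "onto_dag"))
  annotations <- tibble::as_tibble(annotations)
  missing <- setdiff(unique(annotations$term_id), names(dag$anc))
  if (length(missing) > 0) {
    stop("annotation uses unknown term ID(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  annotations |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::reframe(term_id = term_ancestors(dag, unique(.data$term_id))) |>
    dplyr::distinct()
}

#' Information content of ontology terms
#'
#' For each term annotated to at least one gene, the annotation probability
#' is its gene frequency over the annotated corpus,
#' \eqn{p(t) = n_t / n_{genes}}, computed on propagated annotation sets, and
#' the information content is \eqn{IC(t) = -\ln p(t)} (in nats). The root,
#' being annotated to every gene after propagation, has IC 0; IC never
#' decreases from a term to its descendants. Terms annotated to no gene get
#' no row.
#'
#' @param dag An [ontology_dag()].
#' @param annotations Propagated annotations (tibble `gene_id`, `term_id`),
#'   as returned by [propagate_annotations()].
#' @return A tibble with columns `term_id`, `n_genes`, `p`, `ic`.
#' @export
compute_ic <- function(dag, annotations) {
  stopifnot(inherits(dag, "onto_dag"))
  annotations <- dplyr::distinct(tibble::as_tibble(annotations))
  n_corpus <- dplyr::n_distinct(annotations$gene_id)
  if (n_corpus == 0) stop("no annotated genes; cannot compute IC", call. = FALSE)
  annotations |>
    dplyr::count(.data$term_id, name = "n_genes") |>
    dplyr::mutate(p = .data$n_genes / n_corpus, ic = -log(.data$p)) |>
    dplyr::arrange(dplyr::desc(.data$ic))
}

#' Resnik similarity of two terms
#'
#' The information content of the most informative common ancestor (MICA):
#' the maximum IC over the shared ancestor set of the two terms, each term
#' counting as its own ancestor. Symmetric and non-negative; two terms whose
#' only shared ancestor is the root score 0.
#'
#' @param dag An [ontology_dag()].
#' @param ic An IC table from [compute_ic()].
#' @param t1,t2 Term IDs.
#' @return A single non-negative similarity score (nats).
#' @export
resnik_term_similarity <- function(dag, ic, t1, t2) {
  stopifnot(inherits(dag, "onto_dag"))
  ic_vec <- stats::setNames(ic$ic, ic$term_id)
  for (t in c(t1, t2)) {
    if (!(t %in% names(dag$anc))) stop("unknown term: ", t, call. = FALSE)
    if (!(t %in% names(ic_vec))) {
      stop("term has no IC entry (not annotated in corpus): ", t, call. = FALSE)
    }
  }
  shared <- intersect(dag$anc[[t1]], dag$anc[[t2]])
  shared <- shared[shared %in% names(ic_vec)]
  if (length(shared) == 0) return(0)
  max(ic_vec[shared])
}

#' Reduce a term set to its most specific members
#'
#' Drops every term that is a proper ancestor of another member, leaving the
#' terms farthest from the root. Gene similarity is computed on these reduced
#' sets: ancestor terms carry no extra information once a descendant is
#' present. Idempotent.
#'
#' @param dag An [ontology_dag()].
#' @param term_set Character vector of term IDs.
#' @return Character vector: the subset with no member an ancestor of another.
#' @export
most_specific_terms <- function(dag, term_set) {
  stopifnot(inherits(dag, "onto_dag"))
  term_set <- unique(term_set)
  if (length(term_set) <= 1) return(term_set)
  missing <- setdiff(term_set, names(dag$anc))
  if (length(missing) > 0) {
    stop("unknown term ID(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  # strict ancestors of any member are dominated
  strict_anc <- unique(unlist(
    lapply(term_set, function(t) setdiff(dag$anc[[t]], t)),
    use.names = FALSE
  ))
  setdiff(term_set, strict_anc)
}
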