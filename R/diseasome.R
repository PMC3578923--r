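# Bipartite disease-gene tables, their unipartite gene projections, and the
# four-class gene classification crossing disease genicity with gene tropy.

# unordered-pair identity, independent of the endpoints' column order
edge_key <- function(edges) {
  paste(pmin(edges$gene_a, edges$gene_b),
        pmax(edges$gene_a, edges$gene_b), sep = "\r")
}

#' Construct a gene network
#'
#' A simple undirected graph over gene IDs: an edge tibble plus an optional
#' set of isolated (edge-less) nodes. Edges are canonicalized (self-loops
#' dropped, duplicates merged, endpoints sorted within each pair).
#'
#' @param edges Tibble whose first two columns are gene IDs (conventionally
#'   `gene_a`, `gene_b`); extra columns such as `score` are preserved on the
#'   canonical rows.
#' @param nodes Optional character vector of all node IDs; genes listed here
#'   but absent from `edges` become isolated nodes.
#' @return A `gene_network`: list with `edges` (tibble), `nodes` (character),
#'   `isolated` (character).
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    extra <- edges[, -(1:2), drop = FALSE]
    keep <- a != b
    ed <- tibble::tibble(gene_a = pmin(a[keep], b[keep]),
                         gene_b = pmax(a[keep], b[keep]))
    ed <- dplyr::bind_cols(ed, extra[keep, , drop = FALSE])
    ed <- ed[!duplicated(edge_key(ed)), ]
  } else {
    ed <- tibble::tibble(gene_a = character(), gene_b = character())
  }
  connected <- unique(c(ed$gene_a, ed$gene_b))
  nodes <- if (is.null(nodes)) connected else unique(as.character(nodes))
  structure(
    list(edges = ed, nodes = union(nodes, connected),
         isolated = setdiff(nodes, connected)),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges", sep = "")
  if (length(x$isolated) > 0) cat(" (", length(x$isolated), " isolated)", sep = "")
  cat("\n")
  invisible(x)
}

#' Coerce to a gene network
#' @param x A `gene_network`, an edge tibble, or a `sim_edges` tibble.
#' @param ... Passed to [gene_network()].
#' @return A `gene_network`.
#' @export
as_gene_network <- function(x, ...) {
  if (inherits(x, "gene_network")) return(x)
  gene_network(x, ...)
}

#' Read a two-column TSV edge list or disease-gene table
#'
#' `#`-prefixed comment lines are skipped. Returns the first two columns
#' under the supplied names.
#'
#' @param path Path to a TSV file.
#' @param col_names Names for the two columns (default `gene_a`, `gene_b`;
#'   use `c("disease_id", "gene_id")` for diseasome tables).
#' @return A tibble with two character columns.
#' @export
read_edgelist <- function(path, col_names = c("gene_a", "gene_b")) {
  df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2) stop("edge list needs >= 2 columns", call. = FALSE)
  df <- drop_header_row(df, col_names)
  out <- tibble::tibble(a = df[[1]], b = df[[2]])
  names(out) <- col_names
  dplyr::distinct(out)
}

#' Unipartite gene projection of a disease-gene table
#'
#' Links two genes whenever they share at least one disease: each disease
#' with k genes contributes a k-clique, and the union of these cliques (after
#' de-duplication) is the disease-causing gene network. Genes associated only
#' with diseases of their own (no co-association) carry no edge; they are
#' reported as isolated nodes, which downstream comparisons drop as
#' non-structural.
#'
#' @param diseasome Tibble with columns `disease_id`, `gene_id`.
#' @return A [gene_network()] whose `nodes` cover every associated gene and
#'   whose `isolated` set lists the genes without any co-association.
#' @export
project_unipartite <- function(diseasome) {
  diseasome <- dplyr::distinct(tibble::as_tibble(diseasome))
  if (nrow(diseasome) == 0) stop("empty diseasome", call. = FALSE)
  cliques <- diseasome |>
    dplyr::group_by(.data$disease_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(pair = list({
      g <- sort(unique(.data$gene_id))
      idx <- utils::combn(length(g), 2)
      tibble::tibble(gene_a = g[idx[1, ]], gene_b = g[idx[2, ]])
    })) |>
    tidyr::unnest("pair")
  edges <- if (nrow(cliques) > 0) {
    dplyr::distinct(cliques[, c("gene_a", "gene_b")])
  } else {
    tibble::tibble(gene_a = character(), gene_b = character())
  }
  gene_network(edges, nodes = unique(diseasome$gene_id))
}

#' Classify genes by disease genicity and gene tropy
#'
#' A gene is monotropic when associated with exactly one disease, pleiotropic
#' otherwise; a disease is monogenic when associated with exactly one gene,
#' polygenic otherwise. Crossing the two criteria yields four classes:
#' * `MD-MG` — monotropic gene whose single disease is monogenic (the
#'   "bi-univocal" one-to-one associations);
#' * `PD-MG` — monotropic gene whose single disease is polygenic;
#' * `MD-PG` — pleiotropic gene with at least one monogenic disease;
#' * `PD-PG` — pleiotropic gene with at least one polygenic disease.
#' The monotropic classes are exclusive; a pleiotropic gene can sit in both
#' pleiotropic classes at once.
#'
#' @param diseasome Tibble with columns `disease_id`, `gene_id`.
#' @return A tibble with one row per gene: `gene_id`, `n_diseases`,
#'   `monotropy` (`"monotropic"`/`"pleiotropic"`), logical class columns
#'   `MD_MG`, `MD_PG`, `PD_MG`, `PD_PG`, and `classes` (comma-joined labels).
#' @export
classify_genes <- function(diseasome) {
  diseasome <- dplyr::distinct(tibble::as_tibble(diseasome))
  if (nrow(diseasome) == 0) stop("empty diseasome", call. = FALSE)
  dis_size <- diseasome |> dplyr::count(.data$disease_id, name = "n_genes")
  df <- diseasome |>
    dplyr::left_join(dis_size, by = "disease_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_diseases = dplyr::n(),
      any_monogenic = any(.data$n_genes == 1),
      any_polygenic = any(.data$n_genes > 1)
    ) |>
    dplyr::mutate(
      monotropy = ifelse(.data$n_diseases == 1, "monotropic", "pleiotropic"),
      MD_MG = .data$n_diseases == 1 & .data$any_monogenic,
      PD_MG = .data$n_diseases == 1 & .data$any_polygenic,
      MD_PG = .data$n_diseases > 1 & .data$any_monogenic,
      PD_PG = .data$n_diseases > 1 & .data$any_polygenic
    )
  lab <- c("MD-MG", "MD-PG", "PD-MG", "PD-PG")
  mat <- as.matrix(df[, c("MD_MG", "MD_PG", "PD_MG", "PD_PG")])
  df$classes <- apply(mat, 1, function(r) paste(lab[r], collapse = ","))
  df |>
    dplyr::select("gene_id", "n_diseases", "monotropy",
                  "MD_MG", "MD_PG", "PD_MG", "PD_PG", "classes") |>
    dplyr::arrange(.data$gene_id)
}

#' Class-level summary of a disease-gene table
#'
#' For each of the four association classes: gene count, percentage of all
#' associated genes, and the diseases-per-gene ratio (distinct diseases
#' touched by the class's genes divided by the class's gene count — the only
#' reading under which a polygenic-disease class can score below 1, since
#' one shared disease then serves many genes). Optional named gene lists
#' (e.g. essential or metabolic genes) add per-class overlap counts and
#' within-class percentages.
#'
#' @param diseasome Tibble with columns `disease_id`, `gene_id`.
#' @param labels Output of [classify_genes()] on the same table (computed if
#'   missing).
#' @param gene_lists Optional named list of character vectors of gene IDs.
#'   Genes unknown to the diseasome trigger a warning and are ignored.
#' @return A tibble with one row per class (plus an `all` row): `class`,
#'   `n_genes`, `pct_genes`, `diseases_per_gene`, and for each gene list `L`
#'   columns `L_n` and `L_pct`.
#' @export
subset_stats <- function(diseasome, labels = NULL, gene_lists = list()) {
  diseasome <- dplyr::distinct(tibble::as_tibble(diseasome))
  if (is.null(labels)) labels <- classify_genes(diseasome)
  n_all <- nrow(labels)
  gene_dis <- split(diseasome$disease_id, diseasome$gene_id)

  cls <- c(MD_MG = "MD-MG", MD_PG = "MD-PG", PD_MG = "PD-MG", PD_PG = "PD-PG")
  rows <- purrr::map2(names(cls), cls, function(col, name) {
    genes <- labels$gene_id[labels[[col]]]
    n <- length(genes)
    ratio <- if (n == 0) NA_real_ else {
      length(unique(unlist(gene_dis[genes], use.names = FALSE))) / n
    }
    tibble::tibble(class = name, n_genes = n,
                   pct_genes = 100 * n / n_all, diseases_per_gene = ratio)
  })
  all_row <- tibble::tibble(
    class = "all", n_genes = n_all, pct_genes = 100,
    diseases_per_gene = dplyr::n_distinct(diseasome$disease_id) / n_all
  )
  out <- dplyr::bind_rows(rows, all_row)

  for (nm in names(gene_lists)) {
    lst <- unique(gene_lists[[nm]])
    unknown <- setdiff(lst, labels$gene_id)
    if (length(unknown) > 0) {
      warning(length(unknown), " gene(s) in list '", nm,
              "' not in diseasome; ignored", call. = FALSE)
      lst <- setdiff(lst, unknown)
    }
    counts <- vapply(seq_len(nrow(out)), function(i) {
      genes <- if (out$class[i] == "all") labels$gene_id else {
        labels$gene_id[labels[[names(cls)[match(out$class[i], cls)]]]]
      }
      length(intersect(genes, lst))
    }, integer(1))
    out[[paste0(nm, "_n")]] <- counts
    out[[paste0(nm, "_pct")]] <- ifelse(out$n_genes > 0,
                                        100 * counts / out$n_genes, NA_real_)
  }
  out
}
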