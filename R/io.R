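# Plain-text writers paired with the readers: minimal-dialect OBO for
# ontologies, 2/3-column TSV for diseasomes, annotations and edge lists.
# Every TSV starts with '#'-prefixed provenance comment lines.

# files written by write_tsv_commented carry a column-name line; files in
# the bare two-column layout (e.g. HPO exports) do not — tolerate both
drop_header_row <- function(df, expected_names) {
  if (nrow(df) > 0 &&
        all(tolower(unlist(df[1, seq_along(expected_names)])) ==
              tolower(expected_names))) {
    df <- df[-1, ]
  }
  df
}

tsv_header <- function(what, provenance = character()) {
  c(paste0("# pathosim ", as.character(utils::packageVersion("pathosim")),
           " - ", what),
    paste0("# ", provenance))
}

#' Write an ontology as minimal-dialect OBO
#'
#' Emits one `[Term]` stanza per term with `id:`, `name:` and `is_a:` lines
#' — the dialect [load_ontology()] reads back.
#'
#' @param dag An [ontology_dag()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "onto_dag"))
  parents <- split(dag$edges$parent, dag$edges$child)
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$term_id[i]
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", dag$terms$name[i]))
    for (p in parents[[id]]) lines <- c(lines, paste0("is_a: ", p))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a table as TSV with provenance comments
#'
#' @param df A data frame (written without quoting, tab-separated, with a
#'   column-name line after the comments).
#' @param path Output file path.
#' @param what Short description placed in the first comment line.
#' @param provenance Extra comment lines (e.g. `seed=...`).
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(df, path, what = "table",
                                provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(what, provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene network as a TSV edge list
#'
#' @param net A `gene_network` (or edge tibble).
#' @param path Output file path.
#' @param provenance Extra comment lines.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path, provenance = character()) {
  net <- as_gene_network(net)
  write_tsv_commented(net$edges, path, what = "edge list",
                      provenance = provenance)
}
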