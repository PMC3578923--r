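# End-to-end orchestration: ontology + annotations + diseasome +
# interactomes in, one artifact directory of TSV reports out.

#' Pipeline configuration
#'
#' Bundles the input paths and the tunables of a full analysis run. All
#' stages are reproducible from the single `seed`; every output file carries
#' the seed and a configuration hash in its comment header.
#'
#' @param ontology_path OBO file ([load_ontology()] dialect).
#' @param annotations_path Gene-to-term TSV ([read_annotations()] layout).
#' @param diseasome_path Disease-gene TSV.
#' @param interactome_paths Named character vector/list of edge-list TSVs.
#' @param percentile Similarity-network percentile cutoff; default 98 (use
#'   99.5 for dense functional-similarity corpora).
#' @param n_runs Resampling runs for the Mann-Whitney protocol;
#'   default 1000.
#' @param roc_reps ROC replicates per interactome; default 20.
#' @param seed Integer seed; default 1.
#' @param excluded_branch_names Ontology branches pruned before analysis.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ontology_path, annotations_path, diseasome_path,
                            interactome_paths = character(),
                            percentile = 98, n_runs = 1000, roc_reps = 20,
                            seed = 1L,
                            excluded_branch_names = c("mode of inheritance",
                                                      "onset and clinical course")) {
  if (!(percentile > 0 && percentile < 100)) {
    stop("percentile must be in (0, 100)", call. = FALSE)
  }
  structure(
    list(ontology_path = ontology_path, annotations_path = annotations_path,
         diseasome_path = diseasome_path,
         interactome_paths = as.list(interactome_paths),
         percentile = percentile, n_runs = n_runs, roc_reps = roc_reps,
         seed = as.integer(seed),
         excluded_branch_names = excluded_branch_names),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — ontology loading and branch pruning,
#' annotation propagation, information content, similarity network and
#' percentile threshold, unipartite diseasome projection and gene
#' classification, per-interactome comparison reports (observed network and
#' one degree-preserving randomized control each), topology statistics
#' (gene profiles, resampled Mann-Whitney per class, Spearman degree
#' correlations), and ROC validation per interactome — writing one TSV per
#' stage into `out_dir`. A stage failure aborts with the stage name and
#' cause. Outputs are byte-identical across runs with the same
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(paste0("seed=", config$seed),
            paste0("percentile=", config$percentile),
            paste0("config_hash=", rlang::hash(unclass(config))))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(f) file.path(out_dir, f)
  res <- list()

  res$ontology <- stage("ontology", {
    dag <- load_ontology(config$ontology_path,
                         excluded_branch_names = config$excluded_branch_names)
    ann <- read_annotations(config$annotations_path)
    pruned <- prune_excluded(dag, ann)
    prop <- propagate_annotations(pruned$dag, pruned$annotations)
    ic <- compute_ic(pruned$dag, prop)
    write_tsv_commented(ic, out("ic_table.tsv"), "information content", prov)
    list(dag = pruned$dag, direct = pruned$annotations, propagated = prop,
         ic = ic)
  })

  res$simnet <- stage("similarity network", {
    edges <- all_pairs_network(res$ontology$direct, res$ontology$ic,
                               res$ontology$dag, metric = "symmetric_avg")
    thr <- percentile_threshold(edges, config$percentile)
    write_tsv_commented(thr$retained, out("similarity_network.tsv"),
                        "thresholded similarity network", prov)
    write_tsv_commented(
      tibble::tibble(percentile = thr$percentile,
                     cutoff_score = thr$cutoff_score,
                     n_input_pairs = thr$n_input,
                     n_retained = nrow(thr$retained)),
      out("threshold_report.tsv"), "threshold report", prov)
    thr
  })

  res$diseasome <- stage("diseasome", {
    tab <- read_edgelist(config$diseasome_path,
                         col_names = c("disease_id", "gene_id"))
    proj <- project_unipartite(tab)
    labels <- classify_genes(tab)
    stats_tab <- subset_stats(tab, labels)
    write_edgelist(proj, out("unipartite_projection.tsv"), prov)
    write_tsv_commented(labels, out("gene_classes.tsv"), "gene classes", prov)
    write_tsv_commented(stats_tab, out("class_stats.tsv"), "class summary", prov)
    list(table = tab, projection = proj, labels = labels, stats = stats_tab)
  })

  interactomes <- lapply(config$interactome_paths, read_edgelist)
  res$interactomes <- lapply(interactomes, as_gene_network)

  res$comparisons <- stage("network comparison", {
    sim_net <- as_gene_network(res$simnet$retained)
    reports <- purrr::imap(res$interactomes, function(net, nm) {
      both <- restrict_to_common_nodes(sim_net, net)
      obs <- compare_networks(both$reference, both$query,
                              label_reference = "similarity_network",
                              label_query = nm)
      rnd <- randomize_preserving_degrees(both$query,
                                          seed = config$seed + 7L)
      ctl <- compare_networks(both$reference, rnd,
                              label_reference = "similarity_network",
                              label_query = paste0(nm, "_randomized"))
      dplyr::bind_rows(obs, ctl)
    })
    if (length(reports) > 0) {
      tab <- dplyr::bind_rows(reports)
      write_tsv_commented(tab, out("comparison_reports.tsv"),
                          "network comparison", prov)
      tab
    } else {
      NULL
    }
  })

  res$topology <- stage("topology", {
    profiles <- gene_profiles(res$ontology$direct, res$ontology$dag,
                              res$simnet$retained,
                              nets = c(list(projection = res$diseasome$projection),
                                       res$interactomes))
    write_tsv_commented(profiles, out("gene_profiles.tsv"), "gene profiles",
                        prov)
    sim_deg <- degree_table(as_gene_network(res$simnet$retained))
    pop <- stats::setNames(sim_deg$degree, sim_deg$gene_id)
    labels <- res$diseasome$labels
    cls <- c(MD_MG = "MD-MG", MD_PG = "MD-PG", PD_MG = "PD-MG",
             PD_PG = "PD-PG")
    tests <- purrr::imap(cls, function(name, col) {
      genes <- intersect(labels$gene_id[labels[[col]]], names(pop))
      if (length(genes) == 0) return(NULL)
      mw <- resampled_mannwhitney(pop[genes], unname(pop),
                                  n_runs = config$n_runs,
                                  seed = config$seed + 11L)
      tibble::tibble(subset = name, n_genes = length(genes),
                     mean_p = mw$mean_p)
    })
    tests <- dplyr::bind_rows(tests)
    write_tsv_commented(tests, out("topology_tests.tsv"),
                        "resampled Mann-Whitney", prov)
    cors <- purrr::imap(res$interactomes, function(net, nm) {
      deg <- degree_table(net)
      ct <- tryCatch(
        spearman_degree_correlation(pop,
                                    stats::setNames(deg$degree, deg$gene_id)),
        error = function(e) NULL)
      if (is.null(ct)) return(NULL)
      tibble::tibble(network = nm, rho = ct$rho, p_value = ct$p_value,
                     n_shared = ct$n)
    })
    cors <- dplyr::bind_rows(cors)
    write_tsv_commented(cors, out("degree_correlations.tsv"),
                        "Spearman degree correlations", prov)
    list(profiles = profiles, tests = tests, correlations = cors)
  })

  res$roc <- stage("roc", {
    rocs <- purrr::imap(res$interactomes, function(net, nm) {
      exp <- tryCatch(
        averaged_auc_experiment(res$simnet$retained, net,
                                n_reps = config$roc_reps,
                                seed = config$seed + 13L),
        error = function(e) NULL)
      if (is.null(exp)) return(NULL)
      tibble::tibble(network = nm, mean_auc = exp$mean_auc,
                     sd_auc = stats::sd(exp$aucs), n_reps = exp$n_reps)
    })
    rocs <- dplyr::bind_rows(rocs)
    write_tsv_commented(rocs, out("roc_summary.tsv"), "ROC validation", prov)
    rocs
  })

  invisible(res)
}
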