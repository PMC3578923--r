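# Synthetic ontologies, diseasomes, annotations and interactomes with known
# ground truth. Every generator draws from its own seed stream (an offset of
# the spec seed), so stages can be regenerated independently and a fixed
# spec yields identical outputs on every run and platform.

SEED_ONTOLOGY <- 101L
SEED_DISEASOME <- 202L
SEED_ANNOTATION <- 303L
SEED_INTERACTOME <- 404L

EXCLUDED_BRANCH_POOL <- c("Mode of inheritance", "Onset and clinical course",
                          "Clinical modifier", "Frequency",
                          "Blood group", "Past medical history")

#' Specification for the synthetic data generators
#'
#' Collects every knob of the synthetic corpus in one validated object. The
#' defaults describe a small but structured study corpus: a 120-term
#' ontology shaped like HPO (one root, one phenotypic-abnormality branch,
#' two excluded non-phenotypic branches), a diseasome with all four
#' association classes populated, 2-6 ontology terms per disease, and an
#' interactome filled at random around whatever edges are planted.
#'
#' @param seed Integer master seed; each generator derives its own stream
#'   from it.
#' @param n_terms Total ontology terms including the root (>=
#'   `1 + n_excluded_branches`).
#' @param max_children Maximum children per term during growth.
#' @param depth Maximum depth of the term tree (root = depth 0).
#' @param n_excluded_branches Number of non-phenotypic branches hung off the
#'   root and flagged for pruning.
#' @param class_counts Named counts of planted genes per association class:
#'   `MD_MG`, `MD_PG`, `PD_MG`, `PD_PG` (all >= 0).
#' @param terms_per_disease Length-2 integer range (min >= 1): terms drawn
#'   per disease.
#' @param interactome_degree_sequence Optional integer degree sequence for
#'   [generate_interactome()].
#' @param planted_overlap_fraction Fraction in `[0, 1]` of similarity edges
#'   copied into the interactome before random filling.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_terms = 120L,
                           max_children = 5L,
                           depth = 6L,
                           n_excluded_branches = 2L,
                           class_counts = c(MD_MG = 10, MD_PG = 6,
                                            PD_MG = 8, PD_PG = 6),
                           terms_per_disease = c(2L, 6L),
                           interactome_degree_sequence = NULL,
                           planted_overlap_fraction = 0) {
  stopifnot(length(seed) == 1, is.finite(seed))
  seed <- as.integer(seed)
  cc <- class_counts
  if (!all(c("MD_MG", "MD_PG", "PD_MG", "PD_PG") %in% names(cc))) {
    stop("class_counts needs names MD_MG, MD_PG, PD_MG, PD_PG", call. = FALSE)
  }
  cc <- as.integer(cc[c("MD_MG", "MD_PG", "PD_MG", "PD_PG")])
  names(cc) <- c("MD_MG", "MD_PG", "PD_MG", "PD_PG")
  if (any(cc < 0)) stop("class_counts must be >= 0", call. = FALSE)
  if (n_terms < 1 + n_excluded_branches) {
    stop("n_terms must be >= 1 + n_excluded_branches", call. = FALSE)
  }
  if (n_excluded_branches > length(EXCLUDED_BRANCH_POOL)) {
    stop("at most ", length(EXCLUDED_BRANCH_POOL), " excluded branches",
         call. = FALSE)
  }
  if (length(terms_per_disease) != 2 || terms_per_disease[1] < 1 ||
        terms_per_disease[2] < terms_per_disease[1]) {
    stop("terms_per_disease must be a range c(min, max) with min >= 1",
         call. = FALSE)
  }
  if (planted_overlap_fraction < 0 || planted_overlap_fraction > 1) {
    stop("planted_overlap_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(seed = seed, n_terms = as.integer(n_terms),
         max_children = as.integer(max_children), depth = as.integer(depth),
         n_excluded_branches = as.integer(n_excluded_branches),
         class_counts = cc,
         terms_per_disease = as.integer(terms_per_disease),
         interactome_degree_sequence = interactome_degree_sequence,
         planted_overlap_fraction = planted_overlap_fraction),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic ontology DAG
#'
#' Grows a rooted DAG shaped like HPO: the root has one
#' "Phenotypic abnormality" child holding the bulk of the terms, plus
#' `n_excluded_branches` children flagged as excluded branch roots
#' (inheritance mode, clinical course, ...). Remaining terms attach to a
#' random parent within their branch, respecting the depth and fan-out
#' limits; about 15 % of terms get a second parent in the same branch, so
#' the graph is a genuine DAG rather than a tree. Term IDs follow the
#' `HP:%07d` pattern.
#'
#' @param spec A [synthetic_spec()].
#' @return An [ontology_dag()] with `excluded_roots` set.
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed + SEED_ONTOLOGY, {
    n <- spec$n_terms
    ids <- sprintf("HP:%07d", seq_len(n))
    names_vec <- paste("Synthetic term", seq_len(n))
    names_vec[1] <- "All"
    root <- ids[1]
    child <- character(); parent <- character()
    excl_roots <- character()

    nxt <- 2L
    n_excl <- spec$n_excluded_branches
    if (n_excl > 0) {
      for (b in seq_len(n_excl)) {
        excl_roots <- c(excl_roots, ids[nxt])
        names_vec[nxt] <- EXCLUDED_BRANCH_POOL[b]
        child <- c(child, ids[nxt]); parent <- c(parent, root)
        nxt <- nxt + 1L
      }
    }
    main_root <- NULL
    if (nxt <= n) {
      main_root <- ids[nxt]
      names_vec[nxt] <- "Phenotypic abnormality"
      child <- c(child, ids[nxt]); parent <- c(parent, root)
      nxt <- nxt + 1L
    }

    # growth bookkeeping: depth and child count per placed term
    depth <- stats::setNames(rep(0L, n), ids)
    kids <- stats::setNames(rep(0L, n), ids)
    branch <- stats::setNames(rep(NA_character_, n), ids)
    branch[root] <- "root"
    for (er in excl_roots) { depth[er] <- 1L; branch[er] <- er }
    if (!is.null(main_root)) { depth[main_root] <- 1L; branch[main_root] <- "main" }

    placed_main <- main_root
    placed_excl <- excl_roots
    while (nxt <= n) {
      id <- ids[nxt]
      # most terms grow the phenotypic branch; a minority pad the excluded ones
      to_excl <- length(placed_excl) > 0 &&
        (is.null(main_root) || stats::runif(1) < 0.15)
      pool <- if (to_excl) placed_excl else placed_main
      ok <- pool[depth[pool] < spec$depth & kids[pool] < spec$max_children]
      if (length(ok) == 0) ok <- pool  # relax fan-out before failing growth
      p1 <- if (length(ok) == 1) ok else sample(ok, 1)
      child <- c(child, id); parent <- c(parent, p1)
      kids[p1] <- kids[p1] + 1L
      depth[id] <- depth[p1] + 1L
      branch[id] <- branch[p1]
      # occasional second parent within the same branch keeps it a DAG
      same_branch <- if (to_excl) placed_excl else placed_main
      cand <- setdiff(same_branch[branch[same_branch] == branch[id]], p1)
      if (length(cand) > 0 && stats::runif(1) < 0.15) {
        p2 <- if (length(cand) == 1) cand else sample(cand, 1)
        child <- c(child, id); parent <- c(parent, p2)
        kids[p2] <- kids[p2] + 1L
        depth[id] <- max(depth[id], depth[p2] + 1L)
      }
      if (to_excl) placed_excl <- c(placed_excl, id) else {
        placed_main <- c(placed_main, id)
      }
      nxt <- nxt + 1L
    }

    ontology_dag(tibble::tibble(term_id = ids, name = names_vec),
                 tibble::tibble(child = child, parent = parent),
                 excluded_roots = excl_roots)
  })
}

#' Generate a bipartite diseasome with planted class counts
#'
#' Builds a disease-gene association table whose gene classification is
#' known by construction: [classify_genes()] on the output recovers
#' `spec$class_counts` exactly (with `md_pg_overlap = FALSE`). The
#' construction is: one private disease per MD-MG gene; two private
#' monogenic diseases per MD-PG gene; PD-MG genes grouped 2-3 per shared
#' disease; PD-PG genes chained through pairwise shared diseases. Counts
#' that cannot be realized exactly (a single PD-MG gene with no pleiotropic
#' partner, or a single PD-PG gene without two PD-MG partners) raise an
#' explicit error.
#'
#' @param spec A [synthetic_spec()].
#' @param md_pg_overlap If `TRUE`, MD-PG genes are additionally paired
#'   through shared polygenic diseases, so they also satisfy PD-PG (the
#'   overlap between the two pleiotropic classes); the recovered PD-PG count
#'   then exceeds the planted one by the number of overlapped genes.
#'   Default `FALSE`.
#' @return A tibble with columns `disease_id`, `gene_id`; attribute
#'   `planted_classes` maps each gene to its planted class.
#' @export
generate_diseasome <- function(spec, md_pg_overlap = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cc <- spec$class_counts
  if (cc[["PD_PG"]] == 1 && cc[["PD_MG"]] < 2) {
    stop("a single PD_PG gene needs at least two PD_MG partners",
         call. = FALSE)
  }
  consumed_pd_mg <- if (cc[["PD_PG"]] == 1) 2L else 0L
  r_pd_mg <- cc[["PD_MG"]] - consumed_pd_mg
  if (r_pd_mg == 1 && cc[["PD_PG"]] == 0) {
    stop("a single PD_MG gene needs a pleiotropic (PD_PG) partner",
         call. = FALSE)
  }
  if (md_pg_overlap && cc[["MD_PG"]] < 2) {
    stop("md_pg_overlap needs at least two MD_PG genes", call. = FALSE)
  }

  gene_ids <- sprintf("G%04d", seq_len(sum(cc)))
  planted <- rep(names(cc), cc)
  genes <- split(gene_ids, factor(planted, levels = names(cc)))

  d_id <- 0L
  new_disease <- function() {
    d_id <<- d_id + 1L
    sprintf("D%04d", d_id)
  }
  dis <- character(); gen <- character()
  add <- function(disease, gs) {
    dis <<- c(dis, rep(disease, length(gs)))
    gen <<- c(gen, gs)
  }

  for (g in genes$MD_MG) add(new_disease(), g)
  for (g in genes$MD_PG) { add(new_disease(), g); add(new_disease(), g) }

  k <- cc[["PD_PG"]]
  if (k == 1) {
    p <- genes$PD_PG[1]
    m12 <- genes$PD_MG[1:2]
    add(new_disease(), c(p, m12[1]))
    add(new_disease(), c(p, m12[2]))
  } else if (k == 2) {
    add(new_disease(), genes$PD_PG)
    add(new_disease(), genes$PD_PG)
  } else if (k >= 3) {
    for (i in seq_len(k)) {
      add(new_disease(), c(genes$PD_PG[i], genes$PD_PG[i %% k + 1]))
    }
  }

  remaining <- genes$PD_MG[setdiff(seq_len(cc[["PD_MG"]]),
                                   seq_len(consumed_pd_mg))]
  if (length(remaining) == 1) {
    add(new_disease(), c(remaining, genes$PD_PG[1]))
  } else if (length(remaining) >= 2) {
    n_r <- length(remaining)
    sizes <- if (n_r <= 4L) n_r else {
      s <- rep(3L, n_r %/% 3L)
      if (n_r %% 3L > 0L) s[length(s)] <- s[length(s)] + n_r %% 3L
      s
    }
    idx <- 1L
    for (s in sizes) {
      add(new_disease(), remaining[idx:(idx + s - 1L)])
      idx <- idx + s
    }
  }

  if (md_pg_overlap) {
    mg <- genes$MD_PG
    for (i in seq_len(length(mg) %/% 2L)) {
      add(new_disease(), mg[c(2L * i - 1L, 2L * i)])
    }
    if (length(mg) %% 2L == 1L) {
      add(new_disease(), c(mg[length(mg)], mg[1]))
    }
  }

  out <- dplyr::distinct(tibble::tibble(disease_id = dis, gene_id = gen))
  attr(out, "planted_classes") <- tibble::tibble(
    gene_id = gene_ids, class = gsub("_", "-", planted)
  )
  out
}

#' Generate annotations for a synthetic diseasome
#'
#' Assigns each disease a phenotypically coherent set of terms: a random
#' focus term is drawn from the phenotypic branch and the disease's terms
#' (count drawn from `spec$terms_per_disease`) are sampled from the focus
#' term's subtree, padded with random vocabulary when the subtree is too
#' small. Never the root, never an excluded branch. Every gene is then
#' annotated with the union of its diseases' term sets — mirroring how
#' gene-level phenotype annotations are derived from disease-level clinical
#' descriptions, and giving pleiotropic genes multi-cluster term profiles.
#'
#' @param diseasome Tibble with columns `disease_id`, `gene_id`.
#' @param dag An [ontology_dag()], e.g. from [generate_ontology()].
#' @param spec A [synthetic_spec()].
#' @return A tibble of direct gene annotations (`gene_id`, `term_id`);
#'   attribute `disease_annotations` holds the underlying disease-term
#'   table (`disease_id`, `term_id`).
#' @export
generate_annotations <- function(diseasome, dag, spec) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(dag, "onto_dag"))
  diseasome <- dplyr::distinct(tibble::as_tibble(diseasome))
  # usable vocabulary: everything that survives branch pruning, minus root
  kept <- prune_excluded(dag, tibble::tibble(gene_id = character(),
                                             term_id = character()))$dag
  vocab <- setdiff(kept$terms$term_id, kept$root)
  if (length(vocab) == 0) {
    stop("ontology has no annotatable (non-root, non-excluded) terms",
         call. = FALSE)
  }
  # descendant sets within the kept branch, for coherent per-disease foci
  desc <- lapply(vocab, function(f) {
    vocab[vapply(vocab, function(t) f %in% kept$anc[[t]], logical(1))]
  })
  names(desc) <- vocab

  withr::with_seed(spec$seed + SEED_ANNOTATION, {
    diseases <- sort(unique(diseasome$disease_id))
    rng <- spec$terms_per_disease
    sizes <- sample(seq(rng[1], rng[2]), length(diseases), replace = TRUE)
    sizes <- pmin(sizes, length(vocab))
    if (any(sizes == 0)) {
      stop("disease with zero annotated terms", call. = FALSE)
    }
    dterms <- purrr::map2(diseases, sizes, function(d, s) {
      focus <- sample(vocab, 1)
      pool <- desc[[focus]]
      terms <- sample(pool, min(s, length(pool)))
      if (length(terms) < s) {
        terms <- c(terms, sample(setdiff(vocab, terms), s - length(terms)))
      }
      tibble::tibble(disease_id = d, term_id = terms)
    }) |>
      dplyr::bind_rows()

    gene_ann <- diseasome |>
      dplyr::inner_join(dterms, by = "disease_id",
                        relationship = "many-to-many") |>
      dplyr::distinct(.data$gene_id, .data$term_id) |>
      dplyr::arrange(.data$gene_id, .data$term_id)
    attr(gene_ann, "disease_annotations") <- dterms
    gene_ann
  })
}

# Erdos-Gallai graphicality check for a degree sequence
is_graphical <- function(d) {
  d <- sort(as.integer(d), decreasing = TRUE)
  if (any(d < 0) || sum(d) %% 2 != 0) return(FALSE)
  if (length(d) == 0 || all(d == 0)) return(TRUE)
  n <- length(d)
  for (k in seq_len(n)) {
    lhs <- sum(d[seq_len(k)])
    rhs <- k * (k - 1) + if (k < n) sum(pmin(d[(k + 1):n], k)) else 0
    if (lhs > rhs) return(FALSE)
  }
  TRUE
}

#' Select similarity edges to plant into an interactome
#'
#' Draws `fraction` of the similarity network's edges (rounded, at random)
#' as the planted true-interaction set, giving downstream ROC experiments a
#' known signal.
#'
#' @param simnet A `sim_edges` tibble.
#' @param fraction Fraction in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `gene_a`, `gene_b`.
#' @export
plant_overlap_edges <- function(simnet, fraction, seed = NULL) {
  simnet <- tibble::as_tibble(simnet)
  stopifnot(fraction >= 0, fraction <= 1)
  n <- round(fraction * nrow(simnet))
  if (n == 0) return(tibble::tibble(gene_a = character(), gene_b = character()))
  pick <- function() sort(sample.int(nrow(simnet), n))
  idx <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  simnet[idx, c("gene_a", "gene_b")]
}

#' Generate a synthetic interactome
#'
#' Builds a simple undirected graph over the given genes that contains all
#' `planted_edges`. With a degree sequence in the spec, the sequence is
#' checked for graphicality (Erdos-Gallai) and realized by stub matching
#' with rejection of self-loops and duplicate edges (restarting when stuck);
#' otherwise `n_edges` total edges are drawn uniformly at random around the
#' planted ones.
#'
#' @param genes Character vector of gene IDs (the node set).
#' @param spec A [synthetic_spec()]; `interactome_degree_sequence`, when
#'   set, must have one entry per gene (in `genes` order).
#' @param planted_edges Optional tibble (`gene_a`, `gene_b`) of edges that
#'   must appear; endpoints must lie in `genes`.
#' @param n_edges Edge-count target used when no degree sequence is given
#'   (default: `2 * length(genes)`, a sparse interactome-like density).
#' @return A [gene_network()] over `genes`.
#' @export
generate_interactome <- function(genes, spec, planted_edges = NULL,
                                 n_edges = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- unique(as.character(genes))
  planted <- if (is.null(planted_edges) || nrow(planted_edges) == 0) {
    tibble::tibble(gene_a = character(), gene_b = character())
  } else {
    pe <- as_gene_network(planted_edges)$edges[, c("gene_a", "gene_b")]
    if (!all(c(pe$gene_a, pe$gene_b) %in% genes)) {
      stop("planted edge endpoints must be in the gene list", call. = FALSE)
    }
    pe
  }

  withr::with_seed(spec$seed + SEED_INTERACTOME, {
    degs <- spec$interactome_degree_sequence
    if (!is.null(degs)) {
      if (length(degs) != length(genes)) {
        stop("degree sequence length must match the gene list", call. = FALSE)
      }
      if (!is_graphical(degs)) {
        stop("degree sequence is not graphical", call. = FALSE)
      }
      realize_degseq(genes, as.integer(degs), planted)
    } else {
      if (is.null(n_edges)) n_edges <- 2L * length(genes)
      max_m <- length(genes) * (length(genes) - 1) / 2
      if (n_edges > max_m) stop("n_edges exceeds the possible pairs",
                                call. = FALSE)
      fill_random_edges(genes, planted, n_edges)
    }
  })
}

realize_degseq <- function(genes, degs, planted, max_restarts = 500) {
  target <- stats::setNames(degs, genes)
  pdeg <- table(c(planted$gene_a, planted$gene_b))
  resid <- target
  resid[names(pdeg)] <- resid[names(pdeg)] - as.integer(pdeg)
  if (any(resid < 0)) {
    stop("planted edges exceed the degree budget of some node", call. = FALSE)
  }
  planted_keys <- edge_key(planted)
  stubs <- rep(genes, resid[genes])
  if (length(stubs) %% 2 != 0) {
    stop("residual degree sequence has odd sum", call. = FALSE)
  }
  if (length(stubs) == 0) return(gene_network(planted, nodes = genes))

  for (attempt in seq_len(max_restarts)) {
    sh <- sample(stubs)
    a <- sh[seq(1, length(sh), by = 2)]
    b <- sh[seq(2, length(sh), by = 2)]
    ed <- tibble::tibble(gene_a = pmin(a, b), gene_b = pmax(a, b))
    if (any(ed$gene_a == ed$gene_b)) next
    keys <- edge_key(ed)
    if (anyDuplicated(keys) || any(keys %in% planted_keys)) next
    return(gene_network(dplyr::bind_rows(planted, ed), nodes = genes))
  }
  stop("could not realize the degree sequence around the planted edges ",
       "after ", max_restarts, " attempts", call. = FALSE)
}

fill_random_edges <- function(genes, planted, n_edges) {
  need <- n_edges - nrow(planted)
  if (need <= 0) return(gene_network(planted, nodes = genes))
  g <- sort(genes)
  idx <- utils::combn(length(g), 2)
  pool <- tibble::tibble(gene_a = g[idx[1, ]], gene_b = g[idx[2, ]])
  pool <- pool[!(edge_key(pool) %in% edge_key(planted)), ]
  if (need > nrow(pool)) stop("n_edges exceeds the possible pairs",
                              call. = FALSE)
  take <- pool[sample.int(nrow(pool), need), ]
  gene_network(dplyr::bind_rows(planted, take), nodes = genes)
}
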