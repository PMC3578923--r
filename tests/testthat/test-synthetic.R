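test_that("generated ontologies are rooted DAGs with the requested shape", {
  # degenerate: a single root
  spec1 <- synthetic_spec(seed = 1, n_terms = 1, n_excluded_branches = 0,
                          class_counts = c(MD_MG = 1, MD_PG = 0,
                                           PD_MG = 0, PD_PG = 0))
  dag1 <- generate_ontology(spec1)
  expect_equal(nrow(dag1$terms), 1)
  expect_equal(nrow(dag1$edges), 0)

  expect_error(synthetic_spec(seed = 1, n_terms = 2, n_excluded_branches = 3),
               "n_terms")

  # determinism: same spec, same seed, identical output
  spec <- synthetic_spec(seed = 9, n_terms = 50, depth = 4)
  d1 <- generate_ontology(spec)
  d2 <- generate_ontology(spec)
  expect_identical(d1$terms, d2$terms)
  expect_identical(d1$edges, d2$edges)

  # graph properties verified by an independent topological sort
  expect_true(oracle_is_acyclic(d1$terms$term_id, d1$edges))
  roots <- setdiff(d1$terms$term_id, d1$edges$child)
  expect_length(roots, 1)
  # every non-root term reaches the root
  for (t in d1$terms$term_id) {
    expect_true(roots %in% oracle_ancestors(d1$edges, t))
  }
  # exactly the requested number of excluded branch roots, children of root
  expect_length(d1$excluded_roots, 2)
  expect_true(all(d1$edges$parent[d1$edges$child %in% d1$excluded_roots] ==
                    d1$root))
  # term IDs exercise the real-format pattern
  expect_true(all(grepl("^HP:\\d{7}$", d1$terms$term_id)))
})

test_that("planted class counts round-trip through classification", {
  count_classes <- function(dis) {
    lab <- classify_genes(dis)
    c(MD_MG = sum(lab$MD_MG), MD_PG = sum(lab$MD_PG),
      PD_MG = sum(lab$PD_MG), PD_PG = sum(lab$PD_PG))
  }
  cases <- list(
    c(MD_MG = 3, MD_PG = 0, PD_MG = 0, PD_PG = 0),
    c(MD_MG = 0, MD_PG = 0, PD_MG = 4, PD_PG = 0),
    c(MD_MG = 2, MD_PG = 2, PD_MG = 2, PD_PG = 2),
    c(MD_MG = 5, MD_PG = 3, PD_MG = 7, PD_PG = 1),  # PD_PG=1 uses PD_MG partners
    c(MD_MG = 0, MD_PG = 4, PD_MG = 1, PD_PG = 3),  # PD_MG=1 uses a PD_PG partner
    c(MD_MG = 1, MD_PG = 1, PD_MG = 0, PD_PG = 5)
  )
  for (cc in cases) {
    dis <- generate_diseasome(synthetic_spec(seed = 3, class_counts = cc))
    expect_equal(count_classes(dis), cc)
  }

  # the all-MD_MG case is a bijection: n diseases, n genes, n edges
  dis3 <- generate_diseasome(synthetic_spec(
    seed = 3, class_counts = c(MD_MG = 3, MD_PG = 0, PD_MG = 0, PD_PG = 0)))
  expect_equal(nrow(dis3), 3)
  expect_equal(dplyr::n_distinct(dis3$disease_id), 3)
  expect_equal(dplyr::n_distinct(dis3$gene_id), 3)

  # a lone polygenic-disease class keeps one disease with all 4 genes
  dis4 <- generate_diseasome(synthetic_spec(
    seed = 3, class_counts = c(MD_MG = 0, MD_PG = 0, PD_MG = 4, PD_PG = 0)))
  expect_equal(dplyr::n_distinct(dis4$disease_id), 1)
  expect_equal(nrow(dis4), 4)

  # infeasible exact counts fail loudly
  expect_error(generate_diseasome(synthetic_spec(
    seed = 1, class_counts = c(MD_MG = 0, MD_PG = 0, PD_MG = 1, PD_PG = 0))),
    "partner")
  expect_error(generate_diseasome(synthetic_spec(
    seed = 1, class_counts = c(MD_MG = 0, MD_PG = 0, PD_MG = 1, PD_PG = 1))),
    "partner")

  # the overlap flag makes MD_PG genes also PD_PG
  spec_ov <- synthetic_spec(seed = 4, class_counts = c(MD_MG = 1, MD_PG = 4,
                                                       PD_MG = 2, PD_PG = 2))
  got <- count_classes(generate_diseasome(spec_ov, md_pg_overlap = TRUE))
  expect_equal(unname(got[c("MD_MG", "MD_PG", "PD_MG")]), c(1, 4, 2))
  expect_equal(unname(got["PD_PG"]), 2 + 4)
  lab_ov <- classify_genes(generate_diseasome(spec_ov, md_pg_overlap = TRUE))
  expect_gt(sum(lab_ov$MD_PG & lab_ov$PD_PG), 0)
})

test_that("gene annotations are the union of their diseases' term sets", {
  spec <- synthetic_spec(seed = 6)
  dag <- generate_ontology(spec)
  dis <- generate_diseasome(spec)
  ann <- generate_annotations(dis, dag, spec)
  dterms <- attr(ann, "disease_annotations")
  expect_gt(nrow(dterms), 0)
  # no root, no excluded-branch content
  excl_terms <- unlist(lapply(spec_excluded <- dag$excluded_roots, function(r) {
    dag$terms$term_id[vapply(dag$terms$term_id, function(t) {
      r %in% oracle_ancestors(dag$edges, t)
    }, logical(1))]
  }))
  expect_false(any(ann$term_id %in% c(dag$root, excl_terms)))
  # union property, gene by gene
  by_disease <- split(dterms$term_id, dterms$disease_id)
  for (g in unique(dis$gene_id)) {
    expected <- unique(unlist(by_disease[dis$disease_id[dis$gene_id == g]]))
    expect_setequal(ann$term_id[ann$gene_id == g], expected)
  }
  # deterministic
  expect_identical(ann, generate_annotations(dis, dag, spec))
})

test_that("interactome generation honors degree sequences and planted edges", {
  # [1, 1] is a single edge
  spec11 <- synthetic_spec(seed = 2, interactome_degree_sequence = c(1, 1))
  net11 <- generate_interactome(c("g1", "g2"), spec11)
  expect_equal(nrow(net11$edges), 1)

  # [2, 2, 2] can only be the triangle
  spec222 <- synthetic_spec(seed = 2, interactome_degree_sequence = c(2, 2, 2))
  net222 <- generate_interactome(c("g1", "g2", "g3"), spec222)
  expect_setequal(sorted_edge_keys(net222), c("g1 g2", "g1 g3", "g2 g3"))

  # non-graphical sequences fail loudly
  spec_bad <- synthetic_spec(seed = 2, interactome_degree_sequence = c(3, 1))
  expect_error(generate_interactome(c("g1", "g2"), spec_bad), "not graphical")

  # a realized random sequence matches the request exactly
  withr::with_seed(44, {
    degs <- sample(1:4, 20, replace = TRUE)
    if (sum(degs) %% 2 == 1) degs[1] <- degs[1] + 1
  })
  spec_d <- synthetic_spec(seed = 8, interactome_degree_sequence = degs)
  genes <- sprintf("g%02d", 1:20)
  net_d <- generate_interactome(genes, spec_d)
  got <- degree_table(net_d)
  expect_equal(got$degree[match(genes, got$gene_id)], degs)

  # planted edges are always contained; full overlap means containment of
  # the whole similarity slice
  sc <- synthetic_corpus(seed = 7)
  simnet <- all_pairs_network(sc$direct, sc$ic, sc$dag)
  top <- percentile_threshold(simnet, 95)$retained
  all_genes <- sort(unique(c(simnet$gene_a, simnet$gene_b)))
  planted <- plant_overlap_edges(top, 1, seed = 1)  # fraction 1: all edges
  expect_equal(nrow(planted), nrow(top))
  neti <- generate_interactome(all_genes, sc$spec, planted_edges = planted,
                               n_edges = nrow(planted) + 20)
  expect_true(all(sorted_edge_keys(gene_network(planted)) %in%
                    sorted_edge_keys(neti)))
  # determinism of the random fill
  neti2 <- generate_interactome(all_genes, sc$spec, planted_edges = planted,
                                n_edges = nrow(planted) + 20)
  expect_identical(neti$edges, neti2$edges)
})
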