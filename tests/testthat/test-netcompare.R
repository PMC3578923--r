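test_that("common-node filtering keeps only doubly-present endpoints", {
  a <- gene_network(tibble::tibble(gene_a = c("g1", "g2"),
                                   gene_b = c("g2", "g3")))
  same <- restrict_to_common_nodes(a, a)
  expect_equal(sorted_edge_keys(same$reference), sorted_edge_keys(a))
  expect_equal(sorted_edge_keys(same$query), sorted_edge_keys(a))

  b <- gene_network(tibble::tibble(gene_a = "x1", gene_b = "x2"))
  expect_error(restrict_to_common_nodes(a, b), "empty node intersection")

  withr::with_seed(41, {
    ga <- paste0("g", sample(20, 30, replace = TRUE))
    gb <- paste0("g", sample(25, 30, replace = TRUE))
    n1 <- gene_network(tibble::tibble(gene_a = ga, gene_b = gb))
    n2 <- gene_network(tibble::tibble(gene_a = sample(ga), gene_b = sample(gb)))
  })
  res <- restrict_to_common_nodes(n1, n2)
  common <- intersect(n1$nodes, n2$nodes)
  for (net in res) {
    expect_true(all(net$edges$gene_a %in% common))
    expect_true(all(net$edges$gene_b %in% common))
  }
  # every surviving edge existed in its source network
  expect_true(all(sorted_edge_keys(res$reference) %in% sorted_edge_keys(n1)))
  expect_true(all(sorted_edge_keys(res$query) %in% sorted_edge_keys(n2)))
})

test_that("comparison reports satisfy their internal identities", {
  withr::with_seed(51, {
    ref <- gene_network(tibble::tibble(
      gene_a = paste0("g", sample(15, 40, replace = TRUE)),
      gene_b = paste0("g", sample(15, 40, replace = TRUE))))
    qry <- gene_network(tibble::tibble(
      gene_a = paste0("g", sample(15, 30, replace = TRUE)),
      gene_b = paste0("g", sample(15, 30, replace = TRUE))))
  })
  rep <- compare_networks(ref, qry)
  expect_equal(rep$max_edges, rep$n_nodes_union * (rep$n_nodes_union - 1) / 2)
  expect_equal(rep$union_edges,
               rep$n_edges_query + rep$n_edges_reference -
                 rep$observed_intersection)
  expect_equal(rep$jaccard, rep$observed_intersection / rep$union_edges)
  expect_equal(rep$perc_query, 100 * rep$observed_intersection / rep$n_edges_query)
  expect_equal(rep$expected_intersection,
               rep$n_edges_query * rep$n_edges_reference / rep$max_edges)
  expect_lte(rep$observed_intersection,
             min(rep$n_edges_query, rep$n_edges_reference))

  # identical networks: full overlap
  idr <- compare_networks(ref, ref)
  expect_equal(idr$jaccard, 1)
  expect_equal(idr$perc_query, 100)
  expect_equal(idr$perc_reference, 100)

  # swapping reference and query only relabels the percentages
  sw <- compare_networks(qry, ref)
  expect_equal(sw$observed_intersection, rep$observed_intersection)
  expect_equal(sw$jaccard, rep$jaccard)
  expect_equal(sw$p_value, rep$p_value)
  expect_equal(sw$perc_query, rep$perc_reference)

  # tidy() pivots the report long
  td <- tidy(rep)
  expect_true(all(c("statistic", "value") %in% names(td)))
  expect_equal(td$value[td$statistic == "jaccard"], rep$jaccard)
})

test_that("hypergeometric tail equals exhaustive enumeration on small universes", {
  # M = 10 possible pairs, R = 4 reference edges, Q = 3 drawn, obs >= 2
  M <- 10; R <- 4; Q <- 3
  draws <- utils::combn(M, Q)
  is_ref <- seq_len(M) <= R
  tail_counts <- vapply(seq_len(ncol(draws)), function(k) {
    sum(is_ref[draws[, k]])
  }, numeric(1))
  expect_equal(mean(tail_counts >= 2), 1 / 3)  # 40 of 120 draws
  expect_equal(
    stats::phyper(2 - 1, R, M - R, Q, lower.tail = FALSE),
    1 / 3
  )
  # the full report reproduces it from edge lists: build a 5-node universe
  nodes <- paste0("n", 1:5)
  all_pairs <- t(utils::combn(nodes, 2))
  ref <- gene_network(tibble::tibble(gene_a = all_pairs[1:4, 1],
                                     gene_b = all_pairs[1:4, 2]),
                      nodes = nodes)
  qry <- gene_network(tibble::tibble(gene_a = all_pairs[c(1, 2, 7), 1],
                                     gene_b = all_pairs[c(1, 2, 7), 2]),
                      nodes = nodes)
  rep <- compare_networks(ref, qry)
  expect_equal(rep$n_nodes_union, 5)
  expect_equal(rep$observed_intersection, 2)
  expect_equal(rep$p_value, 1 / 3)
})

test_that("double-edge swaps preserve every node degree and simplicity", {
  # a single edge cannot be swapped
  single <- gene_network(tibble::tibble(gene_a = "a", gene_b = "b"))
  expect_equal(randomize_preserving_degrees(single, seed = 1)$edges,
               single$edges)

  # two disjoint edges: any accepted swap yields one of the legal rewirings
  two <- gene_network(tibble::tibble(gene_a = c("a", "c"),
                                     gene_b = c("b", "d")))
  legal <- list(c("a b", "c d"), c("a d", "b c"), c("a c", "b d"))
  withr::with_seed(6, {
    for (i in 1:10) {
      out <- sorted_edge_keys(randomize_preserving_degrees(two, n_swaps = 1))
      expect_true(any(vapply(legal, function(l) all(out == sort(l)),
                             logical(1))))
    }
  })

  # 100-node graph, 10|E| swaps: degree multiset identical, graph stays simple
  withr::with_seed(61, {
    g <- igraph::sample_gnm(100, 300)
    ed <- igraph::as_edgelist(g)
  })
  net <- gene_network(tibble::tibble(gene_a = paste0("g", ed[, 1]),
                                     gene_b = paste0("g", ed[, 2])))
  rnd <- randomize_preserving_degrees(net, seed = 62)
  d0 <- degree_table(net); d1 <- degree_table(rnd)
  expect_equal(d1$degree[match(d0$gene_id, d1$gene_id)], d0$degree)
  expect_false(any(duplicated(sorted_edge_keys(rnd))))
  expect_false(any(rnd$edges$gene_a == rnd$edges$gene_b))
  # and it actually rewired something
  expect_false(identical(sorted_edge_keys(net), sorted_edge_keys(rnd)))
  # reproducible under seed
  expect_identical(randomize_preserving_degrees(net, seed = 62)$edges,
                   rnd$edges)
  expect_error(randomize_preserving_degrees(net, n_swaps = -1), ">= 0")
})

test_that("observed intersections match the hypergeometric expectation for random queries", {
  # queries drawn uniformly from the M possible pairs follow the model exactly
  nodes <- paste0("g", 1:12)
  all_pairs <- t(utils::combn(nodes, 2))
  M <- nrow(all_pairs)
  withr::with_seed(71, {
    ref_idx <- sample(M, 20)
    ref <- gene_network(tibble::tibble(gene_a = all_pairs[ref_idx, 1],
                                       gene_b = all_pairs[ref_idx, 2]),
                        nodes = nodes)
    obs <- replicate(300, {
      q_idx <- sample(M, 15)
      qry <- gene_network(tibble::tibble(gene_a = all_pairs[q_idx, 1],
                                         gene_b = all_pairs[q_idx, 2]),
                          nodes = nodes)
      length(intersect(sorted_edge_keys(ref), sorted_edge_keys(qry)))
    })
  })
  expected <- 15 * 20 / M
  expect_equal(mean(obs), expected, tolerance = 0.05)
})
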