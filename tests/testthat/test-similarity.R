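test_that("one-sided, symmetric and max-pair similarities match hand computations", {
  co <- toy_corpus()
  # g1 = {a1}, g2' = {a1, a2}: forward similarity is ic[a1]
  expect_equal(sim_one_sided("a1", c("a1", "a2"), co$ic, co$dag), log(2))
  # reversed direction averages ic[a1] and resnik(a2, a1) = ic[a]
  rev_expected <- (log(2) + log(4 / 3)) / 2
  expect_equal(sim_one_sided(c("a1", "a2"), "a1", co$ic, co$dag), rev_expected)
  # asymmetry witness
  expect_false(isTRUE(all.equal(
    sim_one_sided("a1", c("a1", "a2"), co$ic, co$dag), rev_expected)))
  # symmetric version is the arithmetic mean of the two directions
  expect_equal(sim_symmetric("a1", c("a1", "a2"), co$ic, co$dag),
               (log(2) + rev_expected) / 2)
  # self-similarity of a gene is its mean term IC
  expect_equal(sim_symmetric(c("a1", "a2"), c("a1", "a2"), co$ic, co$dag),
               mean(c(log(2), log(2))))
  # max-pair similarity
  expect_equal(funsim_max("a1", c("a1", "a2"), co$ic, co$dag), log(2))
  expect_equal(funsim_max("a1", "b1", co$ic, co$dag), 0)  # root-only sharing
  expect_error(sim_one_sided(character(), "a1", co$ic, co$dag), "non-empty")
})

test_that("similarities equal brute-force double loops on random term sets", {
  sc <- synthetic_corpus(seed = 21, n_terms = 40)
  terms <- sc$ic$term_id[sc$ic$term_id != sc$dag$root]
  withr::with_seed(31, {
    for (i in 1:5) {
      s1 <- sample(terms, 3); s2 <- sample(terms, 4)
      expect_equal(sim_one_sided(s1, s2, sc$ic, sc$dag),
                   oracle_one_sided(sc$dag, sc$ic, s1, s2))
      expect_equal(sim_symmetric(s1, s2, sc$ic, sc$dag),
                   (oracle_one_sided(sc$dag, sc$ic, s1, s2) +
                      oracle_one_sided(sc$dag, sc$ic, s2, s1)) / 2)
      expect_equal(sim_symmetric(s1, s2, sc$ic, sc$dag),
                   sim_symmetric(s2, s1, sc$ic, sc$dag))
      bf_max <- max(outer(s1, s2, Vectorize(function(a, b) {
        oracle_resnik(sc$dag, sc$ic, a, b)
      })))
      expect_equal(funsim_max(s1, s2, sc$ic, sc$dag), bf_max)
    }
  })
})

test_that("the all-pairs network matches per-pair recomputation and filters zeros", {
  sc <- synthetic_corpus(seed = 13, class_counts = c(MD_MG = 4, MD_PG = 2,
                                                     PD_MG = 2, PD_PG = 2))
  net <- all_pairs_network(sc$direct, sc$ic, sc$dag)
  genes <- unique(sc$direct$gene_id)
  expect_lte(nrow(net), choose(length(genes), 2))
  expect_true(all(net$score > 0))
  expect_true(all(net$gene_a < net$gene_b))
  # recompute every reported pair (and one unreported zero pair, if any)
  sets <- split(sc$direct$term_id, sc$direct$gene_id)
  sets <- lapply(sets, function(s) most_specific_terms(sc$dag, s))
  for (k in seq_len(min(nrow(net), 15))) {
    expect_equal(net$score[k],
                 sim_symmetric(sets[[net$gene_a[k]]], sets[[net$gene_b[k]]],
                               sc$ic, sc$dag))
  }

  # genes sharing only the root produce no edge
  dag <- toy_dag()
  ann <- tibble::tibble(gene_id = c("gx", "gy"), term_id = c("a1", "b1"))
  prop <- propagate_annotations(dag, ann)
  ic <- compute_ic(dag, prop)
  empty <- all_pairs_network(ann, ic, dag)
  expect_equal(nrow(empty), 0)

  expect_error(all_pairs_network(ann[1, ], ic, dag), "at least 2")
})

test_that("percentile threshold keeps the top slice, ties included", {
  withr::with_seed(8, {
    sc200 <- tibble::tibble(gene_a = sprintf("a%03d", 1:200),
                            gene_b = sprintf("b%03d", 1:200),
                            score = sample(seq(0.1, 20, length.out = 200)))
  })
  thr <- percentile_threshold(sc200, 98)
  expect_equal(nrow(thr$retained), 4)
  expect_setequal(thr$retained$score, sort(sc200$score, decreasing = TRUE)[1:4])

  sc1000 <- tibble::tibble(gene_a = sprintf("a%04d", 1:1000),
                           gene_b = sprintf("b%04d", 1:1000),
                           score = seq_len(1000) / 10)
  expect_equal(nrow(percentile_threshold(sc1000, 99.5)$retained), 5)

  # ties at the cutoff are all retained; count agrees with a sort-based oracle
  tied <- tibble::tibble(gene_a = sprintf("a%03d", 1:100),
                         gene_b = sprintf("b%03d", 1:100),
                         score = c(rep(5, 10), seq(0.1, 4, length.out = 90)))
  thr_t <- percentile_threshold(tied, 95)
  expect_true(all(thr_t$retained$score >= thr_t$cutoff_score))
  oracle_n <- sum(tied$score >= stats::quantile(tied$score, 0.95))
  expect_equal(nrow(thr_t$retained), oracle_n)
  expect_gte(nrow(thr_t$retained), 10)  # the tied block survives whole

  # nesting: a stricter percentile retains a subset
  t98 <- percentile_threshold(sc200, 98)
  t90 <- percentile_threshold(sc200, 90)
  expect_true(all(paste(t98$retained$gene_a, t98$retained$gene_b) %in%
                    paste(t90$retained$gene_a, t90$retained$gene_b)))

  expect_error(percentile_threshold(sc200[0, ], 98), "empty")
  expect_error(percentile_threshold(sc200, 0), "percentile")
})

test_that("threshold optimization maximizes Youden's J over a full scan", {
  pos <- tibble::tibble(gene_a = sprintf("p%02d", 1:10),
                        gene_b = sprintf("q%02d", 1:10))
  withr::with_seed(14, {
    edges <- dplyr::bind_rows(
      dplyr::mutate(pos, score = stats::runif(10, 2, 3)),
      tibble::tibble(gene_a = sprintf("x%02d", 1:30),
                     gene_b = sprintf("y%02d", 1:30),
                     score = stats::runif(30, 0, 1))
    )
  })
  res <- optimize_threshold(edges, pos)
  expect_equal(res$j, 1)  # perfectly separable
  expect_true(all(pos$gene_a %in%
                    edges$gene_a[edges$score >= res$cutoff]))

  # equals an exhaustive scan on an overlapping instance
  withr::with_seed(15, {
    edges2 <- dplyr::bind_rows(
      dplyr::mutate(pos, score = stats::rnorm(10, 1.0, 0.7)),
      tibble::tibble(gene_a = sprintf("x%02d", 1:30),
                     gene_b = sprintf("y%02d", 1:30),
                     score = stats::rnorm(30, 0, 0.7))
    )
  })
  res2 <- optimize_threshold(edges2, pos)
  lab <- paste(edges2$gene_a, edges2$gene_b) %in% paste(pos$gene_a, pos$gene_b)
  best_j <- max(vapply(unique(edges2$score), function(cut) {
    sum(edges2$score >= cut & lab) / sum(lab) +
      sum(edges2$score < cut & !lab) / sum(!lab) - 1
  }, numeric(1)))
  expect_equal(res2$j, best_j)

  expect_error(optimize_threshold(edges[1:10, ], pos), "negative")
})

test_that("score density normalizes and resolves a bimodal mixture", {
  withr::with_seed(4, {
    scores <- c(stats::rnorm(300, 1, 0.05), stats::rnorm(300, 2, 0.05))
  })
  edges <- tibble::tibble(gene_a = sprintf("a%03d", seq_along(scores)),
                          gene_b = sprintf("b%03d", seq_along(scores)),
                          score = scores)
  d <- score_density(edges, bandwidth = 0.05)
  area <- sum(diff(d$score) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-2)
  # two local maxima near the mixture components
  peaks <- d$score[which(diff(sign(diff(d$density))) == -2) + 1]
  expect_equal(length(peaks), 2)
  expect_equal(peaks, c(1, 2), tolerance = 0.1)
  expect_error(score_density(edges, bandwidth = 0), "positive")
})
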