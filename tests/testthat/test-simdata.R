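test_that("benchmark generation is a pure function of its seed", {
  spec <- benchmark_spec(n_genes = 60, n_modules = 2, module_size = 10, seed = 9,
                         source_reliability = c(0.9, 0.6, 0.4))
  b1 <- simulate_benchmark(spec)
  b2 <- simulate_benchmark(spec)
  expect_identical(b1, b2)
  b3 <- simulate_benchmark(benchmark_spec(n_genes = 60, n_modules = 2,
                                          module_size = 10, seed = 10,
                                          source_reliability = c(0.9, 0.6, 0.4)))
  expect_false(identical(b1$sources, b3$sources))
  # generation does not disturb the caller's RNG stream
  set.seed(123); x <- runif(1)
  set.seed(123); invisible(simulate_benchmark(spec)); y <- runif(1)
  expect_identical(x, y)
})

test_that("generated bundles satisfy the type invariants and ground-truth layout", {
  spec <- benchmark_spec(n_genes = 80, n_modules = 3, module_size = 10, seed = 4,
                         source_reliability = c(0.8, 0.5, 0.3))
  b <- simulate_benchmark(spec)
  expect_length(b$sources, 3L)
  for (net in b$sources) {
    e <- net$edges
    expect_true(all(e$gene1 < e$gene2))
    expect_false(any(duplicated(paste(e$gene1, e$gene2))))
    expect_length(b$edge_truth[[net$source_id]], nrow(e))
  }
  expect_true(all(lengths(b$ann) >= 1))           # every gene annotated
  expect_equal(sum(b$truth == 1), 10L)
  expect_length(intersect(b$refs$genes, b$held_out_positives), 0)
  expect_setequal(c(b$refs$genes, b$held_out_positives),
                  names(b$truth)[b$truth == 1])
  # true-labeled edges are within-module by construction
  for (sid in names(b$sources)) {
    e <- b$sources[[sid]]$edges[b$edge_truth[[sid]], ]
    expect_true(all(b$truth[e$gene1] == b$truth[e$gene2] & b$truth[e$gene1] > 0))
  }
})

test_that("equal within/between probabilities give equal edge frequencies", {
  spec <- benchmark_spec(n_genes = 200, n_modules = 4, module_size = 25,
                         p_within = 0.05, p_between = 0.05,
                         source_reliability = c(0, 0, 0), seed = 12)
  b <- simulate_benchmark(spec)
  n_within_pairs <- 4 * choose(25, 2)
  n_between_pairs <- choose(200, 2) - n_within_pairs
  for (net in b$sources) {
    e <- net$edges
    within <- b$truth[e$gene1] > 0 & b$truth[e$gene1] == b$truth[e$gene2]
    f_w <- sum(within) / n_within_pairs
    f_b <- sum(!within) / n_between_pairs
    se <- sqrt(0.05 * 0.95 * (1 / n_within_pairs + 1 / n_between_pairs))
    expect_lt(abs(f_w - f_b), 3 * se)
  }
})

test_that("forced annotation sharing makes every within-module edge share a term", {
  spec <- benchmark_spec(n_genes = 50, n_modules = 2, module_size = 10,
                         p_share_within = 1, seed = 3,
                         source_reliability = c(0.9, 0.9, 0.9))
  b <- simulate_benchmark(spec)
  for (net in b$sources) {
    e <- net$edges
    within <- b$truth[e$gene1] > 0 & b$truth[e$gene1] == b$truth[e$gene2]
    if (!any(within)) next
    share <- mapply(function(u, v) shares_function(u, v, b$ann),
                    e$gene1[within], e$gene2[within])
    expect_true(all(share == 1L))
  }
})

test_that("benchmark spec validates its probability and size invariants", {
  expect_error(benchmark_spec(p_within = 0.1, p_between = 0.5), "p_between")
  expect_error(benchmark_spec(n_genes = 50, n_modules = 5, module_size = 20),
               "exceed")
  expect_error(benchmark_spec(source_reliability = c(1, 1)), "length")
  expect_error(benchmark_spec(p_share_within = 1.2), "probabilities")
})

test_that("block-correlated expression hits its target correlation", {
  m <- simulate_expression(60, 200, block = 1:12, block_correlation = 0.95,
                           seed = 6)
  block <- rownames(m)[1:12]
  r <- cor(t(m[block, ]))
  mean_r <- mean(r[upper.tri(r)])
  expect_lt(abs(mean_r - 0.95), 0.05)
  # zero block correlation: mean within-block r near 0
  m0 <- simulate_expression(60, 200, block = 1:12, block_correlation = 0,
                            seed = 6)
  r0 <- cor(t(m0[rownames(m0)[1:12], ]))
  expect_lt(abs(mean(r0[upper.tri(r0)])), 3 / sqrt(200))
  # determinism
  expect_identical(m, simulate_expression(60, 200, block = 1:12,
                                          block_correlation = 0.95, seed = 6))
  expect_error(simulate_expression(10, 5, block_correlation = 1), "block_correlation")
})

test_that("labeled BLAST bundles drive the homology filter exactly", {
  sim <- simulate_blast_hits(n_proteins = 30, n_true_pairs = 5, n_decoys = 5,
                             seed = 13)
  expect_identical(sim, simulate_blast_hits(30, 5, 5, seed = 13))
  net <- build_homology(sim$hits, sim$query_lengths)
  expect_equal(nrow(net$edges), 5L)
  # the kept pairs are exactly the pass-labeled ones
  pass <- sim$hits[sim$labels == "pass", ]
  want <- sort(paste(pmin(pass$qseqid, pass$sseqid),
                     pmax(pass$qseqid, pass$sseqid)))
  expect_equal(paste(net$edges$gene1, net$edges$gene2), want)
  # zero decoys: kept count equals n_true_pairs
  sim0 <- simulate_blast_hits(20, 7, n_decoys = 0, seed = 2)
  expect_equal(nrow(build_homology(sim0$hits, sim0$query_lengths)$edges), 7L)
  expect_error(simulate_blast_hits(3, 10), "infeasible")
})

test_that("integrated confidences rank true-module edges above background", {
  b <- simulate_benchmark(benchmark_spec(n_genes = 150, n_modules = 3,
                                         module_size = 15, seed = 21,
                                         source_reliability = c(0.9, 0.7, 0.5)))
  fit <- fgn(unname(b$sources), b$ann)
  e <- fit$graph$edges
  within <- b$truth[e$gene1] > 0 & b$truth[e$gene1] == b$truth[e$gene2]
  expect_gt(mean(e$confidence[within]), mean(e$confidence[!within]))
})
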