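test_that("bin_index maps boundary and interior scores per the formula", {
  spec <- bin_spec("s", 0, 10, 10)
  expect_equal(bin_index(0, spec), 1L)     # minimum -> bin 1
  expect_equal(bin_index(10, spec), 10L)   # maximum capped at n
  expect_equal(bin_index(4.2, spec), 5L)
  expect_equal(bin_index(-1, spec), 0L)    # below-minimum scores are unscorable
  # degenerate source: everything at/above the minimum goes to bin 1
  d <- bin_spec("s", 3, 3, 10)
  expect_equal(bin_index(c(2.9, 3, 7), d), c(0L, 1L, 1L))
})

test_that("bin_index matches an independent formula re-evaluation and is monotone", {
  set.seed(3)
  for (rep in 1:200) {
    lo <- runif(1, -5, 5); hi <- lo + runif(1, 0, 10)
    n <- sample(1:15, 1)
    spec <- bin_spec("s", lo, hi, n)
    S <- sort(runif(8, lo - 2, hi + 2))
    got <- bin_index(S, spec)
    want <- vapply(S, bin_index_oracle, 0L, s_min = lo, s_max = hi, n = n)
    expect_identical(got, want)
    expect_true(all(got >= 0L & got <= n))
    expect_true(all(diff(got) >= 0L))      # monotone in S
  }
})

test_that("bin confidence is the smoothed sharing fraction", {
  ann <- tiny_annotation()   # a:{1,2} b:{2} c:{3} d:{1}
  # 3 annotated edges, 2 share a term -> 2/(3+1)
  edges <- data.frame(gene1 = c("a", "a", "b"), gene2 = c("b", "d", "c"),
                      stringsAsFactors = FALSE)
  expect_equal(bin_confidence(edges, ann), 0.5)
  expect_equal(bin_confidence(edges[0, ], ann), 0)       # empty bin
  expect_equal(bin_confidence(edges[1, , drop = FALSE], ann), 0.5)  # 1/(1+1)
  # smoothing keeps every bin confidence strictly below 1
  all_share <- data.frame(gene1 = rep("a", 5), gene2 = rep("b", 5))
  expect_lt(bin_confidence(all_share, ann), 1)
})

test_that("shares_function is the any-term intersection indicator", {
  ann <- tiny_annotation()
  expect_equal(shares_function("a", "b", ann), 1L)
  expect_equal(shares_function("b", "c", ann), 0L)
  expect_equal(shares_function("a", "zz", ann), 0L)  # unannotated shares nothing
})

test_that("confidence_table calibrates per source and per bin", {
  ann <- annotation_map(rep(c("a", "b", "c", "d"), each = 1),
                        c("GO:1", "GO:1", "GO:1", "GO:1"))
  # one source whose scores all fall in one bin, all edges sharing:
  # p = m/(m+1)
  net <- evidence_network(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1), "s1")
  tab <- confidence_table(list(net), ann, n_bins = 10)
  expect_equal(tab$sources$s1$p[1], 3 / 4)
  expect_equal(sum(tab$sources$s1$p[-1]), 0)

  # edges with an unannotated endpoint are excluded from estimation but the
  # network still integrates them with their bin's p
  net2 <- evidence_network(c("a", "a", "x"), c("b", "c", "y"), c(1, 1, 1), "s2")
  tab2 <- confidence_table(list(net2), ann)
  expect_equal(tab2$sources$s2$p[1], 2 / 3)
  g <- integrate_networks(list(net2), tab2)
  expect_equal(g$edges$confidence[g$edges$gene1 == "x"], 2 / 3)

  # two sources get independent bin specs
  net3 <- evidence_network(c("a", "b"), c("b", "c"), c(100, 200), "s3")
  tab3 <- confidence_table(list(net, net3), ann)
  expect_equal(tab3$sources$s3$spec$s_min, 100)
  expect_equal(tab3$sources$s1$spec$s_max, 1)

  # a source with no doubly-annotated edge is unestimable
  net4 <- evidence_network("x", "y", 1, "dark")
  expect_error(confidence_table(list(net4), ann), "dark")
  expect_error(make_bin_spec(evidence_network(character(), character(),
                                              numeric(), "e")), "no edges")
})

test_that("noisy-OR integration follows the combination rule", {
  ann <- annotation_map(c("a", "b", "c"), c("GO:1", "GO:1", "GO:1"))
  # construct two sources whose single bins calibrate to p = 0.5 each:
  # one sharing edge among annotated pairs -> 1/(1+1)
  n1 <- evidence_network("a", "b", 1, "k1")
  n2 <- evidence_network(c("a", "a"), c("b", "c"), c(1, 1), "k2")
  tab <- confidence_table(list(n1, n2), ann)
  expect_equal(tab$sources$k1$p[1], 0.5)
  g <- integrate_networks(list(n1, n2), tab)
  ab <- g$edges[g$edges$gene1 == "a" & g$edges$gene2 == "b", ]
  expect_equal(ab$confidence, 1 - 0.5 * (1 - tab$sources$k2$p[1]))
  expect_equal(ab$sources, "k1,k2")
  # single-source edge keeps its own p
  ac <- g$edges[g$edges$gene2 == "c", ]
  expect_equal(ac$confidence, tab$sources$k2$p[1])
  expect_equal(ac$sources, "k2")
})

test_that("integration is order-invariant, monotone, and bounded below 1", {
  set.seed(21)
  ann_g <- sprintf("g%02d", 1:12)
  ann <- annotation_map(ann_g, paste0("GO:", sample(3, 12, replace = TRUE)))
  nets <- lapply(1:3, function(k) random_network(100 + k, source_id = paste0("s", k)))
  tab <- confidence_table(nets, ann)
  g1 <- integrate_networks(nets, tab)
  g2 <- integrate_networks(rev(nets), tab)
  expect_identical(g1$edges, g2$edges)                  # order invariance
  expect_true(all(g1$edges$confidence >= 0 & g1$edges$confidence < 1))

  # single-source integration returns that source's bin confidences
  tab1 <- confidence_table(nets[1], ann)
  gs <- integrate_networks(nets[1], tab1)
  e <- nets[[1]]$edges
  expect_equal(gs$edges$confidence,
               fgnet:::conf_lookup(tab1, nets[[1]]$source_id, e$score))

  # adding a source never decreases any edge's confidence
  g12 <- integrate_networks(nets[1:2], tab)
  g123 <- integrate_networks(nets, tab)
  key12 <- paste(g12$edges$gene1, g12$edges$gene2)
  key123 <- paste(g123$edges$gene1, g123$edges$gene2)
  m <- match(key12, key123)
  expect_true(all(g123$edges$confidence[m] >= g12$edges$confidence - 1e-12))
})
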