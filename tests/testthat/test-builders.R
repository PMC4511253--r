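test_that("combine_expression z-scores within experiment and aligns blocks", {
  m1 <- matrix(c(1, 2, 3, 4,
                 4, 3, 2, 1,
                 5, 5, 5, 5), nrow = 3, byrow = TRUE,
               dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  attr(m1, "experiment_id") <- "e1"
  m2 <- matrix(c(10, 20, 30,
                 1, 0, -1), nrow = 2, byrow = TRUE,
               dimnames = list(c("gA", "gD"), paste0("s", 1:3)))
  attr(m2, "experiment_id") <- "e2"

  comb <- combine_expression(list(m1, m2))
  expect_equal(dim(comb), c(4L, 7L))
  # single-block rows are plain z-scores
  expect_equal(unname(comb["gA", 1:4]), unname((m1["gA", ] - 2.5) / sd(m1["gA", ])))
  # gene absent from an experiment carries NA in that block
  expect_true(all(is.na(comb["gD", 1:4])))
  expect_true(all(is.na(comb["gB", 5:7])))
  # constant row flagged and not z-scorable
  expect_true(all(is.na(comb["gC", 1:4])))
  expect_equal(attr(comb, "constant_genes"), "gC")

  expect_error(combine_expression(list(m1), de_genes = "gZ"), "no usable genes")
})

test_that("coexpression agrees with the brute-force Pearson oracle", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rnorm(20 * 10), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:10)))
    m[sample(length(m), 15)] <- NA           # exercise pairwise-complete
    net <- build_coexpression(m, threshold = 0.2, min_pairs = 3)
    # every reported edge matches the textbook formula
    for (r in seq_len(nrow(net$edges))) {
      e <- net$edges[r, ]
      expect_equal(e$score, pearson_oracle(m[e$gene1, ], m[e$gene2, ]),
                   tolerance = 1e-10)
    }
    # and no qualifying pair is missed
    expected <- 0L
    for (i in 1:19) for (j in (i + 1):20) {
      ok <- sum(is.finite(m[i, ]) & is.finite(m[j, ])) >= 3
      r_ij <- pearson_oracle(m[i, ], m[j, ])
      if (ok && is.finite(r_ij) && r_ij >= 0.2) expected <- expected + 1L
    }
    expect_equal(nrow(net$edges), expected)
  }
})

test_that("coexpression threshold is signed: strong negatives give no edge", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5),
             g2 = c(1.1, 2, 3, 4, 5.2),
             g3 = c(5, 4, 3, 2, 1))
  net <- build_coexpression(m, threshold = 0.7)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$gene1, "g1")
  expect_equal(net$edges$gene2, "g2")
  # identical rows correlate exactly 1
  net2 <- build_coexpression(rbind(a = 1:4, b = 1:4), threshold = 0.7)
  expect_equal(net2$edges$score, 1.0)
  expect_error(build_coexpression(m[1, , drop = FALSE]), "2 genes")
})

test_that("homology filters retain exactly the qualifying hits", {
  hits <- data.frame(
    qseqid = c("p1", "p1", "p2", "p3", "p4"),
    sseqid = c("p2", "p3", "p3", "p4", "p4"),
    pident = c(50, 80, 30, 60, 90),
    length = c(60, 40, 70, 80, 100),
    evalue = c(1e-6, 1e-9, 1e-9, 1e-3, 1e-20),
    stringsAsFactors = FALSE)
  qlen <- c(p1 = 100, p2 = 100, p3 = 100, p4 = 120)
  net <- build_homology(hits, qlen)
  # hit 1 passes (score -log10(1e-6) = 6); hit 2 fails coverage; hit 3 fails
  # similarity; hit 4 fails the e-value cut (not strict enough); hit 5 self
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$score, 6.0)
  fc <- attr(net, "filter_counts")
  expect_equal(unname(fc), c(1L, 1L, 1L, 1L))

  # zero e-values clamp to a finite score of 180
  h0 <- data.frame(qseqid = "p1", sseqid = "p2", pident = 90, length = 90,
                   evalue = 0, stringsAsFactors = FALSE)
  expect_equal(build_homology(h0, qlen)$edges$score, 180)
  expect_error(build_homology(hits, qlen[-1]), "no query length")
})

test_that("homology edge count matches an independent per-row filter on random hits", {
  set.seed(7)
  n <- 1000
  prot <- sprintf("p%03d", 1:40)
  hits <- data.frame(
    qseqid = sample(prot, n, replace = TRUE),
    sseqid = sample(prot, n, replace = TRUE),
    pident = runif(n, 0, 100),
    length = sample(10:500, n, replace = TRUE),
    evalue = 10^runif(n, -30, 0),
    stringsAsFactors = FALSE)
  qlen <- setNames(sample(100:500, 40, replace = TRUE), prot)
  net <- build_homology(hits, qlen)

  # independent re-implementation: row-by-row filter, then count distinct pairs
  kept <- character()
  for (r in seq_len(n)) {
    h <- hits[r, ]
    if (h$qseqid == h$sseqid) next
    if (h$length / qlen[h$qseqid] < 0.5) next
    if (h$pident / 100 < 0.4) next
    if (!(h$evalue < 1e-4)) next
    kept <- c(kept, paste(min(h$qseqid, h$sseqid), max(h$qseqid, h$sseqid)))
  }
  expect_equal(nrow(net$edges), length(unique(kept)))
})

test_that("shared-domain scores equal intersection sizes", {
  assign <- domain_assignment(
    c("p1", "p1", "p1", "p2", "p2", "p3", "p4"),
    c("D1", "D2", "D3", "D2", "D3", "D1", "D9"))
  net <- build_domain(assign)
  e <- net$edges
  expect_equal(e$score[e$gene1 == "p1" & e$gene2 == "p2"], 2)
  expect_equal(e$score[e$gene1 == "p1" & e$gene2 == "p3"], 1)
  expect_false(any(e$gene1 == "p4" | e$gene2 == "p4"))  # disjoint -> no edge
  # every edge score re-derived from the raw sets
  for (r in seq_len(nrow(e))) {
    expect_equal(e$score[r],
                 length(intersect(assign[[e$gene1[r]]], assign[[e$gene2[r]]])))
  }
  # three proteins sharing one domain form a triangle
  tri <- build_domain(domain_assignment(c("a", "b", "c"), rep("D1", 3)))
  expect_equal(nrow(tri$edges), 3L)
  expect_true(all(tri$edges$score >= 1))
})

test_that("interolog transfer enumerates ortholog combinations and keeps max", {
  donor <- evidence_network(c("H1", "H2"), c("H2", "H3"), c(0.9, 0.4), "humannet")
  orth <- ortholog_map(c("H1", "H1", "H2", "H3"), c("b1", "b1x", "b2", "b2"),
                       "human")
  net <- build_interolog(donor, orth)
  # brute force: enumerate every (donor edge) x (ortholog pair) combination
  expected <- list()
  for (r in seq_len(nrow(donor$edges))) {
    de <- donor$edges[r, ]
    for (a in orth$pairs$target[orth$pairs$donor == de$gene1])
      for (b in orth$pairs$target[orth$pairs$donor == de$gene2]) {
        if (a == b) next
        k <- paste(min(a, b), max(a, b))
        expected[[k]] <- max(expected[[k]] %||% -Inf, de$score)
      }
  }
  got <- setNames(net$edges$score, paste(net$edges$gene1, net$edges$gene2))
  expect_equal(sort(names(got)), sort(names(expected)))
  expect_equal(got[names(expected)],
               setNames(unlist(expected), names(expected)))
  # H2->H3 edge with H2 and H3 mapping to the same target gene emits nothing
  expect_false(any(net$edges$gene1 == "b2" & net$edges$gene2 == "b2"))
  # unmapped endpoint: no edge
  orth2 <- ortholog_map("H1", "b1", "human")
  expect_equal(nrow(build_interolog(donor, orth2)$edges), 0L)
})

test_that("annotation transfer fills only unannotated genes and never shrinks", {
  ann <- annotation_map(c("b2"), c("GO:1"))
  donors <- list(list(
    ann = annotation_map(c("H1", "H2"), c("GO:8150", "GO:2")),
    orth = ortholog_map(c("H1", "H2", "H3"), c("b1", "b2", "b9"), "human")))
  out <- transfer_annotations(ann, donors)
  expect_equal(out[["b1"]], "GO:8150")     # unannotated gene filled
  expect_equal(out[["b2"]], "GO:1")        # annotated gene untouched
  expect_null(out[["b3"]])                 # no ortholog -> still absent
  # widen to union-merge
  merged <- transfer_annotations(ann, donors, fill_only = FALSE)
  expect_equal(merged[["b2"]], c("GO:1", "GO:2"))
  # property: never shrinks, never edits annotated genes (fill-only mode)
  for (seed in 1:10) {
    set.seed(seed)
    g <- sprintf("t%02d", 1:15)
    base <- annotation_map(sample(g, 8), paste0("GO:", sample(5, 8, replace = TRUE)))
    don <- list(list(
      ann = annotation_map(sprintf("d%d", sample(10, 10, replace = TRUE)),
                           paste0("GO:", sample(9, 10, replace = TRUE))),
      orth = ortholog_map(sprintf("d%d", sample(10, 12, replace = TRUE)),
                          sample(g, 12, replace = TRUE), "don")))
    res <- transfer_annotations(base, don)
    for (gene in names(base)) expect_identical(res[[gene]], base[[gene]])
    expect_true(all(names(base) %in% names(res)))
  }
})
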