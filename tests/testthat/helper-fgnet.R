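# Fixture builders shared across test files. Everything is generated in
# code; randomized helpers take an explicit seed.

random_network <- function(seed, n_genes = 12, n_edges = 20, source_id = "src") {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  i <- sample(n_genes, n_edges, replace = TRUE)
  j <- sample(n_genes, n_edges, replace = TRUE)
  keep <- i != j
  evidence_network(genes[i[keep]], genes[j[keep]],
                   round(runif(sum(keep), 0, 10), 4), source_id = source_id)
}

random_integrated <- function(seed, n_genes = 15, n_edges = 30) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  i <- sample(n_genes, n_edges, replace = TRUE)
  j <- sample(n_genes, n_edges, replace = TRUE)
  keep <- i != j
  g1 <- genes[i[keep]]; g2 <- genes[j[keep]]
  key <- paste(pmin(g1, g2), pmax(g1, g2))
  first <- !duplicated(key)
  integrated_network(g1[first], g2[first], runif(sum(first)),
                     rep("s1", sum(first)))
}

# brute-force Pearson r by the textbook formula (independent of stats::cor)
pearson_oracle <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# brute-force DAG: enumerate all (gene, reference) edges one by one
dag_oracle <- function(net, refs, gene) {
  e <- net$edges
  sum_w <- 0; n_links <- 0L
  for (r in seq_len(nrow(e))) {
    u <- e$gene1[r]; v <- e$gene2[r]
    other <- if (u == gene) v else if (v == gene) u else next
    if (other %in% refs && other != gene) {
      sum_w <- sum_w + e$confidence[r]
      n_links <- n_links + 1L
    }
  }
  c(dag = sum_w * n_links, sum_w = sum_w, n_links = n_links)
}

# direct re-evaluation of the bin-index formula, scalar, written separately
# from the package implementation
bin_index_oracle <- function(S, s_min, s_max, n) {
  if (S < s_min) return(0L)
  if (s_max == s_min) return(1L)
  as.integer(min(n, floor((S - s_min) / (s_max - s_min) * n) + 1))
}

# minimal ranking object around a bare score vector, for evaluation tests
make_ranking <- function(scores, refs) {
  genes <- names(scores)
  o <- order(-scores, genes, method = "radix")
  structure(list(
    scores = data.frame(gene = genes[o], sum_weights = scores[o],
                        n_ref_links = 1L, dag = unname(scores[o]),
                        rank = seq_along(scores),
                        is_reference = genes[o] %in% refs,
                        stringsAsFactors = FALSE),
    refs = reference_genes(refs), network = NULL, scope = "all"),
    class = "fgn_ranking")
}

tiny_annotation <- function() {
  annotation_map(c("a", "a", "b", "c", "d"),
                 c("GO:1", "GO:2", "GO:2", "GO:3", "GO:1"))
}
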