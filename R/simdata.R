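## Seeded synthetic-data generator: multi-source networks with planted
## functional modules, module-structured annotations, block-correlated
## expression, and labeled homology-hit tables — every input type the
## pipeline consumes, with known ground truth.

#' Specification of a synthetic benchmark
#'
#' Genes are partitioned into functional modules plus background. Each
#' evidence source reports a within-module pair with probability `p_within`
#' and any other pair with probability `p_between`; an emitted within-module
#' edge is a true-module edge with probability `reliability` (so true edges
#' occur among within-module pairs at rate `p_within * reliability`), and
#' every other emitted edge is noise. True edges draw raw scores from a
#' higher range than noise edges, with overlap, so score binning is
#' informative but imperfect. With all reliabilities 0 and
#' `p_within = p_between`, edges are fully exchangeable between module and
#' background pairs: a no-signal control. Same-module gene pairs share an annotation
#' term with probability `p_share_within`; every gene additionally carries
#' one background term from a pool of `annotation_terms`, so all genes are
#' annotated and background sharing is rare. The reference set is a random
#' half of module 1; the other half is held out as evaluation positives.
#'
#' @param n_genes total genes (default 500).
#' @param n_modules number of planted modules (default 5).
#' @param module_size genes per module (default 20).
#' @param p_within within-module edge probability before reliability
#'   (default 0.3).
#' @param p_between background edge probability (default 0.01).
#' @param n_sources number of evidence sources (default 3).
#' @param source_reliability per-source probability that a within-module
#'   edge is emitted (length `n_sources`; default `c(0.9, 0.7, 0.5)`).
#' @param annotation_terms size of the background term pool (default 100).
#' @param p_share_within probability two same-module genes share the module
#'   term (default 0.8).
#' @param seed integer seed; the bundle is a pure function of it.
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_genes = 500, n_modules = 5, module_size = 20,
                           p_within = 0.3, p_between = 0.01, n_sources = 3,
                           source_reliability = c(0.9, 0.7, 0.5),
                           annotation_terms = 100, p_share_within = 0.8,
                           seed = 42) {
  if (length(source_reliability) != n_sources) {
    stop("source_reliability must have length n_sources", call. = FALSE)
  }
  probs <- c(p_within, p_between, p_share_within, source_reliability)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p_between > p_within) stop("need p_between <= p_within", call. = FALSE)
  if (n_modules * module_size > n_genes) {
    stop("module_size * n_modules must not exceed n_genes", call. = FALSE)
  }
  if (n_genes < 2 || module_size < 2) stop("infeasible sizes", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size), p_within = p_within,
                 p_between = p_between, n_sources = as.integer(n_sources),
                 source_reliability = source_reliability,
                 annotation_terms = as.integer(annotation_terms),
                 p_share_within = p_share_within, seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Generate a synthetic benchmark bundle
#'
#' @param spec a [benchmark_spec()].
#' @return A list (class `benchmark_bundle`) with `sources` (list of
#'   [evidence_network()]), `ann` ([annotation_map()]), `refs`
#'   ([reference_genes()]: half of module 1), `held_out_positives` (the
#'   other half), `truth` (named integer vector of module membership, 0 =
#'   background), `edge_truth` (per source, logical vector marking
#'   true-module edges, aligned to the network's canonical edge order), and
#'   `meta` (score ranges and the spec).
#' @export
simulate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    genes <- sprintf("g%0*d", nchar(n), seq_len(n))
    module <- integer(n)
    module[seq_len(spec$n_modules * spec$module_size)] <-
      rep(seq_len(spec$n_modules), each = spec$module_size)
    names(module) <- genes

    pairs <- utils::combn(n, 2L)
    i <- pairs[1L, ]; j <- pairs[2L, ]
    within <- module[i] > 0L & module[i] == module[j]

    # true scores U[0.5, 1] * scale, noise U[0, 0.7] * scale: overlapping
    # ranges on a different measurement scale per source
    scales <- 5 ^ (seq_len(spec$n_sources) - 1)
    sources <- vector("list", spec$n_sources)
    edge_truth <- vector("list", spec$n_sources)
    for (k in seq_len(spec$n_sources)) {
      p_edge <- ifelse(within, spec$p_within, spec$p_between)
      drawn <- stats::runif(length(p_edge)) < p_edge
      # reliability: probability an emitted within-module edge is scored as a
      # true-module edge rather than noise; true edges occur among
      # within-module pairs at rate p_within * reliability
      is_true <- drawn & within &
        stats::runif(length(p_edge)) < spec$source_reliability[k]
      sc <- numeric(sum(drawn))
      sel_true <- is_true[drawn]
      sc[sel_true] <- stats::runif(sum(sel_true), 0.5, 1) * scales[k]
      sc[!sel_true] <- stats::runif(sum(!sel_true), 0, 0.7) * scales[k]
      sid <- sprintf("source%02d", k)
      net <- evidence_network(genes[i[drawn]], genes[j[drawn]], sc, source_id = sid)
      # align truth flags to the network's canonical edge order
      key_in <- pair_key(genes[i[drawn]], genes[j[drawn]])
      key_net <- pair_key(net$edges$gene1, net$edges$gene2)
      edge_truth[[k]] <- sel_true[match(key_net, key_in)]
      names(edge_truth)[k] <- sid
      sources[[k]] <- net
      names(sources)[k] <- sid
    }

    # annotations: module term carried with prob sqrt(p_share_within) so two
    # module mates share it with prob p_share_within; plus one background term
    q <- sqrt(spec$p_share_within)
    ann_gene <- genes
    ann_term <- paste0("T", sample.int(spec$annotation_terms, n, replace = TRUE))
    in_mod <- module > 0L
    has_mod_term <- in_mod & stats::runif(n) < q
    ann_gene <- c(ann_gene, genes[has_mod_term])
    ann_term <- c(ann_term, sprintf("MOD%02d", module[has_mod_term]))
    ann <- annotation_map(ann_gene, ann_term)

    mod1 <- genes[module == 1L]
    ref_idx <- sample.int(length(mod1), floor(length(mod1) / 2))
    refs <- reference_genes(mod1[ref_idx], trait_label = "planted_module1")
    held_out <- sort_c(mod1[-ref_idx])

    structure(list(sources = sources, ann = ann, refs = refs,
                   held_out_positives = held_out, truth = module,
                   edge_truth = edge_truth,
                   meta = list(spec = spec, scales = scales,
                               true_score_range = c(0.5, 1),
                               noise_score_range = c(0, 0.7))),
              class = "benchmark_bundle")
  })
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf("Synthetic benchmark: %d genes, %d modules of %d, %d sources (seed %d)\n",
              x$meta$spec$n_genes, x$meta$spec$n_modules, x$meta$spec$module_size,
              x$meta$spec$n_sources, x$meta$spec$seed))
  for (net in x$sources) {
    cat(sprintf("  %s: %d edges\n", net$source_id, n_edges(net)))
  }
  cat(sprintf("  %d reference genes, %d held-out positives\n",
              length(x$refs$genes), length(x$held_out_positives)))
  invisible(x)
}

#' Simulate block-correlated expression
#'
#' Genes in the block share one latent factor: each profile is
#' `sqrt(rho) * factor + sqrt(1 - rho) * noise`, giving expected pairwise
#' Pearson correlation `rho` within the block; other genes are independent
#' standard normal noise.
#'
#' @param n_genes number of genes.
#' @param n_samples number of samples.
#' @param block character vector of block gene ids (subset of the generated
#'   ids `g1 ... gN`, zero-padded) or integer indices.
#' @param block_correlation target within-block correlation, in `[0, 1)`.
#' @param seed integer seed.
#' @param experiment_id label attached to the matrix.
#' @return A genes x samples matrix with gene rownames.
#' @export
simulate_expression <- function(n_genes, n_samples, block = integer(),
                                block_correlation = 0.8, seed = 1,
                                experiment_id = "sim") {
  if (n_genes < 1 || n_samples < 2) stop("infeasible sizes", call. = FALSE)
  if (block_correlation < 0 || block_correlation >= 1) {
    stop("block_correlation must lie in [0, 1)", call. = FALSE)
  }
  genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  if (is.numeric(block)) block <- genes[block]
  if (!all(block %in% genes)) stop("block genes must be among the generated genes", call. = FALSE)
  with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes,
                dimnames = list(genes, sprintf("s%d", seq_len(n_samples))))
    if (length(block)) {
      f <- stats::rnorm(n_samples)
      rho <- block_correlation
      m[block, ] <- sqrt(rho) * matrix(f, nrow = length(block), ncol = n_samples,
                                       byrow = TRUE) +
        sqrt(1 - rho) * m[block, , drop = FALSE]
    }
    attr(m, "experiment_id") <- experiment_id
    m
  })
}

#' Simulate a BLAST hit table with labeled pass/fail hits
#'
#' True pairs receive hits passing all three homology filters (coverage >=
#' 50% of the query length, identity >= 40%, e-value < 1e-4); each decoy hit
#' violates exactly one filter, chosen round-robin, and is labeled
#' accordingly.
#'
#' @param n_proteins number of proteins.
#' @param n_true_pairs number of filter-passing pairs.
#' @param n_decoys number of single-filter-violating hits (default equals
#'   `n_true_pairs`).
#' @param seed integer seed.
#' @return A list with `hits` (outfmt-6 style data frame), `query_lengths`
#'   (named vector), and `labels` (per hit: `"pass"`, `"fail_coverage"`,
#'   `"fail_similarity"`, or `"fail_evalue"`).
#' @export
simulate_blast_hits <- function(n_proteins, n_true_pairs,
                                n_decoys = n_true_pairs, seed = 1) {
  n_pairs_all <- choose(n_proteins, 2)
  if (n_proteins < 2 || n_true_pairs + n_decoys > n_pairs_all) {
    stop("infeasible sizes", call. = FALSE)
  }
  with_seed(seed, {
    prot <- sprintf("p%0*d", nchar(n_proteins), seq_len(n_proteins))
    qlen <- sample(200:800, n_proteins, replace = TRUE)
    names(qlen) <- prot
    pairs <- utils::combn(n_proteins, 2L)
    pick <- sample.int(ncol(pairs), n_true_pairs + n_decoys)
    qi <- pairs[1L, pick]; si <- pairs[2L, pick]
    ntot <- n_true_pairs + n_decoys
    labels <- rep("pass", ntot)
    if (n_decoys > 0) {
      labels[(n_true_pairs + 1):ntot] <-
        rep(c("fail_coverage", "fail_similarity", "fail_evalue"),
            length.out = n_decoys)
    }
    ql <- qlen[prot[qi]]
    alen <- ceiling(ql * stats::runif(ntot, 0.6, 0.95))
    pident <- stats::runif(ntot, 50, 95)
    evalue <- 10 ^ stats::runif(ntot, -50, -5)
    fc <- labels == "fail_coverage"
    alen[fc] <- pmax(1, floor(ql[fc] * stats::runif(sum(fc), 0.1, 0.45)))
    fs <- labels == "fail_similarity"
    pident[fs] <- stats::runif(sum(fs), 5, 35)
    fe <- labels == "fail_evalue"
    evalue[fe] <- 10 ^ stats::runif(sum(fe), -3.9, -1)
    hits <- data.frame(
      qseqid = prot[qi], sseqid = prot[si], pident = pident, length = alen,
      mismatch = 0L, gapopen = 0L, qstart = 1L, qend = alen, sstart = 1L,
      send = alen, evalue = evalue,
      bitscore = round(-log10(pmax(evalue, 1e-180)) * 2, 1),
      stringsAsFactors = FALSE)
    list(hits = hits, query_lengths = qlen, labels = labels)
  })
}

#' Write a benchmark bundle to disk in the standard formats
#'
#' Writes one edge-list TSV per source, the annotation TSV, the reference
#' gene list, and a JSON metadata file with the ground truth (module
#' membership, held-out positives, spec parameters).
#'
#' @param bundle a `benchmark_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_benchmark <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (net in bundle$sources) {
    p <- file.path(dir, paste0(net$source_id, ".tsv"))
    write_edge_list(net, p)
    paths$sources <- c(paths$sources, p)
  }
  paths$annotations <- file.path(dir, "annotations.tsv")
  write_annotations(bundle$ann, paths$annotations)
  paths$references <- file.path(dir, "references.txt")
  writeLines(bundle$refs$genes, paths$references)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(module = as.list(bundle$truth),
         held_out_positives = bundle$held_out_positives,
         reference_genes = bundle$refs$genes,
         spec = unclass(bundle$meta$spec),
         scales = bundle$meta$scales),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
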