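## Guilt-by-association prioritization: the degree-of-association statistic
## for a trait's reference gene set, computed on the integrated network.

#' Extract the reference-gene neighborhood subnetwork
#'
#' Keeps the reference genes present in the network plus all their direct
#' neighbors, together with every edge among the retained nodes (the induced
#' subgraph; this includes every edge touching a reference gene).
#'
#' @param net an [integrated_network()].
#' @param refs a [reference_genes()] set or character vector of ids.
#' @return An [integrated_network()]; the `"unmatched_refs"` attribute lists
#'   reference ids absent from `net`.
#' @export
extract_reference_subnet <- function(net, refs) {
  ids <- ref_ids(refs)
  genes <- network_genes(net)
  present <- ids[ids %in% genes]
  unmatched <- setdiff(ids, present)
  if (!length(present)) {
    stop("no reference gene appears in the network", call. = FALSE)
  }
  if (length(unmatched)) {
    message(sprintf("%d reference gene(s) not in the network: %s",
                    length(unmatched),
                    paste(utils::head(unmatched, 5), collapse = ", ")))
  }
  e <- net$edges
  touches <- e$gene1 %in% present | e$gene2 %in% present
  nodes <- sort_c(c(present, e$gene1[touches], e$gene2[touches]))
  keep <- e$gene1 %in% nodes & e$gene2 %in% nodes
  sub <- integrated_network(e$gene1[keep], e$gene2[keep],
                            e$confidence[keep], e$sources[keep])
  attr(sub, "unmatched_refs") <- unmatched
  sub
}

#' Degree-of-association score
#'
#' For a gene i, the score is the product of two sums over the reference
#' genes j directly linked to i (j != i): the sum of the linkage confidences
#' W_ij, and the count of such reference neighbors. A gene with no reference
#' neighbor scores 0; for a reference gene the self term is excluded.
#'
#' @param net an [integrated_network()].
#' @param refs a [reference_genes()] set or character vector of ids.
#' @param genes gene ids to score (default: every gene in `net`). All must
#'   be present in `net`.
#' @return Data frame with one row per gene: `gene`, `sum_weights`,
#'   `n_ref_links`, `dag` (`= sum_weights * n_ref_links`).
#' @export
dag_score <- function(net, refs, genes = NULL) {
  ids <- ref_ids(refs)
  all_genes <- network_genes(net)
  if (is.null(genes)) {
    genes <- all_genes
  } else {
    absent <- setdiff(genes, all_genes)
    if (length(absent)) {
      stop(sprintf("gene(s) not in network: %s",
                   paste(utils::head(absent, 5), collapse = ", ")), call. = FALSE)
    }
  }
  e <- net$edges
  # each edge (u, v, r) contributes to u's score when v is a reference, and
  # vice versa; self terms cannot occur (no self-edges)
  to1 <- e$gene2 %in% ids
  to2 <- e$gene1 %in% ids
  carrier <- c(e$gene1[to1], e$gene2[to2])
  w <- c(e$confidence[to1], e$confidence[to2])
  sum_w <- vapply(split(w, factor(carrier, levels = genes)), sum, 0)
  n_links <- as.integer(lengths(split(w, factor(carrier, levels = genes))))
  data.frame(gene = genes, sum_weights = unname(sum_w), n_ref_links = n_links,
             dag = unname(sum_w) * n_links, stringsAsFactors = FALSE)
}

#' Rank genes by guilt-by-association
#'
#' Computes the degree-of-association score for every gene in scope and
#' ranks descending; ties break deterministically by gene id. By default the
#' scope is the reference neighborhood subnetwork
#' ([extract_reference_subnet()]); `scope = "all"` scores every gene in the
#' network.
#'
#' @param net an [integrated_network()].
#' @param refs a [reference_genes()] set or character vector of ids.
#' @param scope `"subnet"` (default) or `"all"`.
#' @return An object of class `fgn_ranking` with elements `scores` (data
#'   frame `gene`, `sum_weights`, `n_ref_links`, `dag`, `rank`,
#'   `is_reference`, ordered by rank), `refs`, `network` (the scope
#'   network), `scope`.
#' @seealso [evaluate_ranking()], [roc_auc()], [select_candidates()]
#' @export
prioritize <- function(net, refs, scope = c("subnet", "all")) {
  scope <- match.arg(scope)
  ids <- ref_ids(refs)
  scope_net <- if (scope == "subnet") extract_reference_subnet(net, ids) else net
  if (scope == "all" && !any(ids %in% network_genes(net))) {
    stop("no reference gene appears in the network", call. = FALSE)
  }
  sc <- dag_score(scope_net, ids)
  o <- order(-sc$dag, sc$gene, method = "radix")
  sc <- sc[o, , drop = FALSE]
  sc$rank <- seq_len(nrow(sc))
  sc$is_reference <- sc$gene %in% ids
  rownames(sc) <- NULL
  structure(list(scores = sc,
                 refs = if (inherits(refs, "reference_genes")) refs
                        else reference_genes(ids),
                 network = scope_net, scope = scope),
            class = "fgn_ranking")
}

#' @export
print.fgn_ranking <- function(x, n = 10L, ...) {
  s <- x$scores
  cat(sprintf("Guilt-by-association ranking ('%s', scope '%s'): %d genes, %d reference\n",
              x$refs$trait_label, x$scope, nrow(s), sum(s$is_reference)))
  print(utils::head(s, n), row.names = FALSE)
  if (nrow(s) > n) cat(sprintf("... %d more genes\n", nrow(s) - n))
  invisible(x)
}

#' Summarize a guilt-by-association ranking
#'
#' @param object an `fgn_ranking`.
#' @param ... unused.
#' @return List with gene counts, score quartiles and the top of the table.
#' @export
summary.fgn_ranking <- function(object, ...) {
  s <- object$scores
  structure(list(trait = object$refs$trait_label, scope = object$scope,
                 n_genes = nrow(s), n_reference = sum(s$is_reference),
                 n_positive_score = sum(s$dag > 0),
                 dag_quartiles = stats::quantile(s$dag),
                 top = utils::head(s, 10L)),
            class = "summary.fgn_ranking")
}

#' @export
print.summary.fgn_ranking <- function(x, ...) {
  cat(sprintf("Ranking for '%s' (scope %s): %d genes (%d reference), %d with score > 0\n",
              x$trait, x$scope, x$n_genes, x$n_reference, x$n_positive_score))
  cat("DAG score quartiles:\n"); print(round(x$dag_quartiles, 4))
  cat("Top genes:\n"); print(x$top, row.names = FALSE)
  invisible(x)
}

#' Plot the score distribution of a ranking
#'
#' Scores on log axis rank plot, reference genes highlighted.
#'
#' @param x an `fgn_ranking`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fgn_ranking <- function(x, ...) {
  s <- x$scores
  graphics::plot(s$rank, s$dag, type = "h", col = ifelse(s$is_reference, 2, 8),
                 xlab = "rank", ylab = "DAG score", ...)
  graphics::points(s$rank[s$is_reference], s$dag[s$is_reference], col = 2, pch = 19)
  graphics::legend("topright", legend = c("reference", "other"),
                   col = c(2, 8), pch = c(19, NA), lty = c(NA, 1), bty = "n")
  invisible(x)
}

#' Write a ranking as TSV
#'
#' Columns: `gene`, `dag`, `sum_weights`, `n_ref_links`, `rank`,
#' `is_reference`.
#'
#' @param ranking an `fgn_ranking`.
#' @param path destination path.
#' @param comments optional `#` comment lines (run metadata).
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path, comments = NULL) {
  s <- ranking$scores
  pre <- if (length(comments)) paste0("# ", comments) else character()
  writeLines(c(pre, "gene\tdag\tsum_weights\tn_ref_links\trank\tis_reference",
               paste(s$gene, num_chr(s$dag), num_chr(s$sum_weights),
                     s$n_ref_links, s$rank, as.integer(s$is_reference),
                     sep = "\t")),
             path)
  invisible(path)
}
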