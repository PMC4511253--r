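#' Fit a confidence-weighted functional gene network
#'
#' The central fitting function of the package. Given the component evidence
#' networks and a gene-function annotation map, it (i) calibrates each
#' source's raw scores into bin-wise probabilities that an edge links genes
#' sharing a biological process ([confidence_table()]), and (ii) combines
#' all sources into one integrated network whose edge confidences are the
#' noisy-OR of the per-source calibrated probabilities
#' ([integrate_networks()]).
#'
#' The fitted object supports `print()`, `summary()`, `coef()` (the matrix
#' of per-source, per-bin confidences — the model's parameters), `plot()`
#' (calibration profiles), and `predict()` (guilt-by-association candidate
#' prioritization against a reference gene set).
#'
#' @param sources list of [evidence_network()] objects, one per evidence
#'   source; all non-empty.
#' @param annotations an [annotation_map()] (GO Biological Process terms)
#'   used as the calibration standard.
#' @param n_bins number of equal-width score bins per source (default 10).
#' @return An object of class `fgn` with components `sources`, `table` (the
#'   [confidence_table()]), `graph` (the [integrated_network()]), `n_bins`
#'   and `call`.
#' @examples
#' net1 <- evidence_network(c("a", "a", "b"), c("b", "c", "c"), c(1, 2, 3), "s1")
#' net2 <- evidence_network(c("a", "b"), c("b", "d"), c(0.1, 0.9), "s2")
#' ann <- annotation_map(c("a", "b", "c", "d"), c("GO:1", "GO:1", "GO:2", "GO:1"))
#' fit <- fgn(list(net1, net2), ann)
#' fit
#' coef(fit)
#' @seealso [predict.fgn()], [prioritize()], [evaluate_ranking()]
#' @export
fgn <- function(sources, annotations, n_bins = 10) {
  if (!is.list(sources) || !length(sources)) {
    stop("sources must be a non-empty list of evidence networks", call. = FALSE)
  }
  if (!all(vapply(sources, inherits, TRUE, "evidence_network"))) {
    stop("every source must be an evidence_network", call. = FALSE)
  }
  if (!inherits(annotations, "annotation_map")) {
    stop("annotations must be an annotation_map", call. = FALSE)
  }
  ids <- vapply(sources, `[[`, "", "source_id")
  if (anyDuplicated(ids)) stop("source ids must be unique", call. = FALSE)
  names(sources) <- ids
  tab <- confidence_table(sources, annotations, n_bins = n_bins)
  graph <- integrate_networks(sources, tab)
  structure(list(sources = sources, table = tab, graph = graph,
                 n_bins = as.integer(n_bins), call = match.call()),
            class = "fgn")
}

#' @export
print.fgn <- function(x, ...) {
  cat("Integrated functional gene network\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Sources (%d):\n", length(x$sources)))
  for (net in x$sources) {
    cat(sprintf("  %-20s %7d edges\n", net$source_id, n_edges(net)))
  }
  g <- x$graph
  cat(sprintf("Integrated: %d edges over %d genes; confidence in [%.3f, %.3f]\n",
              n_edges(g), length(network_genes(g)),
              if (n_edges(g)) min(g$edges$confidence) else NA,
              if (n_edges(g)) max(g$edges$confidence) else NA))
  invisible(x)
}

#' Summarize a fitted functional gene network
#'
#' @param object an `fgn` fit.
#' @param ... unused.
#' @return A list (class `summary.fgn`) with per-source edge counts and
#'   confidence ranges, the calibration table as a data frame, and
#'   integrated-network size and multi-source edge share.
#' @export
summary.fgn <- function(object, ...) {
  g <- object$graph$edges
  multi <- if (nrow(g)) mean(grepl(",", g$sources, fixed = TRUE)) else NA_real_
  structure(list(
    call = object$call,
    n_sources = length(object$sources),
    source_edges = vapply(object$sources, n_edges, 0L),
    calibration = as.data.frame(object$table),
    n_edges = nrow(g),
    n_genes = length(network_genes(object$graph)),
    confidence_quartiles = if (nrow(g)) stats::quantile(g$confidence) else NULL,
    frac_multi_source = multi
  ), class = "summary.fgn")
}

#' @export
print.summary.fgn <- function(x, ...) {
  cat("Integrated functional gene network\n")
  cat("Call: "); print(x$call)
  cat(sprintf("%d sources -> %d integrated edges over %d genes; %.1f%% multi-source\n",
              x$n_sources, x$n_edges, x$n_genes, 100 * x$frac_multi_source))
  if (!is.null(x$confidence_quartiles)) {
    cat("Edge confidence quartiles:\n")
    print(round(x$confidence_quartiles, 4))
  }
  cat("Calibration (per source, per bin):\n")
  print(x$calibration, row.names = FALSE)
  invisible(x)
}

#' Calibrated bin confidences of a fit
#'
#' @param object an `fgn` fit.
#' @param ... unused.
#' @return Numeric matrix, sources x bins: the probability that an edge in
#'   that source/bin links genes sharing a biological-process term.
#' @export
coef.fgn <- function(object, ...) {
  p <- t(vapply(object$table$sources, `[[`, numeric(object$n_bins), "p"))
  colnames(p) <- paste0("bin", seq_len(object$n_bins))
  p
}

#' Plot calibration profiles of a fit
#'
#' One line per source: calibrated confidence against score bin. A source
#' whose high-score bins earn higher confidence is informative; a flat
#' profile contributes little.
#'
#' @param x an `fgn` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fgn <- function(x, ...) {
  p <- coef(x)
  graphics::matplot(seq_len(ncol(p)), t(p), type = "b", pch = 19, lty = 1,
                    xlab = "score bin", ylab = "bin confidence p(k, bin)",
                    ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = rownames(p), col = seq_len(nrow(p)),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Prioritize candidate genes from a fitted network
#'
#' Applies guilt-by-association scoring ([prioritize()]) to the fit's
#' integrated network.
#'
#' @param object an `fgn` fit.
#' @param refs a [reference_genes()] set (or character vector of ids).
#' @param scope `"subnet"` (default: score genes in the reference
#'   neighborhood subnetwork) or `"all"`.
#' @param ... unused.
#' @return An `fgn_ranking`; see [prioritize()].
#' @export
predict.fgn <- function(object, refs, scope = c("subnet", "all"), ...) {
  prioritize(object$graph, refs, scope = match.arg(scope))
}
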