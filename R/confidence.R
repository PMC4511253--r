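## Score calibration: per-source equal-width binning of raw scores, a
## GO-BP-based confidence per bin, and noisy-OR integration across sources.

#' Bin specification for one evidence source
#'
#' Raw scores of a source are divided into `n_bins` equal-width intervals
#' between the observed minimum and maximum score; each interval is
#' calibrated independently.
#'
#' @param source_id source label.
#' @param s_min,s_max observed score extremes (`s_min <= s_max`).
#' @param n_bins number of bins (default 10).
#' @return An object of class `bin_spec`.
#' @export
bin_spec <- function(source_id, s_min, s_max, n_bins = 10) {
  if (!is.numeric(s_min) || !is.numeric(s_max) || s_min > s_max) {
    stop("need numeric s_min <= s_max", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  structure(list(source_id = source_id, s_min = as.numeric(s_min),
                 s_max = as.numeric(s_max), n_bins = n_bins),
            class = "bin_spec")
}

#' Derive a bin specification from a network's scores
#'
#' @param net a non-empty [evidence_network()].
#' @param n_bins number of bins (default 10).
#' @return A [bin_spec()] with `s_min`/`s_max` the observed score extremes.
#' @export
make_bin_spec <- function(net, n_bins = 10) {
  if (!n_edges(net)) stop(sprintf("network '%s' has no edges", net$source_id), call. = FALSE)
  s <- net$edges$score
  bin_spec(net$source_id, min(s), max(s), n_bins)
}

#' Map a raw score to its bin index
#'
#' Scores below the source minimum map to bin 0 (unscorable: the calibration
#' data cannot speak to them); otherwise the bin is
#' `min(n, floor((S - s_min)/(s_max - s_min) * n) + 1)`, so the minimum maps
#' to bin 1 and the maximum to bin `n`. A degenerate source
#' (`s_min == s_max`) sends every score at or above the minimum to bin 1.
#'
#' @param S numeric vector of raw scores.
#' @param spec a [bin_spec()].
#' @return Integer vector of bin indices in `0:n_bins`.
#' @export
bin_index <- function(S, spec) {
  n <- spec$n_bins
  width <- spec$s_max - spec$s_min
  if (width == 0) {
    return(ifelse(S < spec$s_min, 0L, 1L))
  }
  idx <- pmin(n, floor((S - spec$s_min) / width * n) + 1)
  as.integer(ifelse(S < spec$s_min, 0L, idx))
}

#' Do two genes share an annotated function?
#'
#' @param u,v gene ids.
#' @param ann an [annotation_map()].
#' @return `1L` if the term sets of `u` and `v` intersect, else `0L`. A gene
#'   absent from the map shares nothing.
#' @export
shares_function <- function(u, v, ann) {
  tu <- ann[[u]]; tv <- ann[[v]]
  if (is.null(tu) || is.null(tv)) return(0L)
  as.integer(length(intersect(tu, tv)) > 0L)
}

# vectorized sharing indicator over an edge table
edge_shares <- function(g1, g2, ann) {
  a <- unclass(ann)
  t1 <- a[g1]; t2 <- a[g2]
  mapply(function(x, y) !is.null(x) && !is.null(y) && length(intersect(x, y)) > 0,
         t1, t2, USE.NAMES = FALSE)
}

#' Smoothed confidence of one score bin
#'
#' Given the edges of a bin whose endpoints are both annotated, the bin's
#' confidence is the fraction of them whose endpoints share a term, with
#' add-one smoothing of the denominator: `sum(S_f) / (|E| + 1)`. The
#' smoothing keeps every confidence strictly below 1; an empty bin has
#' confidence 0.
#'
#' @param edges data frame with columns `gene1`, `gene2` (both endpoints
#'   annotated; the caller filters).
#' @param ann an [annotation_map()].
#' @return A single number in `[0, 1)`.
#' @export
bin_confidence <- function(edges, ann) {
  m <- nrow(edges)
  if (!m) return(0)
  sum(edge_shares(edges$gene1, edges$gene2, ann)) / (m + 1)
}

#' Calibrate per-source, per-bin confidences
#'
#' For each source the raw-score range defines equal-width bins
#' ([make_bin_spec()]); edges whose both endpoints carry at least one
#' annotation are partitioned by bin and each bin's confidence estimated by
#' [bin_confidence()]. Bins receiving no annotated edge get confidence 0, as
#' does bin 0 (scores below the source minimum).
#'
#' @param nets list of non-empty [evidence_network()] objects.
#' @param ann an [annotation_map()].
#' @param n_bins bins per source (default 10).
#' @return An object of class `confidence_table`: per source, its
#'   [bin_spec()], the confidence vector `p` (bins `1:n_bins`), and per-bin
#'   edge counts. Coerce with `as.data.frame()`.
#' @export
confidence_table <- function(nets, ann, n_bins = 10) {
  if (!is.list(nets) || !length(nets)) stop("nets must be a non-empty list", call. = FALSE)
  out <- list()
  for (net in nets) {
    sid <- net$source_id
    spec <- make_bin_spec(net, n_bins)
    e <- net$edges
    annotated <- e$gene1 %in% names(ann) & e$gene2 %in% names(ann)
    if (!any(annotated)) {
      stop(sprintf("confidence unestimable for source '%s': no edge has both endpoints annotated", sid),
           call. = FALSE)
    }
    bins_all <- bin_index(e$score, spec)
    ea <- e[annotated, , drop = FALSE]
    bins_a <- bins_all[annotated]
    p <- numeric(spec$n_bins)
    n_annot <- integer(spec$n_bins)
    for (b in seq_len(spec$n_bins)) {
      sel <- bins_a == b
      n_annot[b] <- sum(sel)
      p[b] <- bin_confidence(ea[sel, , drop = FALSE], ann)
    }
    out[[sid]] <- list(spec = spec, p = p,
                       n_edges = tabulate(bins_all, nbins = spec$n_bins),
                       n_annotated = n_annot)
  }
  structure(list(sources = out, n_bins = as.integer(n_bins)),
            class = "confidence_table")
}

#' @export
print.confidence_table <- function(x, ...) {
  cat(sprintf("Confidence table: %d source(s), %d bins each\n",
              length(x$sources), x$n_bins))
  for (sid in names(x$sources)) {
    s <- x$sources[[sid]]
    cat(sprintf("  %s: score range [%g, %g], p in [%.3f, %.3f]\n",
                sid, s$spec$s_min, s$spec$s_max, min(s$p), max(s$p)))
  }
  invisible(x)
}

#' @export
as.data.frame.confidence_table <- function(x, ...) {
  do.call(rbind, lapply(names(x$sources), function(sid) {
    s <- x$sources[[sid]]
    n <- s$spec$n_bins
    width <- (s$spec$s_max - s$spec$s_min) / n
    data.frame(source = sid, bin = seq_len(n),
               s_lo = s$spec$s_min + (seq_len(n) - 1) * width,
               s_hi = s$spec$s_min + seq_len(n) * width,
               n_edges = s$n_edges, n_annotated = s$n_annotated, p = s$p,
               stringsAsFactors = FALSE)
  }))
}

# confidence of each score under one source's calibration (bin 0 -> 0)
conf_lookup <- function(table, source_id, scores) {
  s <- table$sources[[source_id]]
  if (is.null(s)) stop(sprintf("confidence table does not cover source '%s'", source_id),
                       call. = FALSE)
  b <- bin_index(scores, s$spec)
  ifelse(b == 0L, 0, s$p[pmax(b, 1L)])
}

#' Integrate evidence sources into one confidence-weighted network
#'
#' Takes the union of all sources' edges. Each source's raw score is mapped
#' through its calibration to a per-source confidence `p`; the integrated
#' confidence of an edge is the noisy-OR combination
#' `r = 1 - prod(1 - p_k)` over the sources reporting the pair, so evidence
#' from independent sources accumulates and an edge seen by several sources
#' outranks the same edge seen by one.
#'
#' @param nets list of [evidence_network()] objects.
#' @param table a [confidence_table()] covering every source in `nets`.
#' @return An [integrated_network()]; each edge's `sources` field records
#'   the contributing source ids (comma-joined, sorted).
#' @export
integrate_networks <- function(nets, table) {
  parts <- lapply(nets, function(net) {
    e <- net$edges
    data.frame(gene1 = e$gene1, gene2 = e$gene2,
               p = conf_lookup(table, net$source_id, e$score),
               source = rep(net$source_id, nrow(e)),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, parts)
  if (is.null(long) || !nrow(long)) {
    return(integrated_network(character(), character(), numeric(), character()))
  }
  key <- pair_key(long$gene1, long$gene2)
  o <- order(key, long$source, method = "radix")
  long <- long[o, , drop = FALSE]; key <- key[o]
  grp <- factor(key, levels = unique(key))
  r <- 1 - vapply(split(long$p, grp), function(p) prod(1 - p), 0)
  src <- vapply(split(long$source, grp),
                function(s) paste(sort(unique(s), method = "radix"), collapse = ","), "")
  first <- !duplicated(key)
  integrated_network(long$gene1[first], long$gene2[first], r, src)
}
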