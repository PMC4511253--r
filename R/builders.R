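## Builders: one function per evidence source, each returning an
## evidence_network, plus orthology-based annotation transfer.

#' Read a gene-expression matrix
#'
#' First column is the gene id, remaining columns are samples; a header row
#' is required. Missing values use the token `NA`.
#'
#' @param path path to the TSV file.
#' @param experiment_id label attached to the matrix (defaults to the file
#'   name without extension).
#' @return A numeric matrix (genes x samples) with an `experiment_id`
#'   attribute.
#' @export
read_expression <- function(path, experiment_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop(sprintf("%s: expected gene id column plus >=1 sample", path), call. = FALSE)
  genes <- check_gene_ids(as.character(df[[1L]]))
  if (anyDuplicated(genes)) stop(sprintf("%s: duplicated gene ids", path), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  attr(m, "experiment_id") <- experiment_id %||% sub("\\.[^.]*$", "", basename(path))
  m
}

#' Combine expression experiments into one consistent matrix
#'
#' Each experiment's gene rows are z-scored across that experiment's samples
#' (removing platform scale differences), then rows are aligned by gene id
#' and the sample axes concatenated. Genes absent from an experiment carry
#' `NA` in that block; rows with zero variance within an experiment are not
#' z-scorable and become `NA` in that block (they are flagged in the
#' `"constant_genes"` attribute and contribute no correlations).
#'
#' @param experiments list of matrices from [read_expression()] (or any
#'   genes x samples numeric matrices with rownames; an `experiment_id`
#'   attribute names each block).
#' @param de_genes optional character vector; if given, only these genes
#'   (e.g. a differential-expression call made upstream) are retained.
#' @return Combined genes x samples matrix; column names are
#'   `<experiment>.<sample>`.
#' @export
combine_expression <- function(experiments, de_genes = NULL) {
  if (!is.list(experiments) || !length(experiments)) {
    stop("experiments must be a non-empty list of matrices", call. = FALSE)
  }
  ids <- vapply(seq_along(experiments), function(i) {
    attr(experiments[[i]], "experiment_id") %||% names(experiments)[i] %||% sprintf("exp%d", i)
  }, "")
  if (anyDuplicated(ids)) ids <- make.unique(ids)

  zblocks <- vector("list", length(experiments))
  constant <- character()
  for (i in seq_along(experiments)) {
    m <- experiments[[i]]
    if (is.null(rownames(m))) stop("each experiment matrix needs gene rownames", call. = FALSE)
    if (!is.null(de_genes)) m <- m[rownames(m) %in% de_genes, , drop = FALSE]
    mu <- rowMeans(m, na.rm = TRUE)
    sdv <- apply(m, 1L, stats::sd, na.rm = TRUE)
    nobs <- rowSums(!is.na(m))
    bad <- !is.finite(sdv) | sdv == 0 | nobs < 2L
    z <- (m - mu) / sdv
    z[bad, ] <- NA_real_
    constant <- c(constant, rownames(m)[bad & nobs > 0])
    colnames(z) <- paste(ids[i], colnames(m) %||% seq_len(ncol(m)), sep = ".")
    zblocks[[i]] <- z
  }
  genes <- sort_c(as.character(unlist(lapply(zblocks, rownames), use.names = FALSE)))
  if (!length(genes)) stop("no usable genes after filtering", call. = FALSE)
  out <- do.call(cbind, lapply(zblocks, function(z) {
    full <- matrix(NA_real_, nrow = length(genes), ncol = ncol(z),
                   dimnames = list(genes, colnames(z)))
    full[rownames(z), ] <- z
    full
  }))
  attr(out, "experiments") <- ids
  attr(out, "constant_genes") <- sort_c(constant)
  out
}

#' Build a coexpression network
#'
#' Connects two genes when the Pearson correlation of their expression
#' profiles, over pairwise-complete samples, meets the threshold. The
#' threshold applies to the signed coefficient: strong negative correlations
#' produce no edge. The correlation itself is the edge's raw score (and
#' doubles as the source's confidence score).
#'
#' @param expr combined genes x samples matrix (see [combine_expression()]).
#' @param threshold minimum Pearson r for an edge (default 0.7).
#' @param min_pairs minimum shared non-missing samples per gene pair
#'   (default 3).
#' @param source_id source label.
#' @return An [evidence_network()].
#' @export
build_coexpression <- function(expr, threshold = 0.7, min_pairs = 3,
                               source_id = "coexpression") {
  if (!is.matrix(expr) || nrow(expr) < 2L) {
    stop("expr must be a matrix with at least 2 genes", call. = FALSE)
  }
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must lie in (0, 1]", call. = FALSE)
  genes <- rownames(expr)
  r <- suppressWarnings(stats::cor(t(expr), use = "pairwise.complete.obs"))
  nshared <- tcrossprod((!is.na(expr)) * 1)
  ut <- upper.tri(r)
  keep <- ut & is.finite(r) & r >= threshold & nshared >= min_pairs
  idx <- which(keep, arr.ind = TRUE)  # column-major, same order as r[keep]
  evidence_network(genes[idx[, 1L]], genes[idx[, 2L]], r[keep],
                   source_id = source_id)
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Twelve standard columns: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path path to the tabular file.
#' @return Data frame of hits with the standard column names.
#' @export
read_blast_hits <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 12L) stop(sprintf("%s: expected 12 BLAST outfmt-6 columns", path), call. = FALSE)
  df <- df[, 1:12]
  names(df) <- cols
  df$qseqid <- as.character(df$qseqid)
  df$sseqid <- as.character(df$sseqid)
  df
}

#' Build a sequence-homology network from BLAST hits
#'
#' A hit becomes an edge when (i) the alignment covers at least `min_cov` of
#' the query protein's length, (ii) the percent identity is at least
#' `min_sim` (as a fraction), and (iii) the e-value is strictly below
#' `max_e`; self-hits are discarded. The raw score is `-log10(evalue)`;
#' e-values of 0 are clamped to 1e-180 (score 180) so scores stay finite for
#' binning. Reciprocal hits collapse to one edge keeping the maximum score.
#'
#' @param hits data frame from [read_blast_hits()] (needs `qseqid`,
#'   `sseqid`, `pident`, `length`, `evalue`).
#' @param query_lengths named numeric vector: protein id -> sequence length
#'   (aa). Every query in `hits` must be present.
#' @param min_cov minimum alignment-length / query-length (default 0.5).
#' @param min_sim minimum identity fraction (default 0.4).
#' @param max_e e-value must be `< max_e` (default 1e-4).
#' @param source_id source label.
#' @return An [evidence_network()]; the `"filter_counts"` attribute records
#'   how many hits each filter removed.
#' @export
build_homology <- function(hits, query_lengths, min_cov = 0.5, min_sim = 0.4,
                           max_e = 1e-4, source_id = "homology") {
  qlen <- query_lengths[hits$qseqid]
  if (any(is.na(qlen))) {
    missing <- unique(hits$qseqid[is.na(qlen)])
    stop(sprintf("no query length for: %s", paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  not_self <- hits$qseqid != hits$sseqid
  cov_ok <- hits$length / qlen >= min_cov
  sim_ok <- hits$pident / 100 >= min_sim
  e_ok <- hits$evalue < max_e
  keep <- not_self & cov_ok & sim_ok & e_ok
  score <- -log10(pmax(hits$evalue[keep], 1e-180))
  net <- evidence_network(hits$qseqid[keep], hits$sseqid[keep], score,
                          source_id = source_id)
  attr(net, "filter_counts") <- c(self = sum(!not_self),
                                  coverage = sum(not_self & !cov_ok),
                                  similarity = sum(not_self & cov_ok & !sim_ok),
                                  evalue = sum(not_self & cov_ok & sim_ok & !e_ok))
  net
}

#' Read protein-domain assignments
#'
#' Expects lines `protein<TAB>domain_id`; duplicates collapse.
#'
#' @param path path to the TSV file.
#' @return A named list (class `domain_assignment`): protein id -> sorted
#'   unique domain ids.
#' @export
read_domain_assignments <- function(path) {
  d <- read_data_lines(path)
  fields <- strsplit(d$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop(sprintf("%s: line %d has fewer than 2 fields", path, d$lineno[bad]),
         call. = FALSE)
  }
  domain_assignment(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
}

#' Construct a domain assignment
#'
#' @param protein,domain parallel character vectors; one row per
#'   (protein, domain).
#' @return A named list of domain sets, class `domain_assignment`.
#' @export
domain_assignment <- function(protein, domain) {
  protein <- check_gene_ids(as.character(protein), "protein id")
  domain <- as.character(domain)
  if (any(!nzchar(domain))) stop("empty domain identifiers are not allowed", call. = FALSE)
  o <- order(protein, domain, method = "radix")
  protein <- protein[o]; domain <- domain[o]
  dup <- duplicated(paste(protein, domain, sep = "\t"))
  entries <- split(domain[!dup], factor(protein[!dup], levels = unique(protein[!dup])))
  structure(lapply(entries, as.character), class = "domain_assignment")
}

#' Build a shared-domain network
#'
#' Connects every protein pair sharing at least one functional domain; the
#' raw score is the number of shared domains.
#'
#' @param assign a `domain_assignment` (see [read_domain_assignments()]).
#' @param source_id source label.
#' @return An [evidence_network()].
#' @export
build_domain <- function(assign, source_id = "domain") {
  by_domain <- split(rep(names(assign), lengths(assign)),
                     unlist(assign, use.names = FALSE))
  pair_list <- lapply(by_domain, function(p) {
    p <- sort(unique(p), method = "radix")
    if (length(p) < 2L) return(NULL)
    t(utils::combn(p, 2L))
  })
  m <- do.call(rbind, pair_list)
  if (is.null(m) || !nrow(m)) {
    return(evidence_network(character(), character(), numeric(), source_id = source_id))
  }
  key <- pair_key(m[, 1L], m[, 2L])
  counts <- table(key)
  first <- !duplicated(key)
  evidence_network(m[first, 1L], m[first, 2L],
                   as.numeric(counts[key[first]]), source_id = source_id)
}

#' Transfer a donor-organism network by interologs
#'
#' For each donor edge (A, B) with score s and every ortholog pair (a of A,
#' b of B) with a != b, emits the target edge (a, b) with the donor's score.
#' Many-to-many ortholog groups enumerate all combinations; duplicates keep
#' the maximum score; edges with an unmapped endpoint are skipped.
#'
#' @param donor_net the donor organism's [evidence_network()].
#' @param orth an [ortholog_map()] from donor to target genes.
#' @param source_id source label (default derives from the donor network and
#'   organism).
#' @return An [evidence_network()] over target genes.
#' @export
build_interolog <- function(donor_net, orth,
                            source_id = paste0(donor_net$source_id, ".", orth$donor_organism)) {
  e <- donor_net$edges
  p <- orth$pairs
  m <- merge(e, p, by.x = "gene1", by.y = "donor")
  names(m)[names(m) == "target"] <- "a"
  m <- merge(m, p, by.x = "gene2", by.y = "donor")
  names(m)[names(m) == "target"] <- "b"
  m <- m[m$a != m$b, , drop = FALSE]
  evidence_network(m$a, m$b, m$score, source_id = source_id)
}

#' Transfer function annotations by orthology
#'
#' Each target gene absent from `ann` receives the union of its orthologs'
#' terms across all donor organisms; genes already annotated are returned
#' unchanged. Setting `fill_only = FALSE` widens the rule to union-merge
#' donor terms into already-annotated genes as well.
#'
#' @param ann the target organism's [annotation_map()].
#' @param donors list of donors, each a list with elements `ann` (the
#'   donor's annotation map) and `orth` (the donor-to-target
#'   [ortholog_map()]).
#' @param fill_only if `TRUE` (default), only genes with no prior annotation
#'   are filled.
#' @return A new [annotation_map()]; never smaller than `ann`.
#' @export
transfer_annotations <- function(ann, donors, fill_only = TRUE) {
  gene <- rep(names(ann), lengths(ann))
  term <- unlist(ann, use.names = FALSE)
  for (d in donors) {
    if (!inherits(d$orth, "ortholog_map") || !inherits(d$ann, "annotation_map")) {
      stop("each donor needs elements 'ann' (annotation_map) and 'orth' (ortholog_map)",
           call. = FALSE)
    }
    p <- d$orth$pairs
    donor_terms <- unclass(d$ann)[p$donor]
    has <- !vapply(donor_terms, is.null, TRUE)
    tgt <- rep(p$target[has], lengths(donor_terms[has]))
    trm <- unlist(donor_terms[has], use.names = FALSE)
    if (fill_only) {
      keep <- !(tgt %in% names(ann))
      tgt <- tgt[keep]; trm <- trm[keep]
    }
    gene <- c(gene, tgt)
    term <- c(term, trm)
  }
  annotation_map(gene, term)
}
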