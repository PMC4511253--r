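#' Construct an evidence network
#'
#' An evidence network is one source's undirected, weighted gene graph:
#' a set of unordered gene pairs, each carrying the source's raw association
#' score. Edges are stored once in canonical (byte-lexicographic) order,
#' self-edges are dropped, and duplicate pairs are collapsed keeping the
#' maximum score (the strongest evidence the source offers for that pair).
#'
#' @param gene1,gene2 character vectors of gene identifiers (opaque,
#'   case-sensitive strings without whitespace).
#' @param score numeric raw scores, one per pair.
#' @param source_id label for the evidence source (e.g. `"coexpression"`).
#' @return An object of class `evidence_network` with elements `source_id`,
#'   `edges` (data frame `gene1`, `gene2`, `score` in canonical order),
#'   `n_self_dropped` and `n_duplicates_collapsed`.
#' @seealso [read_edge_list()], [build_coexpression()], [build_homology()],
#'   [build_domain()], [build_interolog()]
#' @export
evidence_network <- function(gene1, gene2, score, source_id) {
  if (!is.character(source_id) || length(source_id) != 1L || !nzchar(source_id)) {
    stop("source_id must be a non-empty string", call. = FALSE)
  }
  gene1 <- as.character(gene1)
  gene2 <- as.character(gene2)
  score <- as.numeric(score)
  if (length(gene1) != length(gene2) || length(gene1) != length(score)) {
    stop("gene1, gene2 and score must have equal length", call. = FALSE)
  }
  if (length(gene1)) {
    check_gene_ids(c(gene1, gene2))
    if (any(!is.finite(score))) stop("scores must be finite", call. = FALSE)
  }
  self <- gene1 == gene2
  n_self <- sum(self)
  gene1 <- gene1[!self]; gene2 <- gene2[!self]; score <- score[!self]

  if (length(gene1)) {
    cp <- canonical_pairs(gene1, gene2)
    key <- pair_key(cp$gene1, cp$gene2)
    o <- order(key, -score, method = "radix")
    cp <- cp[o, , drop = FALSE]; score <- score[o]; key <- key[o]
    dup <- duplicated(key)
    edges <- data.frame(gene1 = cp$gene1[!dup], gene2 = cp$gene2[!dup],
                        score = score[!dup], stringsAsFactors = FALSE)
    n_dup <- sum(dup)
  } else {
    edges <- data.frame(gene1 = character(), gene2 = character(),
                        score = numeric(), stringsAsFactors = FALSE)
    n_dup <- 0L
  }
  rownames(edges) <- NULL
  structure(list(source_id = source_id, edges = edges,
                 n_self_dropped = n_self, n_duplicates_collapsed = n_dup),
            class = "evidence_network")
}

#' Construct an integrated network
#'
#' The integrated network is the union graph over all evidence sources; each
#' edge carries a confidence `r` in \[0, 1\] and the provenance set of source
#' ids that reported the pair.
#'
#' @param gene1,gene2 character vectors of gene identifiers.
#' @param confidence numeric confidences in \[0, 1\].
#' @param sources character vector; for each edge, the contributing source
#'   ids joined by commas.
#' @return An object of class `integrated_network` with element `edges`
#'   (data frame `gene1`, `gene2`, `confidence`, `sources`).
#' @seealso [integrate_networks()], [fgn()]
#' @export
integrated_network <- function(gene1, gene2, confidence, sources) {
  gene1 <- as.character(gene1)
  gene2 <- as.character(gene2)
  confidence <- as.numeric(confidence)
  sources <- as.character(sources)
  n <- length(gene1)
  if (length(gene2) != n || length(confidence) != n || length(sources) != n) {
    stop("all arguments must have equal length", call. = FALSE)
  }
  if (n) {
    check_gene_ids(c(gene1, gene2))
    if (any(gene1 == gene2)) stop("self-edges are not allowed", call. = FALSE)
    if (any(!is.finite(confidence)) || any(confidence < 0) || any(confidence > 1)) {
      stop("confidence must lie in [0, 1]", call. = FALSE)
    }
    if (any(!nzchar(sources))) {
      stop("every edge needs a non-empty provenance set", call. = FALSE)
    }
    cp <- canonical_pairs(gene1, gene2)
    key <- pair_key(cp$gene1, cp$gene2)
    if (anyDuplicated(key)) stop("duplicate edges in integrated network", call. = FALSE)
    o <- order(key, method = "radix")
    edges <- data.frame(gene1 = cp$gene1[o], gene2 = cp$gene2[o],
                        confidence = confidence[o], sources = sources[o],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene1 = character(), gene2 = character(),
                        confidence = numeric(), sources = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "integrated_network")
}

#' Genes present in a network
#'
#' @param net an `evidence_network` or `integrated_network`.
#' @return Sorted character vector of the distinct gene ids incident to at
#'   least one edge.
#' @export
network_genes <- function(net) {
  e <- net$edges
  sort_c(c(e$gene1, e$gene2))
}

n_edges <- function(net) nrow(net$edges)

#' @export
print.evidence_network <- function(x, ...) {
  cat(sprintf("Evidence network '%s': %d edges, %d genes\n",
              x$source_id, n_edges(x), length(network_genes(x))))
  if (n_edges(x)) {
    cat(sprintf("  raw score range: [%g, %g]\n",
                min(x$edges$score), max(x$edges$score)))
  }
  if (x$n_self_dropped || x$n_duplicates_collapsed) {
    cat(sprintf("  dropped %d self-edge(s), collapsed %d duplicate(s)\n",
                x$n_self_dropped, x$n_duplicates_collapsed))
  }
  invisible(x)
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf("Integrated network: %d edges, %d genes\n",
              n_edges(x), length(network_genes(x))))
  if (n_edges(x)) {
    cat(sprintf("  confidence range: [%g, %g]\n",
                min(x$edges$confidence), max(x$edges$confidence)))
  }
  invisible(x)
}

#' @export
as.data.frame.evidence_network <- function(x, ...) x$edges

#' @export
as.data.frame.integrated_network <- function(x, ...) x$edges

#' Construct an annotation map
#'
#' Maps each annotated gene to its non-empty set of function terms (GO
#' Biological Process identifiers). Genes with no terms are absent from the
#' map: presence in the map is what "annotated" means throughout the package.
#'
#' @param gene,term parallel character vectors; one row per (gene, term)
#'   assignment. Duplicates collapse.
#' @return An object of class `annotation_map`: a named list of sorted,
#'   unique term sets, keyed by gene id.
#' @seealso [read_annotations()], [transfer_annotations()], [shares_function()]
#' @export
annotation_map <- function(gene = character(), term = character()) {
  gene <- as.character(gene)
  term <- as.character(term)
  if (length(gene) != length(term)) stop("gene and term must have equal length", call. = FALSE)
  if (length(gene)) {
    check_gene_ids(gene)
    if (any(!nzchar(term))) stop("empty term identifiers are not allowed", call. = FALSE)
    o <- order(gene, term, method = "radix")
    gene <- gene[o]; term <- term[o]
    dup <- duplicated(paste(gene, term, sep = "\t"))
    gene <- gene[!dup]; term <- term[!dup]
    entries <- split(term, factor(gene, levels = unique(gene)))
    entries <- lapply(entries, as.character)
  } else {
    entries <- structure(list(), names = character())
  }
  structure(entries, class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("Annotation map: %d annotated genes, %d distinct terms\n",
              length(x), length(unique(unlist(x, use.names = FALSE)))))
  invisible(x)
}

#' @export
as.data.frame.annotation_map <- function(x, ...) {
  data.frame(gene = rep(names(x), lengths(x)),
             term = unlist(x, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Construct an ortholog map
#'
#' A many-to-many set of (donor gene, target gene) ortholog pairs between a
#' donor organism and the target organism.
#'
#' @param donor_gene,target_gene parallel character vectors of ids.
#' @param donor_organism label for the donor organism.
#' @return An object of class `ortholog_map` with elements `donor_organism`
#'   and `pairs` (data frame `donor`, `target`, unique rows).
#' @export
ortholog_map <- function(donor_gene = character(), target_gene = character(),
                         donor_organism = "donor") {
  donor_gene <- as.character(donor_gene)
  target_gene <- as.character(target_gene)
  if (length(donor_gene) != length(target_gene)) {
    stop("donor_gene and target_gene must have equal length", call. = FALSE)
  }
  if (length(donor_gene)) {
    check_gene_ids(donor_gene, "donor gene id")
    check_gene_ids(target_gene, "target gene id")
    o <- order(donor_gene, target_gene, method = "radix")
    donor_gene <- donor_gene[o]; target_gene <- target_gene[o]
    dup <- duplicated(paste(donor_gene, target_gene, sep = "\t"))
    donor_gene <- donor_gene[!dup]; target_gene <- target_gene[!dup]
  }
  pairs <- data.frame(donor = donor_gene, target = target_gene,
                      stringsAsFactors = FALSE)
  structure(list(donor_organism = donor_organism, pairs = pairs),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("Ortholog map '%s': %d pairs (%d donor, %d target genes)\n",
              x$donor_organism, nrow(x$pairs),
              length(unique(x$pairs$donor)), length(unique(x$pairs$target))))
  invisible(x)
}

#' Construct a reference gene set
#'
#' Genes previously associated with the trait of interest; the positives for
#' guilt-by-association prioritization and evaluation.
#'
#' @param genes character vector of gene ids (deduplicated).
#' @param trait_label non-empty trait name.
#' @return An object of class `reference_genes`.
#' @export
reference_genes <- function(genes, trait_label = "trait") {
  genes <- check_gene_ids(as.character(genes))
  if (!length(genes)) stop("reference gene set must be non-empty", call. = FALSE)
  if (!is.character(trait_label) || !nzchar(trait_label)) {
    stop("trait_label must be a non-empty string", call. = FALSE)
  }
  structure(list(trait_label = trait_label, genes = sort_c(genes)),
            class = "reference_genes")
}

#' @export
print.reference_genes <- function(x, ...) {
  cat(sprintf("Reference gene set '%s': %d genes\n",
              x$trait_label, length(x$genes)))
  invisible(x)
}

ref_ids <- function(refs) {
  if (inherits(refs, "reference_genes")) refs$genes else check_gene_ids(as.character(refs))
}

## ---- readers / writers -----------------------------------------------------

read_data_lines <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an edge-list TSV as an evidence network
#'
#' Expects tab-separated lines `gene1<TAB>gene2<TAB>score` (further columns
#' ignored). Lines starting with `#` are comments; a header line is detected
#' by a non-numeric third field. Self-edges are dropped and duplicate pairs
#' keep the maximum score.
#'
#' @param path path to the TSV file.
#' @param source_id label for the evidence source.
#' @return An [evidence_network()].
#' @export
read_edge_list <- function(path, source_id) {
  d <- read_data_lines(path)
  fields <- strsplit(d$lines, "\t", fixed = TRUE)
  if (length(fields)) {
    f1 <- fields[[1L]]
    if (length(f1) >= 3L && is.na(suppressWarnings(as.numeric(f1[3L])))) {
      fields <- fields[-1L]
      d$lineno <- d$lineno[-1L]
    }
  }
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop(sprintf("%s: line %d has %d field(s); expected at least 3 (gene1, gene2, score)",
                 path, d$lineno[bad], nf[bad]), call. = FALSE)
  }
  g1 <- vapply(fields, `[[`, "", 1L)
  g2 <- vapply(fields, `[[`, "", 2L)
  s_chr <- vapply(fields, `[[`, "", 3L)
  s <- suppressWarnings(as.numeric(s_chr))
  if (any(is.na(s))) {
    bad <- which(is.na(s))[1L]
    stop(sprintf("%s: line %d has non-numeric score '%s'",
                 path, d$lineno[bad], s_chr[bad]), call. = FALSE)
  }
  evidence_network(g1, g2, s, source_id = source_id)
}

#' Read an integrated-network TSV
#'
#' Reads the four-column format written by [write_edge_list()] for an
#' integrated network: `gene1<TAB>gene2<TAB>score<TAB>sources`.
#'
#' @param path path to the TSV file.
#' @return An [integrated_network()].
#' @export
read_integrated_network <- function(path) {
  d <- read_data_lines(path)
  fields <- strsplit(d$lines, "\t", fixed = TRUE)
  if (length(fields)) {
    f1 <- fields[[1L]]
    if (length(f1) >= 3L && is.na(suppressWarnings(as.numeric(f1[3L])))) {
      fields <- fields[-1L]
      d$lineno <- d$lineno[-1L]
    }
  }
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    bad <- which(nf < 4L)[1L]
    stop(sprintf("%s: line %d has %d field(s); expected 4 (gene1, gene2, score, sources)",
                 path, d$lineno[bad], nf[bad]), call. = FALSE)
  }
  g1 <- vapply(fields, `[[`, "", 1L)
  g2 <- vapply(fields, `[[`, "", 2L)
  r <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(r))) {
    bad <- which(is.na(r))[1L]
    stop(sprintf("%s: line %d has non-numeric confidence", path, d$lineno[bad]),
         call. = FALSE)
  }
  src <- vapply(fields, `[[`, "", 4L)
  integrated_network(g1, g2, r, src)
}

#' Write a network as an edge-list TSV
#'
#' Writes edges in canonical order with scores at full precision, so that
#' `read_edge_list(write_edge_list(n))` reproduces `n` exactly. Integrated
#' networks gain a fourth `sources` column with comma-joined provenance.
#'
#' @param net an `evidence_network` or `integrated_network`.
#' @param path destination path.
#' @param comments optional character vector written as leading `#` comment
#'   lines (run metadata).
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path, comments = NULL) {
  e <- net$edges
  hdr <- if (inherits(net, "integrated_network")) {
    "gene1\tgene2\tscore\tsources"
  } else {
    "gene1\tgene2\tscore"
  }
  body <- if (inherits(net, "integrated_network")) {
    if (nrow(e)) paste(e$gene1, e$gene2, num_chr(e$confidence), e$sources, sep = "\t") else character()
  } else {
    if (nrow(e)) paste(e$gene1, e$gene2, num_chr(e$score), sep = "\t") else character()
  }
  pre <- if (length(comments)) paste0("# ", comments) else character()
  writeLines(c(pre, hdr, body), path)
  invisible(path)
}

#' Read gene function annotations
#'
#' Two dialects: `tsv2col` (lines `gene<TAB>term`) and `gaf` (GAF 2.x; uses
#' column 2 as the object id and column 5 as the GO id, keeping only rows
#' whose aspect column is `"P"`, i.e. the Biological Process domain).
#'
#' @param path path to the annotation file.
#' @param dialect `"tsv2col"` or `"gaf"`.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, dialect = c("tsv2col", "gaf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "tsv2col") {
    keep <- nzchar(lines) & !startsWith(lines, "#")
    lines <- lines[keep]; lineno <- which(keep)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2L)) {
      bad <- which(nf < 2L)[1L]
      stop(sprintf("%s: line %d has fewer than 2 fields", path, lineno[bad]),
           call. = FALSE)
    }
    annotation_map(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
  } else {
    keep <- nzchar(lines) & !startsWith(lines, "!")
    lines <- lines[keep]; lineno <- which(keep)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 15L)) {
      bad <- which(nf < 15L)[1L]
      stop(sprintf("%s: line %d has %d columns; GAF 2.x requires at least 15",
                   path, lineno[bad], nf[bad]), call. = FALSE)
    }
    obj <- vapply(fields, `[[`, "", 2L)
    go <- vapply(fields, `[[`, "", 5L)
    aspect <- vapply(fields, `[[`, "", 9L)
    bp <- aspect == "P"
    annotation_map(obj[bp], go[bp])
  }
}

#' Write an annotation map as a two-column TSV
#'
#' @param ann an [annotation_map()].
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path) {
  df <- as.data.frame(ann)
  writeLines(c("gene\tterm",
               if (nrow(df)) paste(df$gene, df$term, sep = "\t") else character()),
             path)
  invisible(path)
}

#' Read an ortholog-pair TSV
#'
#' Expects lines `donor_gene<TAB>target_gene`; duplicate pairs collapse.
#'
#' @param path path to the TSV file.
#' @param donor donor organism label.
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path, donor = "donor") {
  d <- read_data_lines(path)
  fields <- strsplit(d$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop(sprintf("%s: line %d has fewer than 2 fields", path, d$lineno[bad]),
         call. = FALSE)
  }
  ortholog_map(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L),
               donor_organism = donor)
}

#' Read a gene list (one id per line)
#'
#' @param path path to the list file (`#` comments skipped).
#' @param trait_label trait name for the resulting reference set.
#' @return A [reference_genes()] object.
#' @export
read_gene_list <- function(path, trait_label = "trait") {
  d <- read_data_lines(path)
  reference_genes(trimws(d$lines), trait_label = trait_label)
}
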