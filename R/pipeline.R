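## Pipeline driver: validate a structured configuration, run
## builders -> annotation transfer -> calibration -> integration ->
## prioritization -> evaluation, writing every stage's artifact.

#' Read a pipeline configuration file
#'
#' YAML key/value configuration; see [run_all()] for recognized keys. All
#' analysis defaults (coexpression threshold 0.7, homology coverage 0.5,
#' similarity 0.4, e-value 1e-4, 10 score bins, PPV cutoff 0.5) are filled
#' in when absent.
#'
#' @param path path to a YAML file.
#' @return A named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

config_defaults <- function() {
  list(n_bins = 10L, min_ppv = 0.5, loo = TRUE, scope = "subnet",
       coexpr_threshold = 0.7, coexpr_min_pairs = 3L,
       homology_min_cov = 0.5, homology_min_sim = 0.4, homology_max_e = 1e-4,
       seed = 1L, annotation_dialect = "tsv2col")
}

as_pipeline_config <- function(cfg) {
  defs <- config_defaults()
  for (k in names(defs)) cfg[[k]] <- cfg[[k]] %||% defs[[k]]
  structure(cfg, class = "pipeline_config")
}

config_error <- function(msg) {
  stop(structure(class = c("fgn_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

validate_config <- function(cfg) {
  cfg <- as_pipeline_config(cfg)
  if (is.null(cfg$annotations)) config_error("config: 'annotations' path is required")
  if (!file.exists(cfg$annotations)) {
    config_error(sprintf("config: annotation file not found: %s", cfg$annotations))
  }
  if (is.null(cfg$references)) config_error("config: 'references' path is required")
  if (!file.exists(cfg$references)) {
    config_error(sprintf("config: reference list not found: %s", cfg$references))
  }
  has_builder <- !is.null(cfg$expression) || !is.null(cfg$blast) ||
    !is.null(cfg$domains) || !is.null(cfg$interolog)
  if (is.null(cfg$sources) && !has_builder) {
    config_error("config: need at least one of 'sources' or a builder input")
  }
  for (p in unlist(cfg$sources)) {
    if (!file.exists(p)) config_error(sprintf("config: source file not found: %s", p))
  }
  if (is.null(cfg$outdir)) config_error("config: 'outdir' is required")
  cfg
}

stage <- function(name, expr) {
  message(sprintf("[fgnet] stage %s", name))
  tryCatch(expr, error = function(e) {
    if (inherits(e, "fgn_config_error")) stop(e)
    stop(structure(class = c("fgn_stage_error", "error", "condition"),
                   list(message = sprintf("stage '%s' failed: %s",
                                          name, conditionMessage(e)),
                        call = NULL)))
  })
}

#' Run the full pipeline
#'
#' Executes the end-to-end workflow on a configuration: build evidence
#' networks from raw inputs (and/or load pre-built edge lists), transfer
#' annotations by orthology, calibrate per-source confidences, integrate by
#' noisy-OR, prioritize against the reference gene list, and evaluate by
#' ROC/AUC and the PPV criterion. Every stage writes its artifact into
#' `outdir`; run metadata (parameters, seed) is embedded as `#` comments.
#'
#' Recognized configuration keys:
#' \describe{
#'   \item{sources}{named list of pre-built edge-list TSV paths.}
#'   \item{expression}{list of expression TSV paths (builds a coexpression
#'     source with `coexpr_threshold`, `coexpr_min_pairs`).}
#'   \item{blast}{list with `hits` and `lengths` paths (builds a homology
#'     source with `homology_min_cov`, `homology_min_sim`, `homology_max_e`).}
#'   \item{domains}{protein-domain TSV path (builds a shared-domain source).}
#'   \item{interolog}{list of entries with `network`, `orthologs`, `donor`
#'     (builds one interolog source per donor network).}
#'   \item{annotations, annotation_dialect}{target annotation file.}
#'   \item{annotation_transfer}{list of entries with `annotations`,
#'     `dialect`, `orthologs`, `donor` for orthology-based transfer.}
#'   \item{references}{reference gene list path.}
#'   \item{n_bins, min_ppv, loo, scope, seed, outdir}{analysis parameters.}
#' }
#'
#' @param config a `pipeline_config`, plain list, or path to a YAML file.
#' @return Invisibly, a list with the fitted `fgn` object, the ranking, the
#'   evaluation, and the written artifact paths.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(sprintf("n_bins=%d min_ppv=%g loo=%s scope=%s seed=%d",
                    cfg$n_bins, cfg$min_ppv, cfg$loo, cfg$scope, cfg$seed))

  nets <- stage("build", {
    nets <- list()
    for (nm in names(cfg$sources)) {
      nets[[nm]] <- read_edge_list(cfg$sources[[nm]], source_id = nm)
    }
    if (!is.null(cfg$expression)) {
      exps <- lapply(cfg$expression, read_expression)
      combined <- combine_expression(exps)
      nets$coexpression <- build_coexpression(combined,
                                              threshold = cfg$coexpr_threshold,
                                              min_pairs = cfg$coexpr_min_pairs)
    }
    if (!is.null(cfg$blast)) {
      hits <- read_blast_hits(cfg$blast$hits)
      len_df <- utils::read.delim(cfg$blast$lengths, header = FALSE, sep = "\t",
                                  stringsAsFactors = FALSE)
      qlen <- stats::setNames(as.numeric(len_df[[2L]]), as.character(len_df[[1L]]))
      nets$homology <- build_homology(hits, qlen, min_cov = cfg$homology_min_cov,
                                      min_sim = cfg$homology_min_sim,
                                      max_e = cfg$homology_max_e)
    }
    if (!is.null(cfg$domains)) {
      nets$domain <- build_domain(read_domain_assignments(cfg$domains))
    }
    for (it in cfg$interolog) {
      donor_net <- read_edge_list(it$network, source_id = it$donor %||% "donor")
      orth <- read_ortholog_map(it$orthologs, donor = it$donor %||% "donor")
      built <- build_interolog(donor_net, orth)
      nets[[built$source_id]] <- built
    }
    for (net in nets) {
      message(sprintf("[fgnet]   source %s: %d edges (%d self dropped, %d duplicates collapsed)",
                      net$source_id, n_edges(net), net$n_self_dropped,
                      net$n_duplicates_collapsed))
    }
    nets
  })

  ann <- stage("annotations", {
    ann <- read_annotations(cfg$annotations, dialect = cfg$annotation_dialect)
    if (!is.null(cfg$annotation_transfer)) {
      donors <- lapply(cfg$annotation_transfer, function(d) {
        list(ann = read_annotations(d$annotations, dialect = d$dialect %||% "tsv2col"),
             orth = read_ortholog_map(d$orthologs, donor = d$donor %||% "donor"))
      })
      n0 <- length(ann)
      ann <- transfer_annotations(ann, donors)
      message(sprintf("[fgnet]   annotation transfer: %d -> %d annotated genes",
                      n0, length(ann)))
    }
    write_annotations(ann, file.path(cfg$outdir, "annotations_used.tsv"))
    ann
  })

  fit <- stage("calibrate+integrate", {
    fit <- fgn(unname(nets), ann, n_bins = cfg$n_bins)
    utils::write.table(as.data.frame(fit$table),
                       file.path(cfg$outdir, "confidence_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_edge_list(fit$graph, file.path(cfg$outdir, "integrated.tsv"),
                    comments = meta)
    fit
  })

  ranking <- stage("prioritize", {
    refs <- read_gene_list(cfg$references)
    ranking <- predict(fit, refs, scope = cfg$scope)
    write_ranking(ranking, file.path(cfg$outdir, "ranking.tsv"), comments = meta)
    ranking
  })

  ev <- stage("evaluate", {
    ev <- evaluate_ranking(ranking, loo = cfg$loo, min_ppv = cfg$min_ppv)
    utils::write.table(ev$roc_points, file.path(cfg$outdir, "roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ev$ppv_curve, file.path(cfg$outdir, "ppv.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(auc = ev$auc,
           selected_threshold = if (is.na(ev$selected_threshold)) NULL else ev$selected_threshold,
           n_candidates = length(ev$candidates), candidates = ev$candidates,
           n_genes_ranked = nrow(ranking$scores),
           n_integrated_edges = n_edges(fit$graph),
           parameters = list(n_bins = cfg$n_bins, min_ppv = cfg$min_ppv,
                             loo = cfg$loo, scope = cfg$scope, seed = cfg$seed)),
      file.path(cfg$outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
    ev
  })

  message(sprintf("[fgnet] done: AUC %.4f, %d candidate(s)", ev$auc,
                  length(ev$candidates)))
  invisible(list(fit = fit, ranking = ranking, evaluation = ev,
                 outdir = cfg$outdir))
}
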