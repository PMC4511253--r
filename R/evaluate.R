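## Evaluation of a gene ranking: ROC/AUC against a positive set, the PPV
## curve over score thresholds, and PPV-based candidate selection.

# scores used for evaluation; with loo = TRUE, every positive gene that also
# served as a scoring reference is re-scored with itself removed from the
# reference set (guards self-association inflation for statistics where the
# self term would otherwise enter)
eval_scores <- function(ranking, positives, loo) {
  s <- ranking$scores
  score <- s$dag
  names(score) <- s$gene
  if (loo) {
    redo <- intersect(positives, intersect(s$gene, ranking$refs$genes))
    for (g in redo) {
      d <- dag_score(ranking$network, setdiff(ranking$refs$genes, g), genes = g)
      score[g] <- d$dag
    }
  }
  score
}

auc_midrank <- function(score, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  r <- rank(score)  # midranks for ties
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points_tbl <- function(score, is_pos) {
  o <- order(-score)
  score <- score[o]; is_pos <- is_pos[o]
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  last <- !duplicated(score, fromLast = TRUE)  # last index of each threshold group
  tp <- cumsum(is_pos)[last]
  fp <- cumsum(!is_pos)[last]
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

new_evaluation <- function() {
  structure(list(auc = NA_real_, random_level = NA, roc_points = NULL,
                 ppv_curve = NULL, selected_threshold = NA_real_,
                 candidates = character(), positives = character(),
                 n_positive = NA_integer_, n_negative = NA_integer_),
            class = "fgn_evaluation")
}

#' ROC curve and AUC of a ranking
#'
#' Positives are the evaluation gene set (by default the ranking's reference
#' genes; pass held-out genes to measure recovery); negatives are all other
#' scored genes. The AUC is the Mann-Whitney rank statistic with midranks
#' for ties, equal to the area under the ROC step curve. An AUC at or below
#' 0.5 is flagged as random-level.
#'
#' @param ranking an `fgn_ranking` from [prioritize()].
#' @param positives character vector of positive gene ids; default the
#'   ranking's reference set.
#' @param loo if `TRUE` (default), each positive gene that was also a
#'   scoring reference is re-scored with itself removed from the reference
#'   set before evaluation.
#' @param exclude optional gene ids dropped from the evaluation universe.
#' @return An `fgn_evaluation` with `auc`, `random_level` and `roc_points`
#'   (`fpr`/`tpr`, from (0,0) to (1,1)) filled.
#' @export
roc_auc <- function(ranking, positives = NULL, loo = TRUE, exclude = NULL) {
  positives <- positives %||% ranking$refs$genes
  score <- eval_scores(ranking, positives, loo)
  if (length(exclude)) score <- score[!(names(score) %in% exclude)]
  is_pos <- names(score) %in% positives
  if (!any(is_pos) || all(is_pos)) {
    stop("evaluation universe needs at least one positive and one negative gene",
         call. = FALSE)
  }
  ev <- new_evaluation()
  ev$positives <- intersect(names(score), positives)
  ev$n_positive <- sum(is_pos)
  ev$n_negative <- sum(!is_pos)
  ev$auc <- auc_midrank(score, is_pos)
  ev$random_level <- ev$auc <= 0.5
  ev$roc_points <- roc_points_tbl(score, is_pos)
  ev
}

#' Positive-predictive-value curve of a ranking
#'
#' For each distinct score t (descending), PPV(t) is the fraction of genes
#' scoring at least t that are positives.
#'
#' @inheritParams roc_auc
#' @return An `fgn_evaluation` with `ppv_curve` filled: data frame
#'   `threshold`, `n_selected`, `n_ref_selected`, `ppv`.
#' @export
ppv_curve <- function(ranking, positives = NULL, loo = TRUE, exclude = NULL) {
  positives <- positives %||% ranking$refs$genes
  score <- eval_scores(ranking, positives, loo)
  if (length(exclude)) score <- score[!(names(score) %in% exclude)]
  is_pos <- names(score) %in% positives
  o <- order(-score)
  score <- score[o]; is_pos <- is_pos[o]
  last <- !duplicated(score, fromLast = TRUE)
  n_sel <- which(last)
  n_pos_sel <- cumsum(is_pos)[last]
  ev <- new_evaluation()
  ev$positives <- names(score)[is_pos]
  ev$n_positive <- sum(is_pos)
  ev$n_negative <- sum(!is_pos)
  ev$ppv_curve <- data.frame(threshold = score[last], n_selected = n_sel,
                             n_ref_selected = n_pos_sel, ppv = n_pos_sel / n_sel)
  rownames(ev$ppv_curve) <- NULL
  ev
}

#' Select candidate genes by the PPV criterion
#'
#' Scans the PPV curve for the lowest score threshold whose PPV strictly
#' exceeds `min_ppv` (the most permissive qualifying cut, maximizing the
#' candidate yield); candidates are the non-reference genes scoring at or
#' above it.
#'
#' @inheritParams roc_auc
#' @param min_ppv PPV must exceed this (strictly) at the chosen threshold;
#'   default 0.5.
#' @return An `fgn_evaluation` with `ppv_curve`, `selected_threshold` (`NA`
#'   if no threshold qualifies) and `candidates` filled.
#' @export
select_candidates <- function(ranking, positives = NULL, loo = TRUE,
                              min_ppv = 0.5, exclude = NULL) {
  positives <- positives %||% ranking$refs$genes
  ev <- ppv_curve(ranking, positives, loo = loo, exclude = exclude)
  pc <- ev$ppv_curve
  ok <- pc$ppv > min_ppv
  if (any(ok)) {
    t <- min(pc$threshold[ok])
    ev$selected_threshold <- t
    score <- eval_scores(ranking, positives, loo)
    if (length(exclude)) score <- score[!(names(score) %in% exclude)]
    sel <- names(score)[score >= t & !(names(score) %in% positives)]
    ev$candidates <- sel[order(-score[sel], sel, method = "radix")]
  }
  ev
}

#' Full evaluation of a ranking
#'
#' Convenience wrapper computing ROC/AUC, the PPV curve and the PPV-based
#' candidate selection in one object.
#'
#' @inheritParams select_candidates
#' @return A complete `fgn_evaluation`.
#' @export
evaluate_ranking <- function(ranking, positives = NULL, loo = TRUE,
                             min_ppv = 0.5, exclude = NULL) {
  a <- roc_auc(ranking, positives, loo = loo, exclude = exclude)
  s <- select_candidates(ranking, positives, loo = loo, min_ppv = min_ppv,
                         exclude = exclude)
  s$auc <- a$auc
  s$random_level <- a$random_level
  s$roc_points <- a$roc_points
  s
}

#' @export
print.fgn_evaluation <- function(x, ...) {
  cat("Ranking evaluation\n")
  if (!is.na(x$auc)) {
    cat(sprintf("  AUC: %.4f (%d positives vs %d negatives)%s\n",
                x$auc, x$n_positive, x$n_negative,
                if (isTRUE(x$random_level)) " [random-level]" else ""))
  }
  if (!is.null(x$ppv_curve)) {
    if (is.na(x$selected_threshold)) {
      cat("  no threshold reaches the PPV criterion\n")
    } else {
      cat(sprintf("  selected threshold: %.6g (%d candidate gene(s))\n",
                  x$selected_threshold, length(x$candidates)))
      if (length(x$candidates)) {
        cat(sprintf("  candidates: %s\n",
                    paste(utils::head(x$candidates, 10), collapse = ", ")))
      }
    }
  }
  invisible(x)
}

#' Plot the ROC curve of an evaluation
#'
#' @param x an `fgn_evaluation` with `roc_points` filled.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fgn_evaluation <- function(x, ...) {
  if (is.null(x$roc_points)) stop("no ROC points; run roc_auc() first", call. = FALSE)
  graphics::plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = 8)
  graphics::legend("bottomright", legend = sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' AUC by trapezoidal integration of ROC points
#'
#' Numerical check companion to the rank-statistic AUC; the two agree to
#' floating-point precision.
#'
#' @param roc_points data frame with `fpr`, `tpr`.
#' @return The trapezoid area.
#' @export
trapezoid_auc <- function(roc_points) {
  x <- roc_points$fpr; y <- roc_points$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
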