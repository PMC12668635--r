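#' Binary AUROC by rank statistic
#'
#' Mann-Whitney formulation with average ranks, so tied scores contribute
#' their expected rank (uniform scores give 0.5).
#'
#' @param labels Logical or 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in \[0, 1\], or `NA` if one class is absent.
#' @export
tm_auroc <- function(labels, scores) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Binary AUPRC (average precision)
#'
#' Average precision: the mean of precision at each positive hit when
#' samples are ranked by decreasing score.
#'
#' @inheritParams tm_auroc
#' @return Average precision in \[0, 1\], or `NA` if no positives.
#' @export
tm_auprc <- function(labels, scores) {
  labels <- as.logical(labels)
  if (sum(labels) == 0L) return(NA_real_)
  ord <- order(-scores)
  y <- labels[ord]
  prec_at_k <- cumsum(y) / seq_along(y)
  mean(prec_at_k[y])
}

#' Multiclass classification metrics from class probabilities
#'
#' Computes the seven evaluation metrics of the pipeline: accuracy (argmax),
#' macro one-vs-rest AUROC and AUPRC, and macro-averaged precision, recall,
#' F1 and specificity from the argmax confusion matrix. Classes with no
#' positive example in `y_true` are excluded from the macro averages with a
#' warning.
#'
#' @param y_true Integer or factor vector of true classes.
#' @param y_prob Numeric matrix, one column per class (columns ordered by
#'   class level), rows summing to 1.
#' @return A one-row tibble with columns `accuracy`, `auroc`, `auprc`,
#'   `f1`, `precision`, `recall`, `specificity`.
#' @export
tm_compute_metrics <- function(y_true, y_prob) {
  y_true <- as.integer(as.factor(y_true))
  k <- ncol(y_prob)
  stopifnot(length(y_true) == nrow(y_prob))
  if (max(abs(rowSums(y_prob) - 1)) > 1e-6) {
    abort("`y_prob` rows must sum to 1")
  }
  pred <- max.col(y_prob, ties.method = "first")
  present <- sort(unique(y_true))
  if (length(present) < k) {
    warn("classes with no positives excluded from macro averages")
  }

  per_class <- purrr::map_dfr(present, function(c) {
    pos <- y_true == c
    tp <- sum(pos & pred == c); fp <- sum(!pos & pred == c)
    fn <- sum(pos & pred != c); tn <- sum(!pos & pred != c)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    tibble::tibble(
      auroc = tm_auroc(pos, y_prob[, c]),
      auprc = tm_auprc(pos, y_prob[, c]),
      precision = prec,
      recall = rec,
      f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
      specificity = tn / (tn + fp)
    )
  })

  tibble::tibble(
    accuracy = mean(pred == y_true),
    auroc = mean(per_class$auroc),
    auprc = mean(per_class$auprc),
    f1 = mean(per_class$f1),
    precision = mean(per_class$precision),
    recall = mean(per_class$recall),
    specificity = mean(per_class$specificity)
  )
}
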