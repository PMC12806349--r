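#' Classification metrics for CNV predictions
#'
#' Computes the standard report from true labels and predicted class
#' probabilities: accuracy (fraction of bins whose argmax prediction is
#' correct, ties broken toward the lowest class index), macro-averaged F1
#' and one-vs-rest AUC over the classes present in `true` (classes absent
#' from the truth are skipped and the macro averages renormalized), a
#' per-class precision/recall/F1 table and the full 4x4 confusion matrix.
#'
#' AUC uses the rank (Mann-Whitney) formulation with mid-rank tie handling.
#'
#' @param true CNV label factor of length n.
#' @param probs n x 4 matrix of class probabilities (finite rows).
#' @return object of class `metrics_report`: list with `accuracy`,
#'   `accuracy_pct`, `f1_macro`, `auc_macro`, `per_class` (data.frame),
#'   `confusion` (4x4 counts, rows = truth), `n_test`.
#' @export
compute_metrics <- function(true, probs) {
  true <- cnv_labels(true)
  probs <- as.matrix(probs)
  if (length(true) != nrow(probs)) stop_bad_arg("length(true) != nrow(probs)")
  if (ncol(probs) != 4L) stop_bad_arg("probs must have 4 columns")
  if (any(!is.finite(probs))) stop_bad_arg("probs contains non-finite values")
  lv <- cnv_classes()
  pred <- cnv_labels(argmax_rows(probs) - 1L)
  confusion <- table(factor(true, lv), factor(pred, lv), dnn = c("true", "pred"))
  confusion <- unclass(confusion)
  acc <- sum(diag(confusion)) / sum(confusion)
  present <- lv[lv %in% as.character(unique(true))]
  per_class <- do.call(rbind, lapply(lv, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else if (cl %in% present) 0 else NA_real_
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(confusion[cl, ]))
  }))
  rownames(per_class) <- NULL
  f1s <- per_class$f1[per_class$class %in% present]
  f1_macro <- mean(f1s, na.rm = TRUE)
  aucs <- vapply(present, function(cl) auc_binary(true == cl, probs[, match(cl, lv)]),
                 numeric(1))
  aucs <- aucs[!is.na(aucs)]
  auc_macro <- if (length(aucs)) mean(aucs) else NA_real_
  structure(list(accuracy = acc, accuracy_pct = 100 * acc,
                 f1_macro = f1_macro, auc_macro = auc_macro,
                 per_class = per_class, confusion = confusion,
                 n_test = length(true)),
            class = "metrics_report")
}

## one-vs-rest AUC by the rank statistic; NA if one of the groups is empty
auc_binary <- function(is_pos, score) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  accuracy %.2f%%  F1(macro) %.4f  AUC(macro) %.4f\n",
              x$n_test, x$accuracy_pct, x$f1_macro, x$auc_macro))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param metrics a [compute_metrics()] report.
#' @param path output path.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "metrics_report"))
  obj <- list(accuracy = metrics$accuracy, accuracy_pct = metrics$accuracy_pct,
              f1_macro = metrics$f1_macro, auc_macro = metrics$auc_macro,
              per_class = metrics$per_class,
              confusion = unname(apply(metrics$confusion, 1L, as.integer,
                                       simplify = FALSE)),
              n_test = metrics$n_test)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' 2-D PCA of learned features
#'
#' Projects an n x d feature matrix (raw contact rows, node2vec embeddings
#' or GCN hidden features) onto its top two principal components, for
#' visual inspection of how well CNV classes separate.
#'
#' @param features numeric matrix with at least 2 non-constant columns.
#' @return n x 2 coordinate matrix, components ordered by decreasing
#'   variance.
#' @export
embed_pca_2d <- function(features) {
  features <- as.matrix(features)
  if (ncol(features) < 2) stop_bad_arg("need at least 2 feature columns")
  if (all(apply(features, 2L, stats::sd) == 0)) {
    stop_bad_arg("features are constant; PCA undefined")
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  unname(pc$x[, 1:2, drop = FALSE])
}

#' Mean silhouette width of a labeled embedding
#'
#' Average silhouette coefficient of the label groups under Euclidean
#' distance; higher means better-separated classes. Used to compare GCN
#' hidden features against raw-matrix PCA.
#'
#' @param coords numeric matrix of point coordinates.
#' @param labels group labels (factor or vector).
#' @return mean silhouette width in `[-1, 1]`.
#' @export
mean_silhouette <- function(coords, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop_bad_arg("need >= 2 groups")
  D <- as.matrix(stats::dist(coords))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                    function(g) {
                      idx <- labels == g
                      if (any(idx)) mean(D[i, idx]) else Inf
                    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
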