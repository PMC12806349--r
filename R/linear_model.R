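#' Train/test split over bins
#'
#' @param n_bins number of bins.
#' @param train_fraction fraction of bins assigned to the training set
#'   (default 0.6, the standard 60/40 protocol).
#' @param seed RNG seed.
#' @return list with disjoint, exhaustive integer index vectors `train` and
#'   `test`.
#' @export
split_bins <- function(n_bins, train_fraction = 0.6, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_bad_arg("`train_fraction` must be in (0, 1)")
  }
  n_train <- max(1L, round(n_bins * train_fraction))
  train <- with_seed(seed, sort(sample.int(n_bins, n_train)))
  list(train = train, test = setdiff(seq_len(n_bins), train))
}

## softmax over rows of a logit matrix, numerically stabilised
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## Multinomial logistic regression by full-batch gradient descent.
## X: n x p (already standardized), Y: n x 4 one-hot. Returns list(W, b, loss).
fit_multinomial_gd <- function(X, Y, epochs, lr, seed, l2 = 0) {
  p <- ncol(X); K <- ncol(Y); n <- nrow(X)
  W <- with_seed(seed, matrix(stats::rnorm(p * K, sd = 0.01), p, K))
  b <- rep(0, K)
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    P <- softmax_rows(X %*% W + matrix(b, n, K, byrow = TRUE))
    loss[e] <- -mean(rowSums(Y * log(pmax(P, 1e-12)))) + l2 * sum(W^2) / 2
    G <- (P - Y) / n
    W <- W - lr * (crossprod(X, G) + l2 * W)
    b <- b - lr * colSums(G)
  }
  list(W = W, b = b, loss = loss)
}

one_hot <- function(labels, K = 4L) {
  codes <- label_codes(labels)
  Y <- matrix(0, length(codes), K)
  Y[cbind(seq_along(codes), codes + 1L)] <- 1
  Y
}

## argmax with lowest-index tie-break (max.col breaks ties randomly)
argmax_rows <- function(P) {
  apply(P, 1L, which.max) # which.max takes the first maximum: lowest index
}

#' Per-chromosome linear CNV classifier
#'
#' Fits the 4-class linear transformation model `y = softmax(x W + b)` that
#' maps a bin's full row of contact counts (or a reduced feature vector) to
#' CNV class probabilities, by full-batch gradient descent on the mean
#' cross-entropy against one-hot labels. Each chromosome gets its own model
#' because the feature dimension is the chromosome length in bins.
#'
#' @param x a [contact_matrix()] (rows are used as features) or a plain
#'   numeric feature matrix with one row per bin (e.g. from
#'   [reduce_dimensions()]).
#' @param labels per-bin CNV labels (length `n_bins`).
#' @param train_fraction,seed train/test split (see [split_bins()]); the
#'   seed also fixes the weight initialisation.
#' @param epochs,lr gradient-descent schedule (defaults 500 epochs at
#'   learning rate 0.1 on standardized features).
#' @param l2 ridge penalty on `W` (default 0.1); the bins-by-bins design is
#'   always wider than the training set, so a little shrinkage is needed for
#'   the fit to generalise.
#' @param transform `"log1p"`, `"none"` or `NULL` (auto: `log1p` when `x`
#'   is a contact matrix of raw counts, `none` for pre-reduced features).
#'   Log-transforming counts turns the multiplicative copy-number effect
#'   into an additive shift shared by every column, which is what a linear
#'   map can exploit.
#' @param standardize centre/scale feature columns before fitting (the
#'   scaling is stored and re-applied at prediction time). Default `TRUE`;
#'   raw Hi-C counts span orders of magnitude and unscaled gradient descent
#'   is poorly conditioned.
#' @return object of class `linear_cnv`: the learnable `W` (p x 4) and `b`
#'   (length 4), the feature scaling, the split, and `metrics` — a
#'   [compute_metrics()] report on the held-out bins.
#' @seealso [predict.linear_cnv()], [fit_shared_linear()]
#' @export
fit_linear_cnv <- function(x, labels, train_fraction = 0.6, seed = 1,
                           epochs = 500, lr = 0.1, l2 = 0.1,
                           transform = NULL, standardize = TRUE) {
  is_cm <- inherits(x, "contact_matrix")
  X <- if (is_cm) x$values else as.matrix(x)
  if (is.null(transform)) transform <- if (is_cm) "log1p" else "none"
  transform <- match.arg(transform, c("log1p", "none"))
  if (transform == "log1p") X <- log1p(X)
  labels <- cnv_labels(labels)
  n <- nrow(X)
  if (length(labels) != n) stop_bad_arg("labels length != number of rows")
  if (n < 10) stop_bad_arg("need at least 10 bins")
  split <- split_bins(n, train_fraction, seed)
  if (length(unique(labels[split$train])) < 2) {
    stop_bad_arg("training split contains a single CNV class; cannot fit")
  }
  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  fit <- fit_multinomial_gd(Xs[split$train, , drop = FALSE],
                            one_hot(labels[split$train]),
                            epochs = epochs, lr = lr, seed = seed, l2 = l2)
  model <- structure(
    list(W = fit$W, b = fit$b, feature_dim = ncol(X),
         center = center, scale = scale, standardize = standardize,
         transform = transform, split = split, loss = fit$loss, seed = seed),
    class = "linear_cnv"
  )
  ## held-out evaluation (X is already transformed here)
  Pte <- softmax_rows(Xs[split$test, , drop = FALSE] %*% fit$W +
                        matrix(fit$b, length(split$test), 4L, byrow = TRUE))
  colnames(Pte) <- cnv_classes()
  model$metrics <- compute_metrics(labels[split$test], Pte)
  model
}

#' Predict CNV classes with a fitted linear model
#'
#' Applies the stored feature scaling and the linear map, returning per-bin
#' class probabilities and the argmax label (ties broken toward the lowest
#' class index).
#'
#' @param object a fitted `linear_cnv` model.
#' @param newdata numeric matrix with `feature_dim` columns (or a
#'   [contact_matrix()] whose rows are the features).
#' @param ... unused.
#' @return list with `labels` (factor) and `prob` (n x 4 matrix; rows sum
#'   to 1).
#' @export
predict.linear_cnv <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "contact_matrix")) newdata$values else as.matrix(newdata)
  if (ncol(X) != object$feature_dim) {
    stop_bad_arg("feature dimension mismatch: model expects ",
                 object$feature_dim, ", got ", ncol(X))
  }
  if (identical(object$transform, "log1p")) X <- log1p(X)
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  P <- softmax_rows(Xs %*% object$W +
                      matrix(object$b, nrow(X), 4L, byrow = TRUE))
  colnames(P) <- cnv_classes()
  list(labels = cnv_labels(argmax_rows(P) - 1L), prob = P)
}

#' @export
print.linear_cnv <- function(x, ...) {
  cat(sprintf("<linear_cnv> %d features -> 4 classes", x$feature_dim))
  if (!is.null(x$metrics)) {
    cat(sprintf("; held-out accuracy %.4f (n=%d)", x$metrics$accuracy,
                x$metrics$n_test))
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.linear_cnv <- function(object, ...) {
  rbind(bias = object$b, object$W)
}

#' Weight-shared linear model across chromosomes
#'
#' Pools the per-chromosome 60% training splits of several chromosomes whose
#' features have been reduced to a common dimension, fits one shared linear
#' map, and reports held-out metrics per chromosome and pooled. Used to ask
#' whether the linear read-count/CNV pattern generalises across chromosomes.
#'
#' @param datasets list of `list(features =, labels =)` entries, one per
#'   chromosome; all feature matrices must share the same column count.
#' @inheritParams fit_linear_cnv
#' @return object of class `shared_linear_cnv`: the shared model plus
#'   `per_chrom` metrics and `pooled` metrics.
#' @export
fit_shared_linear <- function(datasets, train_fraction = 0.6, seed = 1,
                              epochs = 500, lr = 0.1, l2 = 0.1,
                              standardize = TRUE) {
  if (length(datasets) < 1) stop_bad_arg("need at least one dataset")
  dims <- vapply(datasets, function(d) ncol(as.matrix(d$features)), integer(1))
  if (length(unique(dims)) != 1) {
    stop_bad_arg("mixed feature dimensions across chromosomes: ",
                 paste(dims, collapse = ", "))
  }
  seeds <- derive_seeds(seed, length(datasets))
  splits <- lapply(seq_along(datasets), function(i) {
    split_bins(nrow(as.matrix(datasets[[i]]$features)), train_fraction, seeds[i])
  })
  Xtr <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    as.matrix(datasets[[i]]$features)[splits[[i]]$train, , drop = FALSE]
  }))
  ytr <- unlist(lapply(seq_along(datasets), function(i) {
    as.character(cnv_labels(datasets[[i]]$labels)[splits[[i]]$train])
  }))
  ytr <- cnv_labels(ytr)
  if (length(unique(ytr)) < 2) stop_bad_arg("pooled training split has one class")
  center <- rep(0, ncol(Xtr)); scale <- rep(1, ncol(Xtr))
  if (standardize) {
    center <- colMeans(Xtr)
    scale <- apply(Xtr, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  Xs <- sweep(sweep(Xtr, 2L, center), 2L, scale, "/")
  fit <- fit_multinomial_gd(Xs, one_hot(ytr), epochs = epochs, lr = lr,
                            seed = seed, l2 = l2)
  model <- structure(
    list(W = fit$W, b = fit$b, feature_dim = ncol(Xtr),
         center = center, scale = scale, standardize = standardize,
         transform = "none", split = splits, loss = fit$loss, seed = seed),
    class = c("shared_linear_cnv", "linear_cnv")
  )
  per_chrom <- lapply(seq_along(datasets), function(i) {
    te <- splits[[i]]$test
    pred <- predict(model, as.matrix(datasets[[i]]$features)[te, , drop = FALSE])
    compute_metrics(cnv_labels(datasets[[i]]$labels)[te], pred$prob)
  })
  all_true <- unlist(lapply(seq_along(datasets), function(i) {
    as.character(cnv_labels(datasets[[i]]$labels)[splits[[i]]$test])
  }))
  all_prob <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    predict(model,
            as.matrix(datasets[[i]]$features)[splits[[i]]$test, , drop = FALSE])$prob
  }))
  model$per_chrom <- per_chrom
  model$metrics <- compute_metrics(cnv_labels(all_true), all_prob)
  model
}

#' @export
print.shared_linear_cnv <- function(x, ...) {
  cat(sprintf("<shared_linear_cnv> %d features, %d chromosome(s); pooled accuracy %.4f\n",
              x$feature_dim, length(x$per_chrom), x$metrics$accuracy))
  invisible(x)
}

#' Persist / restore a linear model as portable JSON
#'
#' @param model a `linear_cnv` fit.
#' @param path output path.
#' @export
write_linear_model <- function(model, path) {
  stopifnot(inherits(model, "linear_cnv"))
  obj <- list(W = model$W, b = model$b, feature_dim = model$feature_dim,
              center = model$center, scale = model$scale,
              standardize = model$standardize,
              transform = model$transform %||% "none")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_linear_model
#' @export
read_linear_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- obj$W
  if (!is.matrix(W)) W <- matrix(unlist(W), ncol = 4, byrow = TRUE)
  structure(list(W = W, b = as.numeric(obj$b),
                 feature_dim = as.integer(obj$feature_dim),
                 center = as.numeric(obj$center), scale = as.numeric(obj$scale),
                 standardize = isTRUE(obj$standardize),
                 transform = obj$transform %||% "none"),
            class = "linear_cnv")
}
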