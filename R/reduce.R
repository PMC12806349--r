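#' Dimension reduction of contact-matrix rows
#'
#' Reduces each bin's row of contact counts to `d` features so that
#' chromosomes of different lengths can share one classifier. Three methods:
#'
#' * `pca` — projection onto the top-`d` eigenvectors of the row covariance
#'   (components ordered by decreasing eigenvalue);
#' * `fa` — maximum-likelihood factor analysis with `d` factors and varimax
#'   (orthogonal) rotation, features are regression factor scores;
#' * `lle` — locally linear embedding: each bin's row is reconstructed as a
#'   weighted combination of its `n_neighbors` nearest rows, then a global
#'   `d`-dimensional embedding preserving those weights is found from the
#'   bottom eigenvectors of `(I - W)'(I - W)`.
#'
#' The transform is fitted on the full matrix; train/test splitting happens
#' downstream on the reduced rows. That order mirrors the usual
#' reduce-then-split protocol and is mildly leakage-prone: the unsupervised
#' transform has seen the held-out rows (never their labels).
#'
#' @param matrix a [contact_matrix()] or plain numeric matrix (rows = bins).
#' @param method `"pca"`, `"fa"` or `"lle"`.
#' @param d target dimension (`d < n_bins`).
#' @param n_neighbors neighborhood size for `lle` (must exceed `d`).
#' @param seed seed for the factanal starting values.
#' @return object of class `reduced_dataset`: `features` (n x d), `method`,
#'   `d`, plus the fitted transform for [apply_reduction()].
#' @export
reduce_dimensions <- function(matrix, method = c("pca", "fa", "lle"), d,
                              n_neighbors = max(d + 2L, 10L), seed = 1) {
  method <- match.arg(method)
  X <- if (inherits(matrix, "contact_matrix")) matrix$values else as.matrix(matrix)
  n <- nrow(X)
  if (!is_count(d, 1L) || d >= n) stop_bad_arg("need 1 <= d < n_bins")
  d <- as.integer(d)
  out <- switch(method,
    pca = reduce_pca(X, d),
    fa = reduce_fa(X, d, seed),
    lle = reduce_lle(X, d, n_neighbors)
  )
  structure(c(out, list(method = method, d = d)), class = "reduced_dataset")
}

#' @export
print.reduced_dataset <- function(x, ...) {
  cat(sprintf("<reduced_dataset> %s: %d bins x %d features\n",
              x$method, nrow(x$features), x$d))
  invisible(x)
}

reduce_pca <- function(X, d) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(features = pc$x[, seq_len(d), drop = FALSE],
       center = pc$center,
       rotation = pc$rotation[, seq_len(d), drop = FALSE],
       sdev = pc$sdev[seq_len(d)])
}

reduce_fa <- function(X, d, seed) {
  keep <- which(apply(X, 2L, stats::sd) > 0)
  if (length(keep) <= d) stop_bad_arg("too few non-constant columns for ", d, " factors")
  Xk <- X[, keep, drop = FALSE]
  fit <- with_seed(seed, stats::factanal(Xk, factors = d, rotation = "varimax",
                                         scores = "regression"))
  ## regression scoring coefficients on the standardized variables, so the
  ## transform can be replayed on new rows
  L <- fit$loadings
  R <- fit$correlation
  coefs <- solve(R, L)                      # p x d
  center <- colMeans(Xk)
  scale <- apply(Xk, 2L, stats::sd)
  list(features = unclass(fit$scores), keep = keep, center = center,
       scale = scale, coefs = unclass(coefs))
}

reduce_lle <- function(X, d, n_neighbors) {
  n <- nrow(X)
  k <- as.integer(n_neighbors)
  if (k <= d) stop_bad_arg("lle needs n_neighbors > d")
  if (k >= n) stop_bad_arg("n_neighbors must be < n_bins")
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nbr <- t(apply(D, 1L, function(r) order(r)[seq_len(k)]))
  check_knn_connected(nbr, n)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Z <- sweep(X[nbr[i, ], , drop = FALSE], 2L, X[i, ])
    G <- tcrossprod(Z)
    ## Tikhonov regularisation keeps the local Gram solvable when k > p
    G <- G + diag(k) * (1e-3 * sum(diag(G)) / k + 1e-12)
    w <- solve(G, rep(1, k))
    W[i, nbr[i, ]] <- w / sum(w)
  }
  M <- crossprod(diag(n) - W)
  eig <- eigen(M, symmetric = TRUE)
  ## bottom eigenvectors, discarding the constant one with eigenvalue ~0
  idx <- seq.int(n - 1L, n - d)
  emb <- eig$vectors[, idx, drop = FALSE] * sqrt(n)
  list(features = emb, knn = nbr, weights = W, X_train = X, k = k)
}

## error naming a component if the symmetrized kNN graph is disconnected
check_knn_connected <- function(nbr, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- nbr[i, ]
  }
  for (i in seq_len(n)) for (j in adj[[i]]) adj[[j]] <- c(adj[[j]], i)
  seen <- logical(n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) {
    stop_bad_arg("lle neighbor graph is disconnected: component containing bin ",
                 which(!seen)[1L], " is unreachable from bin 1")
  }
}

#' Apply a fitted reduction to held-out rows
#'
#' Replays the transform stored in a `reduced_dataset` on new rows: linear
#' projection for `pca`, standardized regression scoring for `fa`, and for
#' `lle` the standard out-of-sample extension (reconstruct the new row from
#' its `k` nearest training rows and combine their embeddings with the same
#' weights).
#'
#' @param reduced a [reduce_dimensions()] result.
#' @param rows numeric matrix with the original feature dimension.
#' @return numeric matrix `nrow(rows) x d`.
#' @export
apply_reduction <- function(reduced, rows) {
  stopifnot(inherits(reduced, "reduced_dataset"))
  rows <- as.matrix(rows)
  if (reduced$method == "pca") {
    return(sweep(rows, 2L, reduced$center) %*% reduced$rotation)
  }
  if (reduced$method == "fa") {
    Z <- sweep(sweep(rows[, reduced$keep, drop = FALSE], 2L, reduced$center),
               2L, reduced$scale, "/")
    return(Z %*% reduced$coefs)
  }
  ## lle out-of-sample
  out <- matrix(0, nrow(rows), reduced$d)
  for (r in seq_len(nrow(rows))) {
    x <- rows[r, ]
    dists <- sqrt(colSums((t(reduced$X_train) - x)^2))
    nbr <- order(dists)[seq_len(reduced$k)]
    Z <- sweep(reduced$X_train[nbr, , drop = FALSE], 2L, x)
    G <- tcrossprod(Z)
    G <- G + diag(reduced$k) * (1e-3 * sum(diag(G)) / reduced$k + 1e-12)
    w <- solve(G, rep(1, reduced$k))
    w <- w / sum(w)
    out[r, ] <- colSums(reduced$features[nbr, , drop = FALSE] * w)
  }
  out
}
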