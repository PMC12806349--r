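#' Symmetric-normalized propagation matrix
#'
#' Builds the GCN aggregation operator from a chromosomal graph:
#' `A_hat = D^(-1/2) (W + I) D^(-1/2)`, where `W` is the weighted adjacency,
#' `I` adds unit self-loops and `D` is the degree diagonal of `W + I`.
#' Isolated nodes get `A_hat[i, i] = 1` and propagate only themselves.
#'
#' @param graph a [build_graph()] result.
#' @return n x n symmetric numeric matrix.
#' @export
normalize_adjacency <- function(graph) {
  stopifnot(inherits(graph, "chrom_graph"))
  n <- graph$n_nodes
  W <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    W[cbind(graph$edges$u, graph$edges$v)] <- graph$edges$weight
    W[cbind(graph$edges$v, graph$edges$u)] <- graph$edges$weight
  }
  diag(W) <- diag(W) + 1
  dinv <- 1 / sqrt(rowSums(W))
  W * outer(dinv, dinv)
}

## Seeded parameter initialisation (Glorot-style normal).
gcn_init_params <- function(d_in, hidden = 64, n_classes = 4L,
                            dropout = 0.5, seed = 1) {
  shapes <- list(W1 = c(d_in, hidden), W2 = c(hidden, hidden),
                 W3 = c(hidden, hidden), W4 = c(hidden, hidden),
                 W5 = c(hidden, n_classes))
  params <- with_seed(seed, {
    ps <- lapply(shapes, function(s) {
      matrix(stats::rnorm(prod(s), sd = sqrt(2 / sum(s))), s[1L], s[2L])
    })
    ps$b5 <- rep(0, n_classes)
    ps
  })
  structure(c(params, list(hidden_dim = hidden, dropout_rate = dropout,
                           feature_dim = d_in)),
            class = "gcn_params")
}

#' @export
print.gcn_params <- function(x, ...) {
  cat(sprintf("<gcn_params> %d -> 4x GCN(h=%d) + dense head, dropout %.2f\n",
              x$feature_dim, x$hidden_dim, x$dropout_rate))
  invisible(x)
}

#' Forward pass of the residual 4-layer GCN
#'
#' Computes, with `A` the propagation matrix and `X` the node features:
#' `H1 = tanh(A X W1)`, `H2 = tanh(A H1 W2)`, `H3 = tanh(A H2 W3)`,
#' `H4 = tanh(A (H1 + H3) W4)` (residual connection combining the first and
#' third layers), then `O = sigmoid(dropout(H4) W5 + b5)` per class.
#' Dropout is active only when `training = TRUE`. With `head = "softmax"`
#' the output rows are softmax probabilities instead.
#'
#' @param params a `gcn_params` object.
#' @param prop propagation matrix from [normalize_adjacency()].
#' @param features n x d node feature matrix (node2vec embeddings).
#' @param training apply dropout (uses R's RNG; seed it for reproducibility).
#' @param head `"sigmoid"` (independent per-class probabilities, the model's
#'   native head) or `"softmax"`.
#' @param keep_hidden also return the hidden layers (for visualisation of
#'   the learned structural features).
#' @return n x 4 matrix of class probabilities; with `keep_hidden`, a list
#'   `(O, H1, H2, H3, H4)`.
#' @export
gcn_forward <- function(params, prop, features, training = FALSE,
                        head = c("sigmoid", "softmax"), keep_hidden = FALSE) {
  head <- match.arg(head)
  stopifnot(inherits(params, "gcn_params"))
  if (ncol(features) != params$feature_dim) {
    stop_bad_arg("feature dim mismatch: params expect ", params$feature_dim,
                 ", got ", ncol(features))
  }
  if (nrow(prop) != ncol(prop) || nrow(prop) != nrow(features)) {
    stop_bad_arg("propagation matrix must be n x n matching features")
  }
  H1 <- tanh(prop %*% (features %*% params$W1))
  H2 <- tanh(prop %*% (H1 %*% params$W2))
  H3 <- tanh(prop %*% (H2 %*% params$W3))
  H4 <- tanh(prop %*% ((H1 + H3) %*% params$W4))
  D <- H4
  if (training && params$dropout_rate > 0) {
    mask <- matrix(stats::rbinom(length(H4), 1L, 1 - params$dropout_rate),
                   nrow(H4)) / (1 - params$dropout_rate)
    D <- H4 * mask
  }
  Z <- D %*% params$W5 + matrix(params$b5, nrow(D), 4L, byrow = TRUE)
  O <- if (head == "sigmoid") 1 / (1 + exp(-Z)) else softmax_rows(Z)
  colnames(O) <- cnv_classes()
  if (keep_hidden) list(O = O, H1 = H1, H2 = H2, H3 = H3, H4 = H4) else O
}

## One full forward + backward pass; returns loss and parameter gradients.
## Y: n x 4 one-hot; mask: logical over nodes contributing to the loss.
gcn_backward <- function(params, prop, X, Y, mask, drop_mask = NULL,
                         head = "sigmoid") {
  n_tr <- sum(mask)
  H1 <- tanh(prop %*% (X %*% params$W1))
  H2 <- tanh(prop %*% (H1 %*% params$W2))
  H3 <- tanh(prop %*% (H2 %*% params$W3))
  S <- H1 + H3
  H4 <- tanh(prop %*% (S %*% params$W4))
  D <- if (is.null(drop_mask)) H4 else H4 * drop_mask
  Z <- D %*% params$W5 + matrix(params$b5, nrow(D), 4L, byrow = TRUE)
  if (head == "sigmoid") {
    O <- 1 / (1 + exp(-Z))
    Op <- pmin(pmax(O, 1e-12), 1 - 1e-12)
    loss <- -sum((Y * log(Op) + (1 - Y) * log(1 - Op))[mask, ]) / n_tr
  } else {
    O <- softmax_rows(Z)
    loss <- -sum((Y * log(pmax(O, 1e-12)))[mask, ]) / n_tr
  }
  ## both heads share dL/dZ = (O - Y) / n_train on supervised rows
  dZ <- (O - Y) / n_tr
  dZ[!mask, ] <- 0
  dW5 <- crossprod(D, dZ)
  db5 <- colSums(dZ)
  dD <- tcrossprod(dZ, params$W5)
  dH4 <- if (is.null(drop_mask)) dD else dD * drop_mask
  G4 <- dH4 * (1 - H4^2)
  PG4 <- crossprod(prop, G4)               # prop is symmetric
  dW4 <- crossprod(S, PG4)
  dS <- tcrossprod(PG4, params$W4)
  dH3 <- dS
  G3 <- dH3 * (1 - H3^2)
  PG3 <- crossprod(prop, G3)
  dW3 <- crossprod(H2, PG3)
  dH2 <- tcrossprod(PG3, params$W3)
  G2 <- dH2 * (1 - H2^2)
  PG2 <- crossprod(prop, G2)
  dW2 <- crossprod(H1, PG2)
  dH1 <- tcrossprod(PG2, params$W2) + dS   # residual path
  G1 <- dH1 * (1 - H1^2)
  PG1 <- crossprod(prop, G1)
  dW1 <- crossprod(X, PG1)
  list(loss = loss,
       grads = list(W1 = dW1, W2 = dW2, W3 = dW3, W4 = dW4, W5 = dW5,
                    b5 = db5))
}

adam_state <- function(params) {
  nm <- c("W1", "W2", "W3", "W4", "W5", "b5")
  list(m = lapply(params[nm], function(p) p * 0),
       v = lapply(params[nm], function(p) p * 0), t = 0)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the residual GCN CNV classifier
#'
#' Full-batch training of the 4-layer residual GCN on a chromosomal graph
#' with node2vec features: minimizes the mean cross-entropy of the output
#' probabilities against one-hot CNV labels over a random 60% of the
#' (non-isolated) nodes using the Adam optimizer, and reports held-out
#' metrics on the remaining 40%.
#'
#' @param graph a [build_graph()] result.
#' @param features n x d node feature matrix (e.g. [node2vec_embed()]).
#' @param labels per-bin CNV labels.
#' @param train_fraction node split (default 0.6).
#' @param hidden hidden width of the GCN layers (default 64).
#' @param dropout dropout rate on the dense head input (default 0.5).
#' @param epochs,lr Adam schedule (defaults 150 epochs at 0.01).
#' @param head `"sigmoid"` (native) or `"softmax"`.
#' @param seed seed for split, initialisation and dropout; runs are
#'   bit-reproducible.
#' @return object of class `gcn_cnv`: `params`, `metrics` (held-out
#'   [compute_metrics()] report), `loss` (per-epoch training loss), `split`,
#'   `head`, `prop`.
#' @export
train_gcn <- function(graph, features, labels, train_fraction = 0.6,
                      hidden = 64, dropout = 0.5, epochs = 150, lr = 0.01,
                      head = c("sigmoid", "softmax"), seed = 1) {
  head <- match.arg(head)
  stopifnot(inherits(graph, "chrom_graph"))
  labels <- cnv_labels(labels)
  n <- graph$n_nodes
  if (length(labels) != n) stop_bad_arg("labels length != number of nodes")
  if (nrow(features) != n) stop_bad_arg("features rows != number of nodes")
  usable <- which(!graph$isolated)
  seeds <- derive_seeds(seed, 3)
  sp <- split_bins(length(usable), train_fraction, seeds[1])
  train_idx <- usable[sp$train]
  test_idx <- usable[sp$test]
  if (length(unique(labels[train_idx])) < 2) {
    stop_bad_arg("training split contains a single CNV class; cannot fit")
  }
  prop <- normalize_adjacency(graph)
  params <- gcn_init_params(ncol(features), hidden, dropout = dropout,
                            seed = seeds[2])
  Y <- one_hot(labels)
  mask <- rep(FALSE, n); mask[train_idx] <- TRUE
  state <- adam_state(params)
  loss <- numeric(epochs)
  with_seed(seeds[3], {
    for (e in seq_len(epochs)) {
      drop_mask <- if (dropout > 0) {
        matrix(stats::rbinom(n * hidden, 1L, 1 - dropout), n) / (1 - dropout)
      } else NULL
      bk <- gcn_backward(params, prop, features, Y, mask, drop_mask, head)
      loss[e] <- bk$loss
      upd <- adam_update(params, bk$grads, state, lr)
      params <- upd$params
      state <- upd$state
    }
  })
  O <- gcn_forward(params, prop, features, training = FALSE, head = head)
  model <- structure(
    list(params = params, head = head, prop = prop, features_dim = ncol(features),
         split = list(train = train_idx, test = test_idx), loss = loss,
         seed = seed),
    class = "gcn_cnv"
  )
  model$metrics <- compute_metrics(labels[test_idx],
                                   O[test_idx, , drop = FALSE])
  model$prob <- O
  model
}

#' @export
print.gcn_cnv <- function(x, ...) {
  cat(sprintf("<gcn_cnv> %d-dim features, h=%d, %s head",
              x$params$feature_dim, x$params$hidden_dim, x$head))
  if (!is.null(x$metrics)) {
    cat(sprintf("; held-out accuracy %.4f (n=%d)", x$metrics$accuracy,
                x$metrics$n_test))
  }
  cat("\n")
  invisible(x)
}

#' Predict CNV classes on a (new) graph with a trained GCN
#'
#' @param object a `gcn_cnv` model.
#' @param graph a [build_graph()] result (defaults to the training graph's
#'   stored propagation matrix when omitted together with `features`).
#' @param features node feature matrix matching the model's input dimension.
#' @param ... unused.
#' @return list with `labels` (argmax, lowest-index tie-break) and `prob`.
#' @export
predict.gcn_cnv <- function(object, graph = NULL, features = NULL, ...) {
  prop <- if (is.null(graph)) object$prop else normalize_adjacency(graph)
  if (is.null(features)) stop_bad_arg("`features` required")
  O <- gcn_forward(object$params, prop, features, training = FALSE,
                   head = object$head)
  list(labels = cnv_labels(argmax_rows(O) - 1L), prob = O)
}

#' Transfer a trained GCN to a new chromosome/cell line by fine-tuning
#'
#' Continues optimization of an already-trained GCN on a target graph using
#' only a small random fraction of the target labels as supervision (2% by
#' default, for at most a handful of epochs), then evaluates on the target
#' nodes outside that fraction. The zero-shot metrics (no fine-tuning) are
#' reported alongside for comparison.
#'
#' @param model a [train_gcn()] fit.
#' @param graph target [build_graph()].
#' @param features target node features (same dimension and embedding seed
#'   as the source, so the feature spaces are comparable).
#' @param labels target CNV labels.
#' @param label_fraction fraction of target nodes whose labels are revealed
#'   (default 0.02).
#' @param epochs fine-tuning epochs (default 5).
#' @param lr fine-tuning learning rate (default 0.05; a short schedule needs
#'   larger steps than full training).
#' @param seed RNG seed.
#' @return object of class `gcn_transfer`: fine-tuned `model`, `metrics`
#'   (held-out target metrics after fine-tuning), `zero_shot` (metrics
#'   before fine-tuning on the same held-out nodes), `tuned_on` (indices).
#' @export
fine_tune <- function(model, graph, features, labels, label_fraction = 0.02,
                      epochs = 5, lr = 0.05, seed = 1) {
  stopifnot(inherits(model, "gcn_cnv"), inherits(graph, "chrom_graph"))
  if (label_fraction <= 0 || label_fraction >= 1) {
    stop_bad_arg("`label_fraction` must be in (0, 1)")
  }
  labels <- cnv_labels(labels)
  n <- graph$n_nodes
  usable <- which(!graph$isolated)
  seeds <- derive_seeds(seed, 2)
  n_tune <- max(1L, round(length(usable) * label_fraction))
  tune_idx <- with_seed(seeds[1], sort(sample(usable, n_tune)))
  eval_idx <- setdiff(usable, tune_idx)
  if (length(unique(labels[tune_idx])) < 2) {
    stop_bad_arg("fine-tuning sample contains a single CNV class; ",
                 "increase `label_fraction`")
  }
  prop <- normalize_adjacency(graph)
  zero_O <- gcn_forward(model$params, prop, features, training = FALSE,
                        head = model$head)
  zero_shot <- compute_metrics(labels[eval_idx],
                               zero_O[eval_idx, , drop = FALSE])
  params <- model$params
  Y <- one_hot(labels)
  mask <- rep(FALSE, n); mask[tune_idx] <- TRUE
  state <- adam_state(params)
  loss <- numeric(epochs)
  dropout <- params$dropout_rate
  hidden <- params$hidden_dim
  with_seed(seeds[2], {
    for (e in seq_len(epochs)) {
      drop_mask <- if (dropout > 0) {
        matrix(stats::rbinom(n * hidden, 1L, 1 - dropout), n) / (1 - dropout)
      } else NULL
      bk <- gcn_backward(params, prop, features, Y, mask, drop_mask,
                         model$head)
      loss[e] <- bk$loss
      upd <- adam_update(params, bk$grads, state, lr)
      params <- upd$params
      state <- upd$state
    }
  })
  O <- gcn_forward(params, prop, features, training = FALSE, head = model$head)
  tuned <- model
  tuned$params <- params
  tuned$prop <- prop
  tuned$loss <- loss
  structure(
    list(model = tuned,
         metrics = compute_metrics(labels[eval_idx], O[eval_idx, , drop = FALSE]),
         zero_shot = zero_shot, tuned_on = tune_idx, loss = loss),
    class = "gcn_transfer"
  )
}

#' @export
print.gcn_transfer <- function(x, ...) {
  cat(sprintf("<gcn_transfer> zero-shot accuracy %.4f -> fine-tuned %.4f (%d labeled nodes)\n",
              x$zero_shot$accuracy, x$metrics$accuracy, length(x$tuned_on)))
  invisible(x)
}
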