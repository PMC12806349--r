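#' Build a chromosomal graph from a contact matrix
#'
#' Treats bins as nodes and positive contacts as weighted undirected edges:
#' edge `(i, j)` (with `i != j`) exists when the contact count exceeds
#' `min_weight`, with the count as its weight. The diagonal is ignored
#' (self-interaction enters downstream through the GCN's self-loop term).
#' `top_k` optionally sparsifies a dense graph by keeping an edge only when
#' one endpoint ranks the other among its `top_k` strongest partners.
#'
#' @param matrix a [contact_matrix()] or symmetric numeric matrix. Asymmetric
#'   inputs arising from row/value-shuffling perturbations are symmetrized as
#'   `(M + t(M)) / 2`, and negative entries (e.g. after additive Gaussian
#'   noise) are floored at 0 for the edge rule.
#' @param min_weight strict lower threshold for an edge (default 0: all
#'   positive contacts become edges).
#' @param top_k optional per-node cap on edge partners.
#' @return object of class `chrom_graph`: `n_nodes`, `edges` (data.frame
#'   `u < v`, 1-based, `weight`), sorted adjacency lists `adj`/`w_adj`, and
#'   `isolated` (logical per node).
#' @export
build_graph <- function(matrix, min_weight = 0, top_k = NULL) {
  v <- if (inherits(matrix, "contact_matrix")) matrix$values else as.matrix(matrix)
  if (nrow(v) != ncol(v)) stop_bad_arg("matrix must be square")
  v <- (v + t(v)) / 2
  v[v < 0] <- 0
  n <- nrow(v)
  diag(v) <- 0
  keep <- v > min_weight
  if (!is.null(top_k)) {
    top <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      ord <- order(v[i, ], decreasing = TRUE)
      ord <- ord[v[i, ord] > min_weight]
      top[i, utils::head(ord, top_k)] <- TRUE
    }
    keep <- keep & (top | t(top))
  }
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(u = idx[, 1L], v = idx[, 2L], weight = v[idx])
  edges <- edges[order(edges$u, edges$v), ]
  rownames(edges) <- NULL
  adj <- vector("list", n)
  w_adj <- vector("list", n)
  for (i in seq_len(n)) { adj[[i]] <- integer(0); w_adj[[i]] <- numeric(0) }
  if (nrow(edges)) {
    for (side in 1:2) {
      a <- if (side == 1) edges$u else edges$v
      b <- if (side == 1) edges$v else edges$u
      sp <- split(seq_len(nrow(edges)), a)
      for (nm in names(sp)) {
        i <- as.integer(nm)
        adj[[i]] <- c(adj[[i]], b[sp[[nm]]])
        w_adj[[i]] <- c(w_adj[[i]], edges$weight[sp[[nm]]])
      }
    }
    for (i in seq_len(n)) {
      o <- order(adj[[i]])
      adj[[i]] <- adj[[i]][o]
      w_adj[[i]] <- w_adj[[i]][o]
    }
  }
  structure(list(n_nodes = n, edges = edges, adj = adj, w_adj = w_adj,
                 isolated = lengths(adj) == 0L),
            class = "chrom_graph")
}

#' @export
print.chrom_graph <- function(x, ...) {
  cat(sprintf("<chrom_graph> %d nodes, %d edges, %d isolated\n",
              x$n_nodes, nrow(x$edges), sum(x$isolated)))
  invisible(x)
}

#' Second-order (node2vec) transition distribution
#'
#' The biased-walk rule: stepping from `prev` to `cur`, the unnormalized
#' score of moving on to neighbor `x` is `weight(cur, x)` times `1/p` if
#' `x == prev`, `1` if `x` is adjacent to `prev`, and `1/q` otherwise. With
#' `prev = NULL` (first step) the walk samples proportionally to edge
#' weights. `p = q = 1` reduces to weight-proportional sampling.
#'
#' @param graph a [build_graph()] result.
#' @param prev previous node (1-based) or `NULL` for the first step.
#' @param cur current node (1-based).
#' @param p return parameter.
#' @param q in-out parameter.
#' @return named numeric vector of probabilities over the neighbors of
#'   `cur`, summing to 1.
#' @export
walk_transition_probs <- function(graph, prev, cur, p = 1, q = 1) {
  stopifnot(inherits(graph, "chrom_graph"))
  nb <- graph$adj[[cur]]
  if (length(nb) == 0) stop_bad_arg("node ", cur, " is isolated")
  w <- graph$w_adj[[cur]]
  if (!is.null(prev)) {
    if (!(prev %in% nb)) stop_bad_arg("`prev` must be a neighbor of `cur`")
    bias <- vapply(nb, function(x) {
      if (x == prev) 1 / p
      else if (x %in% graph$adj[[prev]]) 1
      else 1 / q
    }, numeric(1))
    w <- w * bias
  }
  stats::setNames(w / sum(w), nb)
}

#' Generate a node2vec walk corpus
#'
#' Runs `num_walks` biased random walks of `walk_length` steps from every
#' non-isolated node (defaults: length 100, 10 walks per node).
#'
#' @param graph a [build_graph()] result.
#' @param walk_length nodes per walk (default 100).
#' @param num_walks walks started per node (default 10).
#' @inheritParams walk_transition_probs
#' @param seed RNG seed; walks are bit-reproducible.
#' @return object of class `walk_corpus`: integer matrix (one walk per row,
#'   1-based node ids) with attribute `n_nodes`.
#' @export
generate_walks <- function(graph, walk_length = 100, num_walks = 10,
                           p = 1, q = 1, seed = 1) {
  stopifnot(inherits(graph, "chrom_graph"))
  starts <- which(!graph$isolated)
  if (length(starts) == 0) stop_bad_arg("graph has no edges")
  adj0 <- lapply(graph$adj, function(a) a - 1L)
  walks <- cpp_generate_walks(adj0, graph$w_adj, starts - 1L,
                              as.integer(walk_length), as.integer(num_walks),
                              p, q, as.double(seed)) + 1L
  structure(walks, n_nodes = graph$n_nodes, class = "walk_corpus")
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling (5 negatives by default) over the walk
#' corpus, maximizing the log-probability of each node's sampled
#' neighborhood given its embedding. Window size defaults to 10. Isolated
#' nodes (absent from the corpus) receive zero vectors.
#'
#' @param corpus a [generate_walks()] result.
#' @param d embedding dimension (default 64).
#' @param window context window (default 10; the per-pair window is drawn
#'   uniformly from `1..window`, the usual skip-gram schedule).
#' @param epochs passes over the corpus (default 5).
#' @param lr initial learning rate, linearly decayed (default 0.025).
#' @param negative negative samples per positive pair.
#' @param seed RNG seed (also fixes the deterministic per-node
#'   initialisation).
#' @return numeric matrix `n_nodes x d` of node embeddings.
#' @export
train_skipgram <- function(corpus, d = 64, window = 10, epochs = 5,
                           lr = 0.025, negative = 5, seed = 1) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (!is_count(d, 1L)) stop_bad_arg("`d` must be a positive integer")
  n_nodes <- attr(corpus, "n_nodes")
  emb <- cpp_train_sgns(unclass(corpus) - 1L, as.integer(n_nodes),
                        as.integer(d), as.integer(window),
                        as.integer(epochs), lr, as.integer(negative),
                        as.double(seed))
  present <- sort(unique(as.integer(corpus)))
  zero <- setdiff(seq_len(n_nodes), present)
  emb[zero, ] <- 0
  emb
}

#' One-call node2vec embedding of a contact matrix
#'
#' Convenience wrapper: [build_graph()] then [generate_walks()] then
#' [train_skipgram()] with the standard hyperparameters (walk length 100,
#' 10 walks per node, window 10, 64 dimensions).
#'
#' @inheritParams build_graph
#' @inheritParams generate_walks
#' @inheritParams train_skipgram
#' @return list with `embedding` (n x d matrix) and `graph`.
#' @export
node2vec_embed <- function(matrix, d = 64, walk_length = 100, num_walks = 10,
                           window = 10, p = 1, q = 1, epochs = 5, lr = 0.025,
                           negative = 5, seed = 1, min_weight = 0,
                           top_k = NULL) {
  graph <- if (inherits(matrix, "chrom_graph")) matrix else
    build_graph(matrix, min_weight = min_weight, top_k = top_k)
  walks <- generate_walks(graph, walk_length, num_walks, p, q, seed)
  emb <- train_skipgram(walks, d = d, window = window, epochs = epochs,
                        lr = lr, negative = negative, seed = seed)
  list(embedding = emb, graph = graph)
}

#' Write / read an embedding matrix as TSV
#'
#' One row per node: 0-based node index followed by the `d` embedding
#' values.
#'
#' @param embedding numeric matrix (nodes x d).
#' @param path file path.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(node = seq_len(nrow(embedding)) - 1L, embedding)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, header = FALSE)
  m <- as.matrix(df[order(df[[1L]]), -1L, drop = FALSE])
  dimnames(m) <- NULL
  m
}
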