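#' Perturbation operators for robustness testing
#'
#' Five ways of corrupting a (matrix, labels) pair while keeping the rest of
#' the training pipeline fixed, used to probe what the GCN actually learns:
#'
#' * `reconstruct_labels()` — replace every label by an independent uniform
#'   draw from the four CNV classes;
#' * `shuffle_labels()` — randomly permute the label vector (class counts
#'   preserved);
#' * `shuffle_rows()` — randomly permute the rows of the matrix, leaving the
#'   labels in place;
#' * `shuffle_values()` — randomly permute all `n^2` cell values;
#' * `add_value_noise()` — add i.i.d. Gaussian noise (mean 0, sd 1 by
#'   default) to every cell.
#'
#' Each operator is a pure function of its input and seed, and the shuffles
#' return a `report` stating the fraction of entries left unchanged by the
#' permutation, since an "unlucky" shuffle that fixes many entries weakens
#' the perturbation. Shuffled matrices are generally asymmetric; they are
#' symmetrized as `(M + t(M)) / 2` (and noise-negative cells floored at 0)
#' only at graph-construction time, see [build_graph()].
#'
#' @param n_bins number of labels to draw.
#' @param seed RNG seed.
#' @return `reconstruct_labels`: a CNV label factor.
#' @name perturbation
NULL

#' @rdname perturbation
#' @export
reconstruct_labels <- function(n_bins, seed = 1) {
  if (!is_count(n_bins, 1L)) stop_bad_arg("`n_bins` must be a positive integer")
  with_seed(seed, cnv_labels(sample(0:3, n_bins, replace = TRUE)))
}

perturbation_report <- function(kind, fraction_unchanged, seed) {
  structure(list(kind = kind, fraction_unchanged = fraction_unchanged,
                 seed = seed),
            class = "perturbation_report")
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat(sprintf("<perturbation_report> %s (seed %s): %.4f unchanged\n",
              x$kind, format(x$seed), x$fraction_unchanged))
  invisible(x)
}

#' @rdname perturbation
#' @param labels CNV label factor.
#' @return `shuffle_labels`: list with `labels` (a uniform random
#'   permutation of the input) and `report`.
#' @export
shuffle_labels <- function(labels, seed = 1) {
  labels <- cnv_labels(labels)
  perm <- with_seed(seed, sample.int(length(labels)))
  out <- labels[perm]
  list(labels = out,
       report = perturbation_report("label_shuffle", mean(out == labels), seed))
}

#' @rdname perturbation
#' @param matrix a [contact_matrix()].
#' @return `shuffle_rows`: list with `matrix` (plain numeric matrix, rows
#'   permuted, columns untouched), `permutation`, `report`.
#' @export
shuffle_rows <- function(matrix, seed = 1) {
  v <- if (inherits(matrix, "contact_matrix")) matrix$values else as.matrix(matrix)
  perm <- with_seed(seed, sample.int(nrow(v)))
  out <- v[perm, , drop = FALSE]
  list(matrix = out, permutation = perm,
       report = perturbation_report("row_shuffle", mean(out == v), seed))
}

#' @rdname perturbation
#' @return `shuffle_values`: list with `matrix` (all cell values permuted
#'   uniformly) and `report`.
#' @export
shuffle_values <- function(matrix, seed = 1) {
  v <- if (inherits(matrix, "contact_matrix")) matrix$values else as.matrix(matrix)
  perm <- with_seed(seed, sample.int(length(v)))
  out <- v
  out[] <- v[perm]
  list(matrix = out,
       report = perturbation_report("value_shuffle", mean(out == v), seed))
}

#' @rdname perturbation
#' @param mean,sd Gaussian noise parameters (defaults 0 and 1, the standard
#'   normal of the robustness protocol).
#' @param cell_fraction fraction of cells receiving noise (default 1: the
#'   full `n x n` noise matrix).
#' @return `add_value_noise`: list with `matrix` (noise added; may contain
#'   negatives — they are floored only at graph construction) and `report`.
#' @export
add_value_noise <- function(matrix, seed = 1, mean = 0, sd = 1,
                            cell_fraction = 1) {
  v <- if (inherits(matrix, "contact_matrix")) matrix$values else as.matrix(matrix)
  out <- with_seed(seed, {
    noise <- matrix(stats::rnorm(length(v), mean, sd), nrow(v))
    if (cell_fraction < 1) {
      keep <- matrix(stats::runif(length(v)) < cell_fraction, nrow(v))
      noise[!keep] <- 0
    }
    v + noise
  })
  list(matrix = out,
       report = perturbation_report("value_noise", mean(out == v), seed))
}

#' Apply a named perturbation to a (matrix, labels) pair
#'
#' Dispatcher used by the robustness suite and the command line: applies one
#' of the five operators and returns the possibly-modified matrix and
#' labels plus the report.
#'
#' @param matrix a [contact_matrix()] or numeric matrix.
#' @param labels CNV label factor.
#' @param kind one of `"label_reconstruction"`, `"label_shuffle"`,
#'   `"row_shuffle"`, `"value_shuffle"`, `"value_noise"`, or `"none"`.
#' @param seed RNG seed.
#' @param ... passed to the underlying operator.
#' @return list with `matrix` (numeric), `labels`, `report` (`NULL` for
#'   `"none"` and `"label_reconstruction"`).
#' @export
apply_perturbation <- function(matrix, labels,
                               kind = c("none", "label_reconstruction",
                                        "label_shuffle", "row_shuffle",
                                        "value_shuffle", "value_noise"),
                               seed = 1, ...) {
  kind <- match.arg(kind)
  v <- if (inherits(matrix, "contact_matrix")) matrix$values else as.matrix(matrix)
  labels <- cnv_labels(labels)
  switch(kind,
    none = list(matrix = v, labels = labels, report = NULL),
    label_reconstruction = list(
      matrix = v, labels = reconstruct_labels(length(labels), seed),
      report = NULL),
    label_shuffle = {
      r <- shuffle_labels(labels, seed)
      list(matrix = v, labels = r$labels, report = r$report)
    },
    row_shuffle = {
      r <- shuffle_rows(v, seed)
      list(matrix = r$matrix, labels = labels, report = r$report)
    },
    value_shuffle = {
      r <- shuffle_values(v, seed)
      list(matrix = r$matrix, labels = labels, report = r$report)
    },
    value_noise = {
      r <- add_value_noise(v, seed, ...)
      list(matrix = r$matrix, labels = labels, report = r$report)
    })
}
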