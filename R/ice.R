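#' ICE matrix balancing (iterative correction)
#'
#' Iterative correction equalises per-bin coverage by factorising the contact
#' matrix into per-bin multiplicative biases: it repeatedly divides the
#' matrix by the outer product of its (mean-centred) row sums until all
#' retained rows have equal sums. Bins whose row is entirely zero (e.g.
#' homozygous deletions, unmappable regions) are masked out of the iteration
#' and returned untouched, with bias `NA`.
#'
#' At convergence `normalized[i, j] == values[i, j] / (bias[i] * bias[j])`
#' over retained bins, and the maximum relative deviation of retained row
#' sums from their mean is below `tol`.
#'
#' @param matrix a [contact_matrix()].
#' @param tol convergence threshold on the relative row-sum deviation
#'   (default `1e-5`).
#' @param max_iter iteration cap (default 200).
#' @param filter_low_pct optional percentile in `[0, 100)`: additionally mask
#'   the bins whose raw coverage falls below this percentile of the non-zero
#'   coverages. Off (`0`) by default.
#' @return object of class `ice_result`: list with `normalized`
#'   ([contact_matrix()]), `biases` (positive, `NA` for masked bins),
#'   `n_iterations`, `converged`, `masked` (logical vector).
#' @examples
#' m <- contact_matrix(matrix(c(4, 2, 2, 1), 2))
#' ice_normalize(m)
#' @export
ice_normalize <- function(matrix, tol = 1e-5, max_iter = 200,
                          filter_low_pct = 0) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (tol <= 0) stop_bad_arg("`tol` must be > 0")
  v <- matrix$values
  n <- nrow(v)
  cov0 <- rowSums(v)
  masked <- cov0 == 0
  if (filter_low_pct > 0) {
    thr <- stats::quantile(cov0[!masked], filter_low_pct / 100, names = FALSE)
    masked <- masked | cov0 < thr
  }
  if (all(masked)) stop_bad_arg("every row of the matrix is zero")
  keep <- which(!masked)
  w <- v[keep, keep, drop = FALSE]
  bias <- rep(1, length(keep))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    s <- rowSums(w)
    dev <- max(abs(s - mean(s))) / mean(s)
    if (dev < tol) { converged <- TRUE; break }
    f <- s / mean(s)
    bias <- bias * f
    w <- w / outer(f, f)
  }
  out <- v
  out[keep, keep] <- w
  biases <- rep(NA_real_, n)
  biases[keep] <- bias
  structure(
    list(normalized = contact_matrix(out, chrom = matrix$chrom,
                                     bin_size = matrix$bin_size),
         biases = biases, n_iterations = iter, converged = converged,
         masked = masked),
    class = "ice_result"
  )
}

#' @export
print.ice_result <- function(x, ...) {
  cat(sprintf("<ice_result> %d bins (%d masked), %d iteration(s), %s\n",
              length(x$biases), sum(x$masked), x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
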