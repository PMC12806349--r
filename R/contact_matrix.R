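#' Contact matrix container
#'
#' A `contact_matrix` holds one intra-chromosomal Hi-C interaction map: a
#' square, symmetric, non-negative matrix of contact counts between fixed-size
#' genomic bins, together with the chromosome identifier and the bin size in
#' base pairs. Row `i` of the matrix is the 1-D interaction profile of bin `i`
#' against every other bin of the chromosome.
#'
#' @param values square numeric matrix of contact counts (symmetric, no
#'   negative entries, no `NA`/`NaN`).
#' @param chrom chromosome identifier, e.g. `"chr1"`.
#' @param bin_size bin width in base pairs (default 40000, i.e. 40-kb bins).
#' @param sym_tol relative tolerance for the symmetry check.
#' @return an object of class `contact_matrix` with fields `values`, `chrom`,
#'   `bin_size`, `n_bins`.
#' @examples
#' m <- matrix(c(4, 2, 2, 1), 2)
#' contact_matrix(m, chrom = "chrS", bin_size = 40000)
#' @export
contact_matrix <- function(values, chrom = "chr1", bin_size = 40000L,
                           sym_tol = 1e-8) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_bad_arg("`values` must be a numeric matrix")
  }
  if (nrow(values) != ncol(values)) {
    stop_bad_arg("non-square contact matrix: ", nrow(values), " x ", ncol(values))
  }
  if (anyNA(values)) stop_bad_arg("contact matrix contains NA/NaN entries")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_bad_arg("negative count at cell (", bad[1L], ", ", bad[2L], ")")
  }
  asym <- abs(values - t(values))
  scale <- pmax(abs(values), abs(t(values)), 1)
  rel <- asym / scale
  if (any(rel > sym_tol)) {
    bad <- which(rel == max(rel), arr.ind = TRUE)[1L, ]
    stop_bad_arg("asymmetric contact matrix at cell (", bad[1L], ", ", bad[2L],
                 "): ", values[bad[1L], bad[2L]], " vs ", values[bad[2L], bad[1L]])
  }
  ## enforce exact symmetry after the tolerance check
  values <- (values + t(values)) / 2
  dimnames(values) <- NULL
  structure(
    list(values = values, chrom = as.character(chrom),
         bin_size = as.integer(bin_size), n_bins = nrow(values)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %s bp, total count %.6g\n",
              x$chrom, x$n_bins, format(x$bin_size, big.mark = ","),
              sum(x$values)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$values)

#' @export
as.matrix.contact_matrix <- function(x, ...) x$values

#' CNV class vocabulary
#'
#' Bin-level copy-number calls use four classes: deletion (copy number at or
#' below 1), neutral (the diploid 2), duplication (3) and high duplication
#' (4 or more). Labels are stored as a factor over these levels; integer
#' codes 0-3 follow the same order.
#'
#' @return character vector of the four class names, in code order 0-3.
#' @export
cnv_classes <- function() c("DEL", "NEUTRAL", "DUP", "HIGH_DUP")

#' Coerce to a CNV label factor
#'
#' @param x integer codes in 0-3, class-name strings, or a factor over
#'   [cnv_classes()].
#' @return factor with levels `DEL`, `NEUTRAL`, `DUP`, `HIGH_DUP`.
#' @export
cnv_labels <- function(x) {
  lv <- cnv_classes()
  if (is.factor(x)) {
    if (!all(levels(x) %in% lv)) stop_bad_arg("unknown CNV label level")
    return(factor(as.character(x), levels = lv))
  }
  if (is.numeric(x)) {
    if (anyNA(x) || any(x != round(x)) || any(x < 0) || any(x > 3)) {
      stop_bad_arg("numeric CNV codes must be integers in 0..3")
    }
    return(factor(lv[x + 1L], levels = lv))
  }
  if (is.character(x)) {
    if (!all(x %in% lv)) stop_bad_arg("unknown CNV label string")
    return(factor(x, levels = lv))
  }
  stop_bad_arg("cannot coerce ", class(x)[1L], " to CNV labels")
}

## integer codes 0..3 from a label factor
label_codes <- function(labels) as.integer(cnv_labels(labels)) - 1L

#' Read a contact matrix from text
#'
#' Two plain-text dialects are supported. `dense`: a whitespace-separated
#' square numeric table with no header. `triplet`: one `bin_i bin_j count`
#' record per line (0-based bin indices, upper triangle or any subset;
#' entries are mirrored to enforce symmetry, duplicate records sum).
#'
#' @param path file path.
#' @param format `"dense"` or `"triplet"`.
#' @param n_bins matrix dimension for triplet input; inferred as
#'   `max(index) + 1` when omitted.
#' @inheritParams contact_matrix
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("dense", "triplet"),
                                n_bins = NULL, chrom = "chr1",
                                bin_size = 40000L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_bad_arg("no such file: ", path)
  if (format == "dense") {
    vals <- as.matrix(utils::read.table(path, header = FALSE,
                                        colClasses = "numeric"))
    if (nrow(vals) != ncol(vals)) {
      stop_bad_arg("non-square dense matrix in ", path, ": ",
                   nrow(vals), " x ", ncol(vals))
    }
    return(contact_matrix(vals, chrom = chrom, bin_size = bin_size))
  }
  tri <- utils::read.table(path, header = FALSE, col.names = c("i", "j", "x"),
                           colClasses = "numeric")
  if (any(tri$i != round(tri$i)) || any(tri$j != round(tri$j)) ||
      any(tri$i < 0) || any(tri$j < 0)) {
    stop_bad_arg("triplet indices must be non-negative integers (0-based)")
  }
  if (any(tri$x < 0)) stop_bad_arg("negative count in triplet input")
  n <- if (is.null(n_bins)) as.integer(max(tri$i, tri$j) + 1) else as.integer(n_bins)
  vals <- matrix(0, n, n)
  for (k in seq_len(nrow(tri))) {
    i <- tri$i[k] + 1L; j <- tri$j[k] + 1L
    vals[i, j] <- vals[i, j] + tri$x[k]
    if (i != j) vals[j, i] <- vals[j, i] + tri$x[k]
  }
  contact_matrix(vals, chrom = chrom, bin_size = bin_size)
}

#' Write a contact matrix as text
#'
#' Inverse of [read_contact_matrix()]: `dense` writes a tab-separated square
#' table with no header (bit-exact round trip); `triplet` writes the non-zero
#' upper triangle (including the diagonal) as 0-based `bin_i bin_j count`
#' lines.
#'
#' @param matrix a [contact_matrix()].
#' @param path output path.
#' @param format `"dense"` or `"triplet"`.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(matrix, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "contact_matrix"))
  v <- matrix$values
  if (format == "dense") {
    utils::write.table(v, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L,
                     x = v[idx])
    df <- df[order(df$i, df$j), ]
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read / write per-bin CNV labels (BED-like text)
#'
#' One row per bin: `chrom  start_bp  end_bp  copy_number  label` with
#' 0-based half-open coordinates (`start_bp = bin_index * bin_size`).
#'
#' @param path file path.
#' @return for the reader, a list with `labels` (factor), `copy_number`
#'   (integer, `NA` when the file carries no copy numbers), `chrom`,
#'   `bin_size`.
#' @export
read_cnv_labels <- function(path) {
  if (!file.exists(path)) stop_bad_arg("no such file: ", path)
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "cn", "label"))
  ord <- order(df$start)
  df <- df[ord, ]
  widths <- unique(df$end - df$start)
  list(labels = cnv_labels(as.character(df$label)),
       copy_number = as.integer(df$cn),
       chrom = df$chrom[1L],
       bin_size = as.integer(widths[1L]))
}

#' @rdname read_cnv_labels
#' @param labels CNV label factor (see [cnv_labels()]).
#' @param copy_number optional per-bin integer copy numbers.
#' @param chrom,bin_size genomic coordinates of the bins.
#' @export
write_cnv_labels <- function(labels, path, copy_number = NULL,
                             chrom = "chr1", bin_size = 40000L) {
  labels <- cnv_labels(labels)
  n <- length(labels)
  if (is.null(copy_number)) copy_number <- rep(NA_integer_, n)
  stopifnot(length(copy_number) == n)
  df <- data.frame(chrom = chrom,
                   start = (seq_len(n) - 1L) * as.double(bin_size),
                   end = seq_len(n) * as.double(bin_size),
                   cn = copy_number,
                   label = as.character(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coarsen a contact matrix to a lower resolution
#'
#' Aggregates `factor x factor` blocks of bins by summation, e.g. 10-kb bins
#' to 40-kb bins with `factor = 4`. A trailing partial block is summed as-is.
#' Total counts are conserved exactly; `bin_size` is multiplied by `factor`.
#'
#' @param matrix a [contact_matrix()].
#' @param factor integer aggregation factor (>= 1).
#' @return a [contact_matrix()] with `ceiling(n_bins / factor)` bins.
#' @export
coarsen_resolution <- function(matrix, factor) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (!is_count(factor, min = 1L)) stop_bad_arg("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(matrix)
  n <- matrix$n_bins
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  n_out <- max(grp)
  agg <- rowsum(matrix$values, grp, reorder = TRUE)        # n_out x n
  agg <- t(rowsum(t(agg), grp, reorder = TRUE))            # n_out x n_out
  contact_matrix(agg, chrom = matrix$chrom,
                 bin_size = matrix$bin_size * factor)
}
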