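#' Simulate copy-number segments for a synthetic chromosome
#'
#' Places `n_segments` non-overlapping CNV segments on a chromosome of
#' `n_bins` bins. Each segment gets a length drawn uniformly from
#' `[min_len, max_len]` and a copy number drawn uniformly from
#' `copy_number_pool`; bins not covered by any segment keep the diploid
#' copy number 2.
#'
#' @param n_bins number of bins on the chromosome.
#' @param n_segments number of CNV segments to place.
#' @param copy_number_pool non-empty vector of non-negative integer copy
#'   numbers to draw from.
#' @param min_len,max_len segment length bounds, in bins.
#' @param seed RNG seed; identical seeds give identical output.
#' @return an object of class `cnv_segments`: list with `segments` (a
#'   data.frame `start_bin` 0-based inclusive, `end_bin` 0-based exclusive,
#'   `copy_number`) and `n_bins`.
#' @examples
#' simulate_cnv_segments(100, 3, c(1, 3, 4), 5, 10, seed = 1)
#' @export
simulate_cnv_segments <- function(n_bins, n_segments, copy_number_pool = c(1, 3, 4),
                                  min_len = 5, max_len = 20, seed = 1) {
  if (!is_count(n_bins, 1L)) stop_bad_arg("`n_bins` must be a positive integer")
  if (!is_count(n_segments)) stop_bad_arg("`n_segments` must be a non-negative integer")
  if (n_segments > 0 && length(copy_number_pool) == 0) {
    stop_bad_arg("`copy_number_pool` must be non-empty")
  }
  if (any(copy_number_pool < 0) || any(copy_number_pool != round(copy_number_pool))) {
    stop_bad_arg("copy numbers must be non-negative integers")
  }
  if (min_len > max_len || min_len < 1) stop_bad_arg("need 1 <= min_len <= max_len")
  if (n_segments * max_len > n_bins) {
    stop_bad_arg("infeasible packing: ", n_segments, " segments of up to ",
                 max_len, " bins cannot fit in ", n_bins, " bins")
  }
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      copy_number = integer(0))
  if (n_segments == 0) {
    return(structure(list(segments = empty, n_bins = as.integer(n_bins)),
                     class = "cnv_segments"))
  }
  segs <- with_seed(seed, {
    lens <- if (min_len == max_len) rep(as.integer(min_len), n_segments) else
      sample(seq.int(min_len, max_len), n_segments, replace = TRUE)
    cns <- if (length(copy_number_pool) == 1L) {
      rep(as.integer(copy_number_pool), n_segments)
    } else {
      as.integer(sample(copy_number_pool, n_segments, replace = TRUE))
    }
    ## place segments left to right: distribute the leftover space as random
    ## gaps before each segment and after the last one
    slack <- n_bins - sum(lens)
    cuts <- sort(sample.int(slack + 1L, n_segments, replace = TRUE) - 1L)
    starts <- cuts + c(0L, cumsum(lens))[seq_len(n_segments)]
    data.frame(start_bin = as.integer(starts),
               end_bin = as.integer(starts + lens),
               copy_number = cns)
  })
  segs <- segs[order(segs$start_bin), ]
  rownames(segs) <- NULL
  stopifnot(all(segs$end_bin[-nrow(segs)] <= segs$start_bin[-1L]),
            all(segs$start_bin >= 0), all(segs$end_bin <= n_bins))
  structure(list(segments = segs, n_bins = as.integer(n_bins)),
            class = "cnv_segments")
}

#' @export
print.cnv_segments <- function(x, ...) {
  cat(sprintf("<cnv_segments> %d bins, %d segment(s)\n", x$n_bins,
              nrow(x$segments)))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

#' Per-bin copy numbers implied by a segment set
#'
#' @param segments a `cnv_segments` object.
#' @return integer vector of length `n_bins`; uncovered bins are 2.
#' @export
copy_number_profile <- function(segments) {
  stopifnot(inherits(segments, "cnv_segments"))
  cn <- rep(2L, segments$n_bins)
  for (k in seq_len(nrow(segments$segments))) {
    s <- segments$segments[k, ]
    cn[(s$start_bin + 1L):s$end_bin] <- s$copy_number
  }
  cn
}

#' Map copy numbers to the four CNV classes
#'
#' Copy number 0 or 1 is a deletion, 2 is neutral, 3 a duplication, and 4 or
#' more a high duplication. The mapping is total over non-negative integers
#' and idempotent.
#'
#' @param copy_numbers non-negative integer vector of per-bin copy numbers.
#' @return CNV label factor (see [cnv_classes()]).
#' @examples
#' labels_from_copy_number(c(0, 1, 2, 3, 4, 7))
#' @export
labels_from_copy_number <- function(copy_numbers) {
  if (any(copy_numbers < 0) || anyNA(copy_numbers)) {
    stop_bad_arg("copy numbers must be non-negative")
  }
  codes <- ifelse(copy_numbers <= 1, 0L,
                  ifelse(copy_numbers == 2, 1L,
                         ifelse(copy_numbers == 3, 2L, 3L)))
  cnv_labels(codes)
}

#' Simulation configuration for synthetic Hi-C
#'
#' Parameters of the generative contact model: expected contact count between
#' bins `i` and `j` is
#' `base_depth * (|i - j| + 1)^(-decay_exponent) * cn_i * cn_j / 4`,
#' multiplied by `diagonal_boost` when `|i - j| <= 1`. The `cn_i cn_j / 4`
#' term encodes the linear read-count/copy-number relationship: a diploid
#' pair sits exactly at the distance-decay background, and doubling one
#' partner's copy number doubles the expected count. `noise_model =
#' "poisson"` draws each upper-triangle entry independently from a Poisson
#' with that mean and mirrors it.
#'
#' @param n_bins number of bins (>= 10).
#' @param bin_size bin width in bp (default 40000).
#' @param decay_exponent power-law exponent of distance decay (> 0,
#'   default 1, the classic genomic-distance falloff).
#' @param base_depth expected count at genomic distance of one bin for a
#'   diploid pair (> 0).
#' @param diagonal_boost multiplier for self and adjacent-bin contacts,
#'   mimicking short-range dominance of real Hi-C.
#' @param noise_model `"none"` (exact expectations) or `"poisson"`.
#' @param seed RNG seed for the noise draws.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_bins, bin_size = 40000L, decay_exponent = 1,
                       base_depth = 100, diagonal_boost = 5,
                       noise_model = c("none", "poisson"), seed = 1) {
  noise_model <- match.arg(noise_model)
  if (!is_count(n_bins, 10L)) stop_bad_arg("`n_bins` must be an integer >= 10")
  if (base_depth <= 0) stop_bad_arg("`base_depth` must be > 0")
  if (decay_exponent <= 0) stop_bad_arg("`decay_exponent` must be > 0")
  structure(list(n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
                 decay_exponent = decay_exponent, base_depth = base_depth,
                 diagonal_boost = diagonal_boost, noise_model = noise_model,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a Hi-C contact matrix with embedded CNV signal
#'
#' Generates a symmetric contact matrix from the distance-decay model of
#' [sim_config()], with expected counts scaled multiplicatively by the copy
#' numbers of the two interacting bins.
#'
#' @param segments a `cnv_segments` object (the ground truth).
#' @param config a [sim_config()]; `config$n_bins` must match
#'   `segments$n_bins`.
#' @return a [contact_matrix()].
#' @export
simulate_contact_matrix <- function(segments, config) {
  stopifnot(inherits(segments, "cnv_segments"), inherits(config, "sim_config"))
  if (segments$n_bins != config$n_bins) {
    stop_bad_arg("segments and config disagree on n_bins")
  }
  mu <- expected_contacts(segments, config)
  if (config$noise_model == "none") {
    return(contact_matrix(mu, bin_size = config$bin_size))
  }
  n <- config$n_bins
  vals <- with_seed(config$seed, {
    up <- upper.tri(mu, diag = TRUE)
    draws <- numeric(n * n)
    dim(draws) <- c(n, n)
    draws[up] <- stats::rpois(sum(up), mu[up])
    draws + t(draws) - diag(diag(draws))
  })
  contact_matrix(vals, bin_size = config$bin_size)
}

#' Closed-form expected contact counts
#'
#' The noise-free mean matrix of the generative model, useful as an oracle
#' for Monte-Carlo checks.
#'
#' @inheritParams simulate_contact_matrix
#' @return plain numeric matrix of expectations.
#' @export
expected_contacts <- function(segments, config) {
  stopifnot(inherits(segments, "cnv_segments"), inherits(config, "sim_config"))
  n <- config$n_bins
  cn <- copy_number_profile(segments)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- config$base_depth * (d + 1)^(-config$decay_exponent)
  mu <- mu * outer(cn, cn) / 4
  mu[d <= 1] <- mu[d <= 1] * config$diagonal_boost
  mu
}

#' One-call synthetic chromosome
#'
#' Convenience wrapper bundling segment placement, matrix simulation and
#' label construction, used as the standard fixture throughout the test
#' suite.
#'
#' @inheritParams simulate_cnv_segments
#' @param ... passed to [sim_config()] (e.g. `noise_model`, `base_depth`,
#'   `decay_exponent`).
#' @return list with `matrix` ([contact_matrix()]), `labels` (factor),
#'   `copy_number`, `segments`, `config`.
#' @export
simulate_chromosome <- function(n_bins = 1000, n_segments = 10,
                                copy_number_pool = c(1, 2, 3, 4),
                                min_len = 20, max_len = 50, seed = 1, ...) {
  seeds <- derive_seeds(seed, 2)
  segs <- simulate_cnv_segments(n_bins, n_segments, copy_number_pool,
                                min_len, max_len, seed = seeds[1])
  cfg <- sim_config(n_bins = n_bins, seed = seeds[2], ...)
  cn <- copy_number_profile(segs)
  list(matrix = simulate_contact_matrix(segs, cfg),
       labels = labels_from_copy_number(cn),
       copy_number = cn, segments = segs, config = cfg)
}
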