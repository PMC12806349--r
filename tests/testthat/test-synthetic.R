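test_that("simulated segments are disjoint, in bounds and reproducible", {
  s1 <- simulate_cnv_segments(200, 6, c(1, 3, 4), 5, 15, seed = 7)
  s2 <- simulate_cnv_segments(200, 6, c(1, 3, 4), 5, 15, seed = 7)
  s3 <- simulate_cnv_segments(200, 6, c(1, 3, 4), 5, 15, seed = 8)
  expect_identical(s1$segments, s2$segments)
  expect_false(identical(s1$segments, s3$segments))
  df <- s1$segments
  expect_equal(nrow(df), 6)
  expect_true(all(df$start_bin >= 0))
  expect_true(all(df$end_bin <= 200))
  expect_true(all(df$end_bin - df$start_bin >= 5))
  expect_true(all(df$end_bin - df$start_bin <= 15))
  ## sorted and non-overlapping
  expect_true(all(diff(df$start_bin) >= 0))
  expect_true(all(df$end_bin[-6] <= df$start_bin[-1]))
  expect_true(all(df$copy_number %in% c(1, 3, 4)))
})

test_that("infeasible segment packing is rejected", {
  expect_error(simulate_cnv_segments(50, 6, c(1, 3), 10, 10, seed = 1),
               "infeasible")
  ## exactly-full packing is allowed
  s <- simulate_cnv_segments(60, 6, c(1, 3), 10, 10, seed = 1)
  expect_equal(sum(s$segments$end_bin - s$segments$start_bin), 60)
})

test_that("copy-number profile fills uncovered bins with the diploid 2", {
  s <- simulate_cnv_segments(50, 2, c(1, 4), 5, 5, seed = 2)
  cn <- copy_number_profile(s)
  expect_length(cn, 50)
  covered <- unlist(lapply(seq_len(2), function(k) {
    (s$segments$start_bin[k] + 1):s$segments$end_bin[k]
  }))
  expect_true(all(cn[-covered] == 2))
  expect_true(all(cn[covered] %in% c(1, 4)))
})

test_that("copy numbers map onto the four classes at the documented cutoffs", {
  lab <- labels_from_copy_number(c(0, 1, 2, 3, 4, 5, 9))
  expect_equal(as.character(lab),
               c("DEL", "DEL", "NEUTRAL", "DUP", "HIGH_DUP", "HIGH_DUP",
                 "HIGH_DUP"))
  expect_error(labels_from_copy_number(c(2, -1)), "non-negative")
})

test_that("expected contacts follow the closed-form distance-decay law", {
  s <- simulate_cnv_segments(20, 1, 4, 5, 5, seed = 1)
  cfg <- sim_config(20, decay_exponent = 1.2, base_depth = 80,
                    diagonal_boost = 3)
  mu <- expected_contacts(s, cfg)
  cn <- copy_number_profile(s)
  expect_true(isSymmetric(mu))
  ## spot-check one off-diagonal and one boosted cell by hand
  i <- 2; j <- 10
  expect_equal(mu[i, j], 80 * (abs(i - j) + 1)^(-1.2) * cn[i] * cn[j] / 4)
  expect_equal(mu[5, 5], 80 * 3 * cn[5]^2 / 4)
  expect_equal(mu[5, 6], 80 * 2^(-1.2) * 3 * cn[5] * cn[6] / 4)
})

test_that("noise-free simulation returns the exact expectations", {
  s <- simulate_cnv_segments(30, 2, c(1, 3), 4, 6, seed = 5)
  cfg <- sim_config(30, noise_model = "none")
  m <- simulate_contact_matrix(s, cfg)
  expect_s3_class(m, "contact_matrix")
  expect_equal(m$values, expected_contacts(s, cfg))
})

test_that("Poisson noise is unbiased, symmetric, integer and seed-stable", {
  s <- simulate_cnv_segments(60, 2, c(1, 4), 5, 10, seed = 4)
  cfg1 <- sim_config(60, noise_model = "poisson", seed = 11)
  m1 <- simulate_contact_matrix(s, cfg1)
  m2 <- simulate_contact_matrix(s, cfg1)
  expect_identical(m1$values, m2$values)
  m3 <- simulate_contact_matrix(s, sim_config(60, noise_model = "poisson",
                                              seed = 12))
  expect_false(identical(m1$values, m3$values))
  expect_true(isSymmetric(m1$values))
  expect_true(all(m1$values == round(m1$values)))
  ## Monte-Carlo mean over seeds approaches the oracle
  mu <- expected_contacts(s, cfg1)
  draws <- lapply(1:40, function(k) {
    simulate_contact_matrix(s, sim_config(60, noise_model = "poisson",
                                          seed = 100 + k))$values
  })
  avg <- Reduce(`+`, draws) / length(draws)
  ## relative error on well-populated cells
  big <- mu > 20
  expect_lt(max(abs(avg[big] - mu[big]) / mu[big]), 0.15)
})

test_that("simulate_chromosome bundles matrix, labels and truth consistently", {
  sim <- small_sim()
  expect_equal(sim$matrix$n_bins, 120)
  expect_length(sim$labels, 120)
  expect_identical(sim$labels, labels_from_copy_number(sim$copy_number))
  expect_identical(copy_number_profile(sim$segments), sim$copy_number)
  ## RNG state of the session is untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_chromosome(n_bins = 50, n_segments = 2, min_len = 3,
                                max_len = 5, seed = 1))
  expect_identical(before, .Random.seed)
})
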