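test_that("bin splits are disjoint, exhaustive and seed-stable", {
  s <- split_bins(100, 0.6, seed = 5)
  expect_length(s$train, 60)
  expect_length(s$test, 40)
  expect_setequal(c(s$train, s$test), 1:100)
  expect_identical(split_bins(100, 0.6, seed = 5), s)
  expect_false(identical(split_bins(100, 0.6, seed = 6)$train, s$train))
})

test_that("softmax rows are probabilities and argmax breaks ties low", {
  z <- matrix(c(1, 2, 0, -1, 3, 3, 3, 3), 2, byrow = TRUE)
  p <- softmax_rows(z)
  expect_equal(rowSums(p), c(1, 1))
  expect_equal(p[2, ], rep(0.25, 4))
  expect_equal(argmax_rows(p), c(2L, 1L))
  ## extreme logits do not overflow
  expect_equal(rowSums(softmax_rows(matrix(c(1000, 0, 0, 0), 1))), 1)
})

test_that("one-hot encoding puts a single 1 in the label column", {
  y <- cnv_labels(c(0, 2, 3, 1))
  Y <- one_hot(y)
  expect_equal(dim(Y), c(4L, 4L))
  expect_equal(rowSums(Y), rep(1, 4))
  expect_equal(which(Y[1, ] == 1), 1L)
  expect_equal(which(Y[3, ] == 1), 4L)
})

test_that("the multinomial fit matches nnet::multinom on shared data", {
  sim <- small_sim()
  X <- log1p(sim$matrix$values)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  fit <- fit_multinomial_gd(Xs, one_hot(sim$labels), epochs = 500, lr = 0.1,
                            seed = 1, l2 = 0.1)
  P <- softmax_rows(Xs %*% fit$W + matrix(fit$b, nrow(Xs), 4, byrow = TRUE))
  ours <- mean(argmax_rows(P) == label_codes(sim$labels) + 1L)
  ## the 120-bin fixture has an empty class, which multinom warns about and
  ## drops from its factor levels -- compare as character
  ref <- suppressWarnings(
    nnet::multinom(y ~ ., data.frame(y = sim$labels, as.data.frame(Xs)),
                   trace = FALSE, MaxNWts = 5000))
  theirs <- mean(as.character(predict(ref)) == as.character(sim$labels))
  ## same training data: in-sample accuracies agree closely
  expect_gt(ours, theirs - 0.05)
  ## loss decreases monotonically-ish: final well below initial
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1] * 0.5)
})

test_that("fit_linear_cnv returns a working classed model", {
  sim <- small_sim()
  fit <- fit_linear_cnv(sim$matrix, sim$labels, seed = 2)
  expect_s3_class(fit, "linear_cnv")
  expect_equal(fit$transform, "log1p")
  expect_output(print(fit), "linear_cnv")
  expect_equal(dim(coef(fit)), c(121L, 4L))  # bias row + one row per bin
  pr <- predict(fit, sim$matrix)
  expect_equal(rowSums(pr$prob), rep(1, 120), tolerance = 1e-12)
  expect_s3_class(pr$labels, "factor")
  ## the reported metrics correspond to the stored test split
  direct <- compute_metrics(sim$labels[fit$split$test],
                            pr$prob[fit$split$test, ])
  expect_equal(fit$metrics$accuracy, direct$accuracy)
  ## determinism
  expect_equal(fit_linear_cnv(sim$matrix, sim$labels, seed = 2)$metrics,
               fit$metrics)
})

test_that("a single-class training split is rejected", {
  sim <- small_sim()
  one_class <- cnv_labels(rep(1L, 120))
  expect_error(fit_linear_cnv(sim$matrix, one_class, seed = 1),
               "single CNV class")
})

test_that("linear models round-trip through JSON with identical predictions", {
  sim <- small_sim()
  fit <- fit_linear_cnv(sim$matrix, sim$labels, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_linear_model(fit, path)
  back <- read_linear_model(path)
  p1 <- predict(fit, sim$matrix)
  p2 <- predict(back, sim$matrix)
  expect_equal(p2$prob, p1$prob, tolerance = 1e-12)
  expect_identical(p2$labels, p1$labels)
})

test_that("the shared model pools splits and reports per-chromosome metrics", {
  simA <- small_sim()
  simB <- fixture("small_sim_b", function() {
    simulate_chromosome(n_bins = 120, n_segments = 4, min_len = 8,
                        max_len = 15, seed = 9, noise_model = "poisson")
  })
  sh <- fit_shared_linear(list(
    A = list(features = log1p(simA$matrix$values), labels = simA$labels),
    B = list(features = log1p(simB$matrix$values), labels = simB$labels)),
    seed = 1)
  expect_s3_class(sh, "shared_linear_cnv")
  expect_length(sh$per_chrom, 2)
  expect_s3_class(sh$metrics, "metrics_report")
  ## pooled test size = sum of the per-chromosome test splits
  expect_equal(sh$metrics$n_test, sum(vapply(sh$per_chrom, `[[`, 0, "n_test")))
  ## mixed feature dimensions are rejected up front
  expect_error(fit_shared_linear(list(
    A = list(features = matrix(1, 20, 5), labels = cnv_labels(rep(0:3, 5))),
    B = list(features = matrix(1, 20, 6), labels = cnv_labels(rep(0:3, 5))))),
    "mixed feature dimensions")
})
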