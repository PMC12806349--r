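test_that("the propagation operator is the symmetric-normalized adjacency", {
  g <- toy_graph()
  A <- normalize_adjacency(g)
  expect_true(isSymmetric(A))
  ## manual oracle: D^(-1/2) (W + I) D^(-1/2)
  W <- matrix(0, 5, 5)
  W[cbind(g$edges$u, g$edges$v)] <- g$edges$weight
  W <- W + t(W) + diag(5)
  dinv <- 1 / sqrt(rowSums(W))
  expect_equal(A, diag(dinv) %*% W %*% diag(dinv), tolerance = 1e-12)
  ## an isolated node propagates only itself
  g2 <- build_graph(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3))
  A2 <- normalize_adjacency(g2)
  expect_equal(A2[3, ], c(0, 0, 1))
})

test_that("the forward pass matches a naive loop implementation to 1e-10", {
  ## hand-sized instance: 2 nodes, 3 features, hidden width 2
  g <- build_graph(matrix(c(0, 2, 2, 0), 2))
  prop <- normalize_adjacency(g)
  params <- gcn_init_params(d_in = 3, hidden = 2, seed = 42)
  X <- matrix(c(0.3, -1, 2, 0.5, 1.2, -0.7), 2, 3)
  O <- gcn_forward(params, prop, X)
  ## naive re-implementation with explicit loops over nodes and units
  mm <- function(A, B) {
    C <- matrix(0, nrow(A), ncol(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(B)))
      C[i, j] <- sum(A[i, ] * B[, j])
    C
  }
  H1 <- tanh(mm(prop, mm(X, params$W1)))
  H2 <- tanh(mm(prop, mm(H1, params$W2)))
  H3 <- tanh(mm(prop, mm(H2, params$W3)))
  H4 <- tanh(mm(prop, mm(H1 + H3, params$W4)))
  Z <- mm(H4, params$W5)
  for (i in 1:2) Z[i, ] <- Z[i, ] + params$b5
  expect_lt(max(abs(O - 1 / (1 + exp(-Z)))), 1e-10)
  ## softmax head normalizes the same logits
  Os <- gcn_forward(params, prop, X, head = "softmax")
  expect_equal(unname(rowSums(Os)), c(1, 1), tolerance = 1e-12)
  expect_lt(max(abs(Os - exp(Z) / rowSums(exp(Z)))), 1e-10)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(31)
  n <- 6
  m <- matrix(runif(n * n), n); m <- m + t(m); diag(m) <- 0
  g <- build_graph(m)
  prop <- normalize_adjacency(g)
  X <- matrix(rnorm(n * 4), n, 4)
  Y <- one_hot(cnv_labels(sample(0:3, n, replace = TRUE)))
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  for (head in c("sigmoid", "softmax")) {
    params <- gcn_init_params(d_in = 4, hidden = 3, dropout = 0, seed = 7)
    bk <- gcn_backward(params, prop, X, Y, mask, NULL, head)
    eps <- 1e-6
    for (nm in c("W1", "W2", "W3", "W4", "W5", "b5")) {
      theta <- params[[nm]]
      idx <- if (nm == "b5") 1:2 else cbind(c(1, 2), c(1, 2))
      num <- analytic <- numeric(2)
      for (k in 1:2) {
        pp <- params
        if (nm == "b5") {
          pp[[nm]][idx[k]] <- theta[idx[k]] + eps
          analytic[k] <- bk$grads[[nm]][idx[k]]
        } else {
          pp[[nm]][idx[k, 1], idx[k, 2]] <- theta[idx[k, 1], idx[k, 2]] + eps
          analytic[k] <- bk$grads[[nm]][idx[k, 1], idx[k, 2]]
        }
        up <- gcn_backward(pp, prop, X, Y, mask, NULL, head)$loss
        if (nm == "b5") pp[[nm]][idx[k]] <- theta[idx[k]] - eps
        else pp[[nm]][idx[k, 1], idx[k, 2]] <- theta[idx[k, 1], idx[k, 2]] - eps
        dn <- gcn_backward(pp, prop, X, Y, mask, NULL, head)$loss
        num[k] <- (up - dn) / (2 * eps)
      }
      expect_equal(analytic, num, tolerance = 1e-5,
                   label = paste("grad", nm, head))
    }
  }
})

test_that("GCN training is reproducible and its metrics match the split", {
  sim <- small_sim()
  emb <- fixture("small_emb", function() {
    node2vec_embed(small_sim()$matrix, d = 16, walk_length = 30,
                   num_walks = 5, epochs = 2, seed = 2)
  })
  fit <- train_gcn(emb$graph, emb$embedding, sim$labels, hidden = 16,
                   epochs = 60, seed = 4)
  expect_s3_class(fit, "gcn_cnv")
  expect_output(print(fit), "gcn_cnv")
  fit2 <- train_gcn(emb$graph, emb$embedding, sim$labels, hidden = 16,
                    epochs = 60, seed = 4)
  expect_identical(fit$metrics$accuracy, fit2$metrics$accuracy)
  expect_identical(fit$loss, fit2$loss)
  ## held-out metrics recomputable from the stored probabilities
  direct <- compute_metrics(sim$labels[fit$split$test],
                            fit$prob[fit$split$test, ])
  expect_equal(fit$metrics$accuracy, direct$accuracy)
  ## training loss decreases substantially
  expect_lt(mean(tail(fit$loss, 5)), mean(head(fit$loss, 5)) * 0.8)
  ## predict replays the stored forward pass
  pr <- predict(fit, features = emb$embedding)
  expect_equal(unname(pr$prob), unname(fit$prob))
  expect_error(train_gcn(emb$graph, emb$embedding, cnv_labels(rep(2, 120))),
               "single CNV class")
})

test_that("fine-tuning uses only the labeled fraction and reports zero-shot", {
  sim <- small_sim()
  emb <- fixture("small_emb", function() {
    node2vec_embed(small_sim()$matrix, d = 16, walk_length = 30,
                   num_walks = 5, epochs = 2, seed = 2)
  })
  fit <- train_gcn(emb$graph, emb$embedding, sim$labels, hidden = 16,
                   epochs = 60, seed = 4)
  tr <- fine_tune(fit, emb$graph, emb$embedding, sim$labels,
                  label_fraction = 0.1, epochs = 5, seed = 8)
  expect_s3_class(tr, "gcn_transfer")
  expect_length(tr$tuned_on, round(120 * 0.1))
  expect_length(tr$loss, 5)
  ## evaluation never includes the tuned-on nodes
  expect_equal(tr$metrics$n_test, 120 - length(tr$tuned_on))
  expect_equal(tr$zero_shot$n_test, tr$metrics$n_test)
  expect_output(print(tr), "zero-shot")
  expect_error(fine_tune(fit, emb$graph, emb$embedding, sim$labels,
                         label_fraction = 0), "label_fraction")
})
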