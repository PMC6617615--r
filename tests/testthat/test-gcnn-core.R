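test_that("convolution handles forced small cases", {
  # isolated atom, identity self-weight: no neighbours, ReLU passes it through
  g1 <- mol_graph("iso", "C")
  f1 <- matrix(c(1, 0), 1, 2)
  w_id <- conv_stage_weights(diag(2), matrix(0, 2, 2))
  expect_equal(unname(convolve(f1, g1, w_id)[1, ]), c(1, 0),
               ignore_attr = TRUE)

  # two bonded atoms, scalar weights 1: each row becomes self + neighbour
  g2 <- mol_graph("pair", c("C", "C"), rbind(c(1, 2)))
  f2 <- matrix(c(1, 2), 2, 1)
  w1 <- conv_stage_weights(matrix(1), matrix(1))
  expect_equal(as.numeric(convolve(f2, g2, w1)), c(3, 3))

  # negated identity on non-negative input: ReLU clamps everything to zero
  w_neg <- conv_stage_weights(-diag(2), -diag(2))
  g3 <- mol_graph("tri", c("C", "C", "C"), rbind(c(1, 2), c(2, 3)))
  f3 <- matrix(abs(rnorm(6)), 3, 2)
  expect_true(all(convolve(f3, g3, w_neg) == 0))
})

test_that("convolution increments the layer index and stays non-negative", {
  set.seed(31)
  g <- random_test_graph("g", 7)
  f <- one_hot_encode(g, infer_alphabet(list(g)))
  w <- conv_stage_weights(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 3, 4),
                          rnorm(3))
  out <- convolve(f, g, w)
  expect_equal(attr(out, "layer_index"), 1L)
  expect_true(all(out >= 0))
  expect_error(convolve(f[, 1:2], g, w), class = "mgcnn_dimension_error")
})

test_that("vectorised convolution matches the explicit double-loop oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    g <- random_test_graph(paste0("r", rep), n)
    d_in <- sample(2:5, 1)
    d_out <- sample(2:5, 1)
    f <- matrix(rnorm(n * d_in), n, d_in)
    w <- conv_stage_weights(matrix(rnorm(d_out * d_in), d_out, d_in),
                            matrix(rnorm(d_out * d_in), d_out, d_in),
                            rnorm(d_out))
    expect_lt(max(abs(convolve(f, g, w) - oracle_convolve(f, g, w))), 1e-10)
  }
})

test_that("max pooling takes neighbourhood maxima including the vertex", {
  path <- mol_graph("p", c("C", "C", "C"), rbind(c(1, 2), c(2, 3)))
  f <- matrix(c(1, 5, 2), 3, 1)
  expect_equal(as.numeric(max_pool(f, path)), c(5, 5, 5))

  # idempotent on constants
  fc <- matrix(3, 3, 2)
  expect_equal(unname(max_pool(fc, path)), fc, ignore_attr = TRUE)

  # isolated atom keeps its own row
  iso <- mol_graph("i", "O")
  expect_equal(as.numeric(max_pool(matrix(c(-2, 4), 1, 2), iso)), c(-2, 4))
})

test_that("batched pooling agrees with the per-molecule operator", {
  set.seed(77)
  graphs <- lapply(1:6, function(i) random_test_graph(paste0("m", i),
                                                      sample(2:9, 1)))
  ab <- infer_alphabet(graphs)
  batch <- mgcnn:::build_batch(graphs, ab)
  h <- matrix(rnorm(batch$n_total * 3), batch$n_total, 3)
  pooled <- mgcnn:::pool_forward(h, batch$pool_idx)$p
  off <- 0L
  for (g in graphs) {
    n <- length(g$atoms)
    expect_equal(unname(pooled[off + seq_len(n), , drop = FALSE]),
                 unname(max_pool(h[off + seq_len(n), , drop = FALSE], g)),
                 ignore_attr = TRUE)
    off <- off + n
  }
})

test_that("gather sums atom rows and is permutation-invariant", {
  f <- rbind(c(1, 2), c(3, 4))
  expect_equal(gather_molecule(f), c(4, 6))
  expect_equal(gather_molecule(matrix(c(7, 8), 1, 2)), c(7, 8))
  set.seed(5)
  fr <- matrix(rnorm(30), 10, 3)
  expect_equal(gather_molecule(fr), gather_molecule(fr[sample(10), ]))
})

test_that("paired softmax heads score categories independently", {
  head <- classifier_head(matrix(0, 4, 3), categories = c("a", "b"))
  p <- classify(c(1, 2, 3), head)
  expect_equal(p$y_pos, c(0.5, 0.5))
  expect_equal(p$y_pos + p$y_neg, c(1, 1))

  # widening the negative logit drives y_neg to 1
  h2 <- classifier_head(rbind(c(0, 0), c(50, 0), c(0, 0), c(0, 0)),
                        categories = c("a", "b"))
  p2 <- classify(c(1, 0), h2)
  expect_gt(p2$y_neg[1], 1 - 1e-9)

  set.seed(9)
  h3 <- classifier_head(matrix(rnorm(10 * 4), 10, 4),
                        categories = paste0("k", 1:5))
  p3 <- classify(rnorm(4), h3)
  expect_equal(p3$y_pos + p3$y_neg, rep(1, 5), tolerance = 1e-12)
})

test_that("summed cross-entropy matches closed forms and the scalar oracle", {
  # uniform prediction over K categories: K * ln 2
  k <- 15L
  head <- classifier_head(matrix(0, 2 * k, 4), categories = paste0("k", 1:k))
  unif <- classify(rep(0, 4), head)
  expect_equal(cross_entropy_loss(unif, rep(1, k)), k * log(2),
               tolerance = 1e-9)
  expect_equal(cross_entropy_loss(unif, rep(0, k)), k * log(2),
               tolerance = 1e-9)

  # confident correct prediction: loss ~ 0
  conf <- data.frame(category = c("a", "b"),
                     y_pos = c(1 - 1e-12, 1e-12),
                     y_neg = c(1e-12, 1 - 1e-12))
  expect_lt(cross_entropy_loss(conf, c(1, 0)), 1e-6)

  # random pairs against the per-category accumulation oracle
  set.seed(55)
  for (rep in 1:20) {
    kk <- sample(2:8, 1)
    lg <- matrix(rnorm(2 * kk), 1)
    pr <- mgcnn:::softmax_pairs(lg)
    pred <- data.frame(category = paste0("k", 1:kk),
                       y_pos = pr[1, seq(1, 2 * kk, 2)],
                       y_neg = pr[1, seq(2, 2 * kk, 2)])
    lab <- rbinom(kk, 1, 0.5)
    expect_equal(cross_entropy_loss(pred, lab),
                 oracle_loss(pred$y_pos, pred$y_neg, lab),
                 tolerance = 1e-12)
  }

  expect_gte(cross_entropy_loss(unif, rbinom(k, 1, 0.5)), 0)
})

test_that("forward pass is invariant under vertex relabelling", {
  set.seed(17)
  for (rep in 1:10) {
    g <- random_test_graph(paste0("perm", rep), sample(4:12, 1))
    model <- mgcnn_model(infer_alphabet(list(g)), c("a", "b"),
                         n_stages = 3, stage_dims = c(8, 8, 8), seed = rep)
    base <- forward(g, model)
    for (j in 1:3) {
      perm <- sample(length(g$atoms))
      gp <- permute_graph(g, perm)
      expect_equal(forward(gp, model)$y_pos, base$y_pos, tolerance = 1e-9)
    }
  }
})

test_that("forward with untrained weights yields finite paired probabilities", {
  set.seed(3)
  g <- random_test_graph("f", 10)
  model <- mgcnn_model(infer_alphabet(list(g)), paste0("k", 1:4), seed = 2)
  p <- forward(g, model)
  expect_true(all(is.finite(p$y_pos)))
  expect_equal(p$y_pos + p$y_neg, rep(1, 4), tolerance = 1e-9)
})

test_that("features after s stages depend only on the radius-s neighbourhood", {
  # long path; perturbing a distant atom's input cannot reach atom 1
  n <- 12L
  g <- mol_graph("path", rep("C", n), cbind(1:(n - 1), 2:n))
  ab <- atom_alphabet(c("C", "N"))
  set.seed(23)
  stages <- lapply(1:2, function(s) {
    conv_stage_weights(matrix(rnorm(4), 2, 2), matrix(rnorm(4), 2, 2),
                       rnorm(2))
  })
  run_stages <- function(f) {
    for (w in stages) {
      f <- convolve(f, g, w)
      f <- max_pool(f, g)
    }
    f
  }
  f0 <- one_hot_encode(g, ab)
  base <- run_stages(f0)
  f_pert <- f0
  f_pert[n, ] <- c(0, 1)   # flip the far end of the path
  pert <- run_stages(f_pert)
  # 2 stages of conv+pool reach at most graph distance 4
  reach <- 4L
  expect_equal(base[seq_len(n - reach - 1L), ], pert[seq_len(n - reach - 1L), ],
               ignore_attr = TRUE)
  # and the perturbed end itself must differ (sanity of the probe)
  expect_false(isTRUE(all.equal(base[n, ], pert[n, ])))
})
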