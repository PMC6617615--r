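make_tiny_task <- function(n = 24, seed = 13) {
  generate_molecules(n, seed = seed,
                     rules = list(rule_contains("N"), rule_contains("O")))
}

test_that("zero learning rate leaves weights untouched and the loss flat", {
  ds <- make_tiny_task()
  cfg <- training_config(epochs = 5, learning_rate = 0, seed = 4,
                         dropout_input = 0, dropout_after_pool = 0,
                         n_stages = 2, stage_dims = c(8, 8))
  fit <- train_mgcnn(ds$graphs, ds$labels, cfg)
  init <- mgcnn_model(infer_alphabet(ds$graphs), colnames(ds$labels),
                      n_stages = 2, stage_dims = c(8, 8), seed = 4)
  expect_identical(fit$checkpoint$model$stages[[1]]$w_self,
                   init$stages[[1]]$w_self)
  expect_identical(fit$checkpoint$model$head$weights, init$head$weights)
  expect_equal(length(unique(fit$loss_curve)), 1L)
})

test_that("training is bitwise reproducible for a fixed seed", {
  ds <- make_tiny_task()
  cfg <- training_config(epochs = 8, seed = 99, n_stages = 2,
                         stage_dims = c(8, 8))
  f1 <- train_mgcnn(ds$graphs, ds$labels, cfg)
  f2 <- train_mgcnn(ds$graphs, ds$labels, cfg)
  expect_identical(f1$loss_curve, f2$loss_curve)
  expect_identical(f1$checkpoint$model$stages, f2$checkpoint$model$stages)
  f3 <- train_mgcnn(ds$graphs, ds$labels,
                    training_config(epochs = 8, seed = 100, n_stages = 2,
                                    stage_dims = c(8, 8)))
  expect_false(identical(f1$loss_curve, f3$loss_curve))
})

test_that("training descends on a separable element-presence task", {
  ds <- generate_molecules(80, seed = 21, rules = list(rule_contains("N")))
  cfg <- training_config(epochs = 40, seed = 8, n_stages = 2,
                         stage_dims = c(32, 32))
  fit <- train_mgcnn(ds$graphs, ds$labels, cfg)
  expect_lt(fit$loss_curve[length(fit$loss_curve)], fit$loss_curve[1])
})

test_that("the model can memorise a 10-molecule task to near-zero loss", {
  ds <- make_tiny_task(n = 10, seed = 3)
  cfg <- training_config(epochs = 400, seed = 5,
                         dropout_input = 0, dropout_after_pool = 0,
                         n_stages = 2, stage_dims = c(32, 32))
  fit <- train_mgcnn(ds$graphs, ds$labels, cfg)
  expect_lt(min(fit$loss_curve), 0.01)
})

test_that("inverted dropout zeroes the stated fraction and rescales survivors", {
  f <- matrix(1, 100, 100)
  expect_identical(apply_dropout(f, 0), f)
  expect_identical(apply_dropout(f, 0.5, training = FALSE), f)
  set.seed(42)
  out <- apply_dropout(f, 0.8)
  frac <- mean(out == 0)
  expect_lt(abs(frac - 0.8), 0.02)
  expect_equal(unique(out[out != 0]), 1 / 0.2, tolerance = 1e-12)
  expect_error(apply_dropout(f, 1), class = "mgcnn_format_error")
})

test_that("analytic gradients match central finite differences", {
  g <- mol_graph("t", c("N", "C", "O"), rbind(c(1, 2), c(2, 3)))
  lab <- label_matrix("t", c("k1", "k2"), matrix(c(1L, 0L), 1, 2))
  model <- mgcnn_model(atom_alphabet(c("C", "N", "O")), c("k1", "k2"),
                       n_stages = 2, stage_dims = c(2, 2), seed = 5)
  res <- gradient_check(model, list(g), lab)
  expect_lt(res$max_rel_err, 1e-4)
})

test_that("a trained checkpoint round-trips through JSON bit-identically", {
  ds <- make_tiny_task(n = 12, seed = 6)
  cfg <- training_config(epochs = 4, seed = 2, n_stages = 2,
                         stage_dims = c(6, 6))
  fit <- train_mgcnn(ds$graphs, ds$labels, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(fit, f)
  back <- read_checkpoint(f)
  expect_identical(back$model$stages, fit$checkpoint$model$stages)
  expect_identical(back$model$head$weights, fit$checkpoint$model$head$weights)
  p1 <- predict(fit$checkpoint, ds$graphs)
  p2 <- predict(back, ds$graphs)
  expect_identical(p1$probabilities, p2$probabilities)
})

test_that("prediction thresholds at y_pos > 0.5 and ignores input order", {
  ds <- make_tiny_task(n = 15, seed = 9)
  cfg <- training_config(epochs = 10, seed = 3, n_stages = 2,
                         stage_dims = c(8, 8))
  fit <- train_mgcnn(ds$graphs, ds$labels, cfg)
  pred <- predict(fit, ds$graphs)
  expect_identical(unname(unclass(pred$calls)),
                   unname((as.matrix(pred$probabilities[, -1]) > 0.5) * 1L))
  shuf <- sample(length(ds$graphs))
  pred2 <- predict(fit, ds$graphs[shuf])
  ord <- match(pred$probabilities$compound_id, pred2$probabilities$compound_id)
  expect_equal(unname(as.matrix(pred2$probabilities[ord, -1])),
               unname(as.matrix(pred$probabilities[, -1])))
})

test_that("an all-zero head makes every pair (0.5, 0.5) and no positive calls", {
  ds <- make_tiny_task(n = 8, seed = 10)
  model <- mgcnn_model(infer_alphabet(ds$graphs), colnames(ds$labels),
                       n_stages = 2, stage_dims = c(8, 8), seed = 1)
  ckpt <- structure(list(version = 1L, model = model,
                         config = training_config(n_stages = 2,
                                                  stage_dims = c(8, 8))),
                    class = "mgcnn_checkpoint")
  pred <- predict(ckpt, ds$graphs)
  expect_true(all(as.matrix(pred$probabilities[, -1]) == 0.5))
  expect_true(all(unclass(pred$calls) == 0L))
})

test_that("molecules with atoms outside the alphabet are skipped with a warning", {
  graphs <- list(
    mol_graph("amine", c("N", "C", "H"), rbind(c(1, 2), c(2, 3))),
    mol_graph("ether", c("C", "O", "C"), rbind(c(1, 2), c(2, 3))),
    mol_graph("chain", c("C", "C", "O"), rbind(c(1, 2), c(2, 3)))
  )
  labels <- label_matrix(c("amine", "ether", "chain"), "has_N",
                         matrix(c(1L, 0L, 0L), 3, 1))
  cfg <- training_config(epochs = 3, seed = 1, n_stages = 2,
                         stage_dims = c(4, 4))
  fit <- train_mgcnn(graphs, labels, cfg)
  alien <- mol_graph("alien", c("P", "C"), rbind(c(1, 2)))
  expect_warning(pred <- predict(fit, c(graphs[1:2], list(alien))),
                 "outside the alphabet")
  expect_equal(pred$skipped, "alien")
  expect_equal(nrow(pred$probabilities), 2L)
})

test_that("per-molecule loss is independent of batching", {
  ds <- make_tiny_task(n = 20, seed = 14)
  base <- training_config(epochs = 1, learning_rate = 0, seed = 7,
                          dropout_input = 0, dropout_after_pool = 0,
                          n_stages = 2, stage_dims = c(8, 8))
  small <- base; small$batch_size <- 4L
  big <- base; big$batch_size <- 20L
  f_small <- train_mgcnn(ds$graphs, ds$labels, small)
  f_big <- train_mgcnn(ds$graphs, ds$labels, big)
  expect_equal(f_small$loss_curve, f_big$loss_curve, tolerance = 1e-12)
})
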