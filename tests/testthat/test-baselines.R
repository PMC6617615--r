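test_that("ECFP fingerprints are 1024 binary bits and deterministic", {
  fp <- ecfp_fingerprints(c(ethanol = "CCO", phenol = "c1ccccc1O",
                            ethanol2 = "CCO"))
  expect_equal(ncol(fp), 1024L)
  expect_true(all(fp %in% c(0, 1)))
  # identical molecules give identical fingerprints
  expect_equal(unname(fp[1, ]), unname(fp[3, ]))
  expect_false(identical(unname(fp[1, ]), unname(fp[2, ])))
  # Tanimoto similarity of a nonzero fingerprint with itself is 1
  a <- fp[1, ]
  expect_gt(sum(a), 0)
  expect_equal(sum(a & a) / sum(a | a), 1)
})

test_that("feature selection keeps one representative per correlated block", {
  set.seed(60)
  n <- 50
  v1 <- rnorm(n)
  d <- descriptor_matrix(
    sprintf("c%02d", 1:n), c("v1", "v2", "v3"),
    cbind(v1, v1 + rnorm(n, sd = 0.01), rnorm(n))
  )
  sel <- select_features(d, r_threshold = 0.6, seed = 1)
  expect_equal(sel$n_components, 2L)
  expect_length(sel$kept_variable_names, 2L)
  expect_true("v3" %in% sel$kept_variable_names)
  expect_true(any(c("v1", "v2") %in% sel$kept_variable_names))
})

test_that("constant variables are removed as non-informative, never clustered", {
  set.seed(61)
  d <- descriptor_matrix(
    sprintf("c%02d", 1:30), c("const", "a", "b"),
    cbind(rep(2, 30), rnorm(30), rnorm(30))
  )
  sel <- select_features(d)
  expect_equal(sel$removed_noninformative, "const")
  expect_false("const" %in% names(sel$component_assignment))
  expect_false("const" %in% sel$kept_variable_names)
})

test_that("independent variables all survive a near-1 threshold", {
  set.seed(62)
  d <- descriptor_matrix(sprintf("c%03d", 1:200), paste0("v", 1:10),
                         matrix(rnorm(2000), 200, 10))
  cm <- abs(stats::cor(unclass(d)))
  diag(cm) <- 0
  expect_lt(max(cm), 0.999)   # the simulation premise
  sel <- select_features(d, r_threshold = 0.999)
  expect_equal(sel$n_components, 10L)
  expect_setequal(sel$kept_variable_names, paste0("v", 1:10))
})

test_that("component structure matches a union-find oracle on random designs", {
  set.seed(63)
  for (rep in 1:5) {
    p <- 12
    n <- 80
    base <- matrix(rnorm(n * 4), n, 4)
    # variables 1..8 are noisy clones of 4 latents, 9..12 independent
    x <- cbind(base[, rep(1:4, each = 2)] + rnorm(n * 8, sd = 0.05),
               matrix(rnorm(n * 4), n, 4))
    d <- descriptor_matrix(sprintf("c%03d", 1:n), paste0("v", 1:p), x)
    sel <- select_features(d, r_threshold = 0.6, seed = rep)

    cm <- abs(stats::cor(x))
    edges <- which(upper.tri(cm) & cm > 0.6, arr.ind = TRUE)
    oracle <- oracle_components(p, edges)
    # same partition up to component relabelling
    expect_equal(max(oracle), sel$n_components)
    pkg <- sel$component_assignment[paste0("v", 1:p)]
    expect_true(all(outer(pkg, pkg, "==") == outer(oracle, oracle, "==")))
  }
})

test_that("component assignment is invariant to variable ordering", {
  set.seed(64)
  n <- 60
  base <- rnorm(n)
  x <- cbind(a = base + rnorm(n, sd = 0.01), b = rnorm(n),
             c = base + rnorm(n, sd = 0.01), d = rnorm(n))
  d1 <- descriptor_matrix(sprintf("c%02d", 1:n), colnames(x), x)
  perm <- c(3, 1, 4, 2)
  d2 <- descriptor_matrix(sprintf("c%02d", 1:n), colnames(x)[perm],
                          x[, perm])
  s1 <- select_features(d1, seed = 5)
  s2 <- select_features(d2, seed = 5)
  for (v in colnames(x)) {
    for (w in colnames(x)) {
      expect_equal(s1$component_assignment[[v]] == s1$component_assignment[[w]],
                   s2$component_assignment[[v]] == s2$component_assignment[[w]])
    }
  }
})

test_that("a leaked label column gives perfect baseline accuracy", {
  set.seed(65)
  n <- 60
  y <- rbinom(n, 1, 0.5)
  feats <- descriptor_matrix(sprintf("c%02d", 1:n),
                             c("leak", "noise1", "noise2"),
                             cbind(y, rnorm(n), rnorm(n)))
  labels <- label_matrix(sprintf("c%02d", 1:n), "target",
                         matrix(y, ncol = 1))
  for (lrn in c("rf", "svm")) {
    rep <- run_baseline(feats, labels, learner = lrn, seed = 3)
    expect_equal(unname(rep$per_category_accuracy["target"]), 1)
  }
})

test_that("label-shuffled features score near chance", {
  set.seed(66)
  n <- 200
  feats <- descriptor_matrix(sprintf("c%03d", 1:n), paste0("v", 1:5),
                             matrix(rnorm(n * 5), n, 5))
  y <- rep(c(0L, 1L), each = n / 2)   # balanced, independent of features
  labels <- label_matrix(sprintf("c%03d", 1:n), "null", matrix(y, ncol = 1))
  rep <- run_baseline(feats, labels, learner = "rf", seed = 4)
  se <- sqrt(0.25 / n)
  expect_lt(abs(rep$per_category_accuracy[["null"]] - 0.5), 3 * se + 0.05)
})

test_that("baseline reports share the cv_report contract with the network", {
  set.seed(67)
  ds <- generate_molecules(20, seed = 70,
                           rules = list(rule_contains("N"), rule_contains("O")))
  feats <- descriptor_matrix(
    rownames(ds$labels), c("f1", "f2"),
    cbind(vapply(ds$graphs, function(g) sum(g$atoms == "N"), numeric(1)),
          vapply(ds$graphs, function(g) sum(g$atoms == "O"), numeric(1)))
  )
  rep <- run_baseline(feats, ds$labels, learner = "nn", seed = 5)
  net <- cross_validate(ds$graphs, ds$labels,
                        training_config(epochs = 2, seed = 1, n_stages = 2,
                                        stage_dims = c(4, 4)))
  expect_s3_class(rep, "cv_report")
  expect_setequal(names(rep)[names(rep) %in% names(net)],
                  names(net)[names(net) %in% names(rep)])
  for (nm in c("scheme", "per_category_accuracy", "global_average",
               "confusion", "n_samples", "calls", "truth")) {
    expect_true(nm %in% names(rep))
    expect_true(nm %in% names(net))
  }
  expect_equal(names(rep$per_category_accuracy), colnames(ds$labels))
})
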