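# Fingerprint/descriptor baselines and the correlation-network feature
# selection procedure used to compare the graph network against classical
# learners on fixed molecular representations.

#' 1024-bit ECFP fingerprints (diameter 2)
#'
#' Extended-connectivity fingerprints computed by OpenBabel (ECFP2 =
#' diameter 2) and folded from the toolkit's native 4096 bits down to 1024
#' by OR-ing congruent positions -- the standard treatment of hashed
#' circular fingerprints.
#'
#' @param structures Either a character vector of SMILES strings (names
#'   become compound ids) or a `ChemmineR::SDFset`.
#' @return A [descriptor_matrix()] with 1024 binary columns `ecfp_0001` ...
#'   `ecfp_1024`.
#' @examples
#' \dontrun{
#' fp <- ecfp_fingerprints(c(ethanol = "CCO", phenol = "c1ccccc1O"))
#' }
#' @export
ecfp_fingerprints <- function(structures) {
  if (is.character(structures)) {
    ids <- if (!is.null(names(structures))) names(structures) else structures
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(structures))
  } else if (methods::is(structures, "SDFset")) {
    sdf <- structures
    ids <- ChemmineR::sdfid(sdf)
  } else {
    format_error("structures must be SMILES strings or an SDFset")
  }
  raw <- ChemmineR::fingerprintOB(sdf, "ECFP2")@fpma
  fold <- ((seq_len(ncol(raw)) - 1L) %% 1024L) + 1L
  folded <- t(rowsum(t(raw), group = fold))
  folded <- (folded > 0) * 1L
  colnames(folded) <- sprintf("ecfp_%04d", seq_len(1024L))
  descriptor_matrix(ids, colnames(folded), folded)
}

#' Descriptor matrix container
#'
#' A plain numeric compounds-by-variables matrix for fingerprint bits
#' and/or continuous descriptors, as consumed by [select_features()] and
#' [run_baseline()].  Pre-computed descriptor tables (e.g. from an external
#' descriptor generator) are read with [read_descriptor_csv()].
#'
#' @param compound_ids Character vector of compound ids.
#' @param variable_names Unique variable names.
#' @param values Numeric matrix, `length(compound_ids)` rows.
#' @return Object of class `descriptor_matrix` (a numeric matrix with
#'   dimnames).
#' @export
descriptor_matrix <- function(compound_ids, variable_names, values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(compound_ids) ||
      ncol(values) != length(variable_names)) {
    format_error("descriptor matrix shape does not match ids/variable names")
  }
  if (anyDuplicated(variable_names)) format_error("variable names must be unique")
  if (anyNA(values)) format_error("descriptor matrix contains missing values")
  dimnames(values) <- list(as.character(compound_ids),
                           as.character(variable_names))
  structure(values, class = c("descriptor_matrix", "matrix", "array"))
}

#' @rdname descriptor_matrix
#' @param path CSV/TSV file whose first column is the compound id and
#'   remaining columns are numeric variables.
#' @export
read_descriptor_csv <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  descriptor_matrix(df[[1L]], colnames(df)[-1L],
                    as.matrix(df[, -1L, drop = FALSE]))
}

#' Correlation-network feature selection
#'
#' Reduces a redundant descriptor set in four steps: (1) drop
#' non-informative variables whose values are identical for all samples;
#' (2) compute the Pearson correlation matrix of the remainder; (3) link
#' two variables when their correlation exceeds `r_threshold` (strictly;
#' by default on the absolute value, since strongly anti-correlated
#' variables carry the same information); (4) keep exactly one
#' seeded-random representative from each connected component of that
#' correlation network (singletons keep themselves).
#'
#' @param d A [descriptor_matrix()] with at least 3 samples.
#' @param r_threshold Correlation threshold in (0, 1); default 0.6.
#' @param seed Integer seed for the per-component representative draw.
#' @param absolute Link on `|r|` (default TRUE) rather than signed `r`.
#' @return A `selection_result`: list with `kept_variable_names`,
#'   `removed_noninformative`, `component_assignment` (named integer
#'   vector over informative variables), `n_components`, `r_threshold`,
#'   `seed`.
#' @export
select_features <- function(d, r_threshold = 0.6, seed = 1L, absolute = TRUE) {
  if (nrow(d) < 3L) format_error("need at least 3 samples to correlate")
  if (r_threshold <= 0 || r_threshold >= 1) {
    format_error("r_threshold must lie in (0, 1)")
  }
  vars <- colnames(d)
  constant <- vapply(seq_len(ncol(d)), function(j) {
    all(d[, j] == d[1L, j])
  }, logical(1))
  removed <- vars[constant]
  keep <- vars[!constant]
  if (!length(keep)) format_error("all variables are non-informative")

  cm <- stats::cor(unclass(d)[, keep, drop = FALSE])
  if (absolute) cm <- abs(cm)
  adj <- cm > r_threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  names(comp) <- keep

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  kept <- vapply(seq_len(max(comp)), function(cid) {
    members <- keep[comp == cid]
    if (length(members) == 1L) members else members[sample.int(length(members), 1L)]
  }, character(1))

  structure(
    list(kept_variable_names = kept,
         removed_noninformative = removed,
         component_assignment = comp,
         n_components = max(comp),
         r_threshold = r_threshold, absolute = absolute,
         seed = as.integer(seed)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %d kept of %d informative variables (%d components), %d non-informative removed>\n",
              length(x$kept_variable_names), length(x$component_assignment),
              x$n_components, length(x$removed_noninformative)))
  invisible(x)
}

baseline_grids <- function(learner, p) {
  switch(learner,
    rf = expand.grid(mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 4)))),
                     ntree = 500L),
    nn = expand.grid(size = c(4L, 8L), decay = c(0.01, 0.1)),
    svm = expand.grid(cost = c(1, 10), gamma = unique(c(1 / p, 0.1)))
  )
}

fit_baseline_learner <- function(learner, x, y, par) {
  switch(learner,
    rf = randomForest::randomForest(x = x, y = y, mtry = par$mtry,
                                    ntree = par$ntree),
    nn = nnet::nnet(x = x, y = as.numeric(y == "pos"),
                    size = par$size, decay = par$decay, maxit = 200L,
                    MaxNWts = 50000L, trace = FALSE, entropy = TRUE),
    svm = e1071::svm(x = x, y = y, cost = par$cost, gamma = par$gamma,
                     kernel = "radial")
  )
}

predict_baseline_learner <- function(learner, fit, x) {
  if (learner == "nn") {
    as.integer(stats::predict(fit, x) > 0.5)
  } else {
    as.integer(stats::predict(fit, x) == "pos")
  }
}

#' Fingerprint/descriptor baseline cross-validation
#'
#' Trains one independent binary classifier per category (mirroring the
#' graph network's independent heads) on a fixed descriptor representation,
#' with a small grid search performed inside each training fold (75/25
#' inner split, best setting refit on the full training fold).  Grids:
#' random forest `mtry` in \{sqrt(p), p/4\} at 500 trees; neural network
#' size in \{4, 8\} x decay \{0.01, 0.1\}; radial SVM cost \{1, 10\} x
#' gamma \{1/p, 0.1\}.
#'
#' @param features A [descriptor_matrix()].
#' @param labels A [label_matrix()] over the same compounds.
#' @param learner `"rf"`, `"nn"` or `"svm"`.
#' @param scheme `"CV5"` or `"LOOCV"`.
#' @param seed Integer seed for fold assignment and learner randomness.
#' @return A `cv_report` with the same shape as [cross_validate()]'s, so
#'   graph-network and baseline results compare directly.
#' @export
run_baseline <- function(features, labels, learner = c("rf", "nn", "svm"),
                         scheme = c("CV5", "LOOCV"), seed = 1L) {
  learner <- match.arg(learner)
  scheme <- match.arg(scheme)
  ids <- rownames(features)
  miss <- setdiff(ids, rownames(labels))
  if (length(miss)) {
    format_error(sprintf("no label row for compound(s): %s",
                         paste(utils::head(miss, 5L), collapse = ", ")))
  }
  membership <- unclass(labels)[ids, , drop = FALSE]
  x_all <- unclass(features)
  n <- nrow(x_all)
  categories <- colnames(labels)
  k <- length(categories)
  n_folds <- if (scheme == "CV5") 5L else n
  if (n < n_folds) format_error("dataset smaller than fold count")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  grid <- baseline_grids(learner, ncol(x_all))

  calls <- matrix(NA_integer_, n, k, dimnames = list(ids, categories))
  for (f in seq_len(n_folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    x_tr <- x_all[train_idx, , drop = FALSE]
    x_te <- x_all[test_idx, , drop = FALSE]
    inner <- sample(c(TRUE, FALSE), length(train_idx), replace = TRUE,
                    prob = c(0.75, 0.25))
    for (j in seq_len(k)) {
      y_tr <- membership[train_idx, j]
      if (length(unique(y_tr)) < 2L) {
        warning(sprintf("category '%s': single class in training fold %d; skipped",
                        categories[j], f))
        next
      }
      yf <- factor(ifelse(y_tr == 1L, "pos", "neg"), levels = c("neg", "pos"))
      best <- 1L
      if (nrow(grid) > 1L && length(unique(y_tr[inner])) == 2L &&
          length(unique(y_tr[!inner])) == 2L) {
        val_acc <- vapply(seq_len(nrow(grid)), function(gi) {
          fit <- fit_baseline_learner(learner, x_tr[inner, , drop = FALSE],
                                      yf[inner], grid[gi, , drop = FALSE])
          mean(predict_baseline_learner(learner, fit,
                                        x_tr[!inner, , drop = FALSE]) ==
                 y_tr[!inner])
        }, numeric(1))
        best <- which.max(val_acc)
      }
      fit <- fit_baseline_learner(learner, x_tr, yf, grid[best, , drop = FALSE])
      calls[test_idx, j] <- predict_baseline_learner(learner, fit, x_te)
    }
  }

  acc <- vapply(seq_len(k), function(j) {
    ok <- !is.na(calls[, j])
    if (!any(ok)) return(NA_real_)
    mean(calls[ok, j] == membership[ok, j])
  }, numeric(1))
  names(acc) <- categories
  confusion <- lapply(seq_len(k), function(j) {
    ok <- !is.na(calls[, j])
    tab <- matrix(0L, 2L, 2L,
                  dimnames = list(truth = c("pos", "neg"),
                                  call = c("pos", "neg")))
    tab["pos", "pos"] <- sum(membership[ok, j] == 1L & calls[ok, j] == 1L)
    tab["pos", "neg"] <- sum(membership[ok, j] == 1L & calls[ok, j] == 0L)
    tab["neg", "pos"] <- sum(membership[ok, j] == 0L & calls[ok, j] == 1L)
    tab["neg", "neg"] <- sum(membership[ok, j] == 0L & calls[ok, j] == 0L)
    tab
  })
  names(confusion) <- categories

  calls_out <- calls
  calls_out[is.na(calls_out)] <- 0L
  structure(
    list(scheme = scheme, per_category_accuracy = acc,
         global_average = mean(acc, na.rm = TRUE),
         per_fold_seeds = rep(as.integer(seed), n_folds),
         confusion = confusion, n_samples = n,
         calls = label_matrix(make.unique(ids), categories, calls_out),
         truth = label_matrix(make.unique(ids), categories, membership),
         learner = learner, seed = as.integer(seed)),
    class = "cv_report"
  )
}
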