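#' Cross-validate an MGCNN on a labelled molecule set
#'
#' Trains one model per fold (each with the full `cfg$epochs` budget) and
#' scores every sample exactly once as held-out data.  Fold assignment is
#' seeded random without stratification; when the input contains duplicate
#' compound ids (the same compound contributing several samples), the set
#' is deduplicated to one sample per (compound, label row) by default and
#' folds are always assigned per compound, so no compound ever appears on
#' both sides of a split.
#'
#' "Accuracy" for category k is the per-category binary accuracy: the
#' fraction of held-out samples whose thresholded positive call matches the
#' binary label for k.  The global average is the mean of the K
#' per-category accuracies.
#'
#' @param graphs List of [mol_graph()] objects (ids may repeat).
#' @param labels A [label_matrix()] covering every distinct compound id.
#' @param cfg A [training_config()]; `cfg$seed` drives fold assignment and
#'   per-fold training seeds.
#' @param scheme `"CV5"` (five folds) or `"LOOCV"` (one fold per sample).
#' @param keep_duplicates Keep duplicated compound ids as distinct samples
#'   (they still share a fold).
#' @param verbose Report per-fold progress.
#' @return A `cv_report`: list with `scheme`, `per_category_accuracy`,
#'   `global_average`, `per_fold_seeds`, `confusion` (per-category 2x2
#'   counts), `n_samples`, plus the pooled held-out `calls` and `truth`
#'   label matrices for downstream statistics.
#' @export
cross_validate <- function(graphs, labels, cfg = training_config(),
                           scheme = c("CV5", "LOOCV"),
                           keep_duplicates = FALSE, verbose = FALSE) {
  scheme <- match.arg(scheme)
  ids <- vapply(graphs, `[[`, character(1), "compound_id")
  if (!keep_duplicates && anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    graphs <- graphs[keep]
    ids <- ids[keep]
  }
  membership <- align_labels(graphs, labels)
  n <- length(graphs)
  uniq <- unique(ids)
  n_folds <- if (scheme == "CV5") 5L else length(uniq)
  if (length(uniq) < n_folds) {
    format_error(sprintf("%d distinct compounds is fewer than %d folds",
                         length(uniq), n_folds))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  fold_of_compound <- sample(rep(seq_len(n_folds), length.out = length(uniq)))
  names(fold_of_compound) <- uniq
  fold <- fold_of_compound[ids]

  alphabet <- infer_alphabet(graphs)
  categories <- colnames(labels)
  k <- length(categories)
  calls <- matrix(NA_integer_, n, k, dimnames = list(ids, categories))
  fold_seeds <- integer(n_folds)

  for (f in seq_len(n_folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    fold_cfg <- cfg
    fold_cfg$seed <- (cfg$seed + f) %% .Machine$integer.max
    fold_seeds[f] <- fold_cfg$seed
    fit <- train_mgcnn(graphs[train_idx], labels, fold_cfg,
                       alphabet = alphabet)
    pred <- predict(fit$checkpoint, graphs[test_idx])
    # predict() preserves input order, so assign positionally (ids may repeat
    # when keep_duplicates = TRUE)
    calls[test_idx, ] <- unclass(pred$calls)
    if (verbose) {
      message(sprintf("[%s] fold %d/%d: trained on %d, tested on %d",
                      scheme, f, n_folds, length(train_idx), length(test_idx)))
    }
  }

  confusion <- lapply(seq_len(k), function(j) {
    tab <- matrix(0L, 2L, 2L,
                  dimnames = list(truth = c("pos", "neg"),
                                  call = c("pos", "neg")))
    tab["pos", "pos"] <- sum(membership[, j] == 1L & calls[, j] == 1L)
    tab["pos", "neg"] <- sum(membership[, j] == 1L & calls[, j] == 0L)
    tab["neg", "pos"] <- sum(membership[, j] == 0L & calls[, j] == 1L)
    tab["neg", "neg"] <- sum(membership[, j] == 0L & calls[, j] == 0L)
    tab
  })
  names(confusion) <- categories
  acc <- vapply(seq_len(k), function(j) mean(calls[, j] == membership[, j]),
                numeric(1))
  names(acc) <- categories

  structure(
    list(scheme = scheme, per_category_accuracy = acc,
         global_average = mean(acc), per_fold_seeds = fold_seeds,
         confusion = confusion, n_samples = n,
         calls = label_matrix(make.unique(ids), categories, calls),
         truth = label_matrix(make.unique(ids), categories, membership),
         seed = cfg$seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %s over %d samples, global average %.3f>\n",
              x$scheme, x$n_samples, x$global_average))
  for (nm in names(x$per_category_accuracy)) {
    cat(sprintf("  %-24s %.3f\n", nm, x$per_category_accuracy[nm]))
  }
  invisible(x)
}

#' Multilabel count statistics
#'
#' Compares how many categories each compound is assigned to (predicted)
#' with how many it truly belongs to, the diagnostic used to check that a
#' multilabel classifier neither inflates nor truncates label counts:
#' per-compound mean counts on both sides, the Pearson correlation between
#' per-category compound totals, and an ordinary least-squares regression
#' of predicted on original totals with 95% confidence intervals.  With an
#' ideal classifier the relation is the identity (r = 1, slope 1,
#' intercept 0).
#'
#' @param predicted,original [label_matrix()] objects over the same
#'   compounds and categories (order-insensitive).
#' @return A `count_stats` list: `mean_original`, `mean_predicted`,
#'   `correlation_r`, `r_defined` (FALSE when a side has zero variance
#'   across categories, in which case r is NA rather than an error),
#'   `slope`, `intercept`, `slope_ci`, `intercept_ci`,
#'   `per_category_totals`.
#' @export
count_statistics <- function(predicted, original) {
  if (!setequal(rownames(predicted), rownames(original)) ||
      !setequal(colnames(predicted), colnames(original))) {
    format_error("predicted and original must cover identical compounds and categories")
  }
  pred <- unclass(predicted)[rownames(original), colnames(original), drop = FALSE]
  orig <- unclass(original)

  mean_original <- mean(rowSums(orig))
  mean_predicted <- mean(rowSums(pred))
  tot_orig <- colSums(orig)
  tot_pred <- colSums(pred)

  r_defined <- stats::sd(tot_orig) > 0 && stats::sd(tot_pred) > 0
  r <- if (r_defined) stats::cor(tot_orig, tot_pred) else NA_real_

  slope <- intercept <- NA_real_
  slope_ci <- intercept_ci <- c(NA_real_, NA_real_)
  if (r_defined && length(tot_orig) >= 3L) {
    fit <- stats::lm(tot_pred ~ tot_orig)
    cf <- stats::coef(fit)
    intercept <- cf[[1L]]; slope <- cf[[2L]]
    if (stats::sigma(fit) < 1e-10) {
      # zero-residual fit (e.g. predicted == original): degenerate intervals
      intercept_ci <- c(intercept, intercept)
      slope_ci <- c(slope, slope)
    } else {
      ci <- stats::confint(fit, level = 0.95)
      intercept_ci <- unname(ci[1L, ]); slope_ci <- unname(ci[2L, ])
    }
  }

  structure(
    list(mean_original = mean_original, mean_predicted = mean_predicted,
         correlation_r = r, r_defined = r_defined,
         slope = slope, intercept = intercept,
         slope_ci = slope_ci, intercept_ci = intercept_ci,
         per_category_totals = data.frame(category = colnames(orig),
                                          original = tot_orig,
                                          predicted = tot_pred,
                                          row.names = NULL)),
    class = "count_stats"
  )
}

#' @export
print.count_stats <- function(x, ...) {
  cat(sprintf("<count_stats: mean labels %.2f (original) vs %.2f (predicted)>\n",
              x$mean_original, x$mean_predicted))
  if (x$r_defined) {
    cat(sprintf("  per-category totals: r = %.3f, slope %.2f [%.2f, %.2f], intercept %.1f [%.1f, %.1f]\n",
                x$correlation_r, x$slope, x$slope_ci[1L], x$slope_ci[2L],
                x$intercept, x$intercept_ci[1L], x$intercept_ci[2L]))
  } else {
    cat("  correlation undefined (zero variance in per-category totals)\n")
  }
  invisible(x)
}

#' Sweep the number of convolution stages
#'
#' Repeats [cross_validate()] with the stage count varied and everything
#' else fixed, reporting the global average accuracy per depth -- the
#' experiment that shows how much neighbourhood context the task needs.
#' Stage widths are held at the final width of `cfg`.
#'
#' @param graphs,labels,cfg,scheme As in [cross_validate()].
#' @param stage_range Integer vector of stage counts to evaluate.
#' @return Data frame with columns `n_stages` and `global_average`; the
#'   full `cv_report`s are attached as attribute `"reports"`.
#' @export
stage_sweep <- function(graphs, labels, cfg = training_config(),
                        stage_range = 1:6, scheme = "CV5") {
  if (!length(stage_range)) format_error("stage_range must be non-empty")
  width <- cfg$stage_dims[length(cfg$stage_dims)]
  reports <- vector("list", length(stage_range))
  for (i in seq_along(stage_range)) {
    s <- stage_range[i]
    cfg_s <- cfg
    cfg_s$n_stages <- as.integer(s)
    cfg_s$stage_dims <- rep(as.integer(width), s)
    reports[[i]] <- cross_validate(graphs, labels, cfg_s, scheme = scheme)
  }
  out <- data.frame(
    n_stages = as.integer(stage_range),
    global_average = vapply(reports, `[[`, numeric(1), "global_average")
  )
  attr(out, "reports") <- reports
  out
}
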