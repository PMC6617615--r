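# Core MGCNN operators.
#
# One convolution stage maps the atom feature matrix V (atoms x in_dim) to
#   v_i' = ReLU( W0 v_i + sum_{j ~ i} W1 v_j + b ),
# i.e. the neighbourhood sum runs over Adj(i) -- the bonded neighbours of i
# plus i itself -- with a weight matrix indexed by graph distance: W0 for
# d = 0 (the vertex itself) and W1 for d = 1 (bonded neighbours).  Pooling
# then replaces each atom's vector by the elementwise maximum over the same
# neighbourhood.  After the last stage a gather layer sums all atom vectors
# into one molecule vector, and K independent (positive, negative) softmax
# pairs turn it into per-category probabilities.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Weights of one convolution stage
#'
#' @param w_self Matrix (out_dim x in_dim) applied to the vertex itself
#'   (distance 0).
#' @param w_neighbor Matrix of identical shape applied to each bonded
#'   neighbour (distance 1).
#' @param bias Optional length-out_dim bias; `NULL` for the strict
#'   bias-free form of the convolution equation.
#' @return Object of class `conv_stage_weights`.
#' @export
conv_stage_weights <- function(w_self, w_neighbor, bias = NULL) {
  w_self <- as.matrix(w_self)
  w_neighbor <- as.matrix(w_neighbor)
  if (!identical(dim(w_self), dim(w_neighbor))) {
    dimension_error("w_self and w_neighbor must have identical shape")
  }
  if (!all(is.finite(w_self)) || !all(is.finite(w_neighbor))) {
    dimension_error("non-finite convolution weights")
  }
  if (is.null(bias)) bias <- numeric(nrow(w_self))
  if (length(bias) != nrow(w_self)) {
    dimension_error("bias length must equal the stage output width")
  }
  structure(list(w_self = w_self, w_neighbor = w_neighbor, bias = as.numeric(bias)),
            class = "conv_stage_weights")
}

#' Graph convolution over bonded neighbourhoods
#'
#' Computes, for every atom i,
#' `ReLU(w_self f_i + sum over bonded j of w_neighbor f_j + bias)`.
#' The output layer index is the input's plus one; outputs are elementwise
#' non-negative by construction.
#'
#' @param f Atom feature matrix (atoms x in_dim), e.g. from
#'   [one_hot_encode()] or a previous stage.
#' @param g The [mol_graph()] the features live on.
#' @param w A [conv_stage_weights()] whose input width matches `ncol(f)`.
#' @return Atom feature matrix (atoms x out_dim).
#' @export
convolve <- function(f, g, w) {
  f <- as.matrix(f)
  if (nrow(f) != n_atoms(g)) {
    dimension_error(sprintf("feature rows (%d) != atom count (%d)",
                            nrow(f), n_atoms(g)))
  }
  if (ncol(f) != ncol(w$w_self)) {
    dimension_error(sprintf("feature width (%d) != weight input width (%d)",
                            ncol(f), ncol(w$w_self)))
  }
  nbr_sum <- matrix(0, nrow(f), ncol(f))
  if (nrow(g$edges)) {
    e <- g$edges
    # accumulate both directions of every undirected bond
    src <- c(e[, 2L], e[, 1L]); dst <- c(e[, 1L], e[, 2L])
    acc <- rowsum(f[src, , drop = FALSE], group = dst)
    rows <- as.integer(rownames(acc))
    nbr_sum[rows, ] <- acc
  }
  z <- f %*% t(w$w_self) + nbr_sum %*% t(w$w_neighbor)
  z <- sweep(z, 2L, w$bias, `+`)
  out <- relu(z)
  li <- attr(f, "layer_index")
  attr(out, "layer_index") <- if (is.null(li)) 1L else li + 1L
  out
}

#' Neighbourhood max-pooling
#'
#' Replaces each atom's feature vector by the columnwise maximum over its
#' bonded neighbours and itself -- the same neighbourhood convention as the
#' convolution sum.  Shape and layer index are preserved.
#'
#' @inheritParams convolve
#' @return Pooled atom feature matrix, same shape as `f`.
#' @export
max_pool <- function(f, g) {
  f <- as.matrix(f)
  if (nrow(f) != n_atoms(g)) {
    dimension_error(sprintf("feature rows (%d) != atom count (%d)",
                            nrow(f), n_atoms(g)))
  }
  nbr <- neighbor_list(g)
  out <- f
  for (i in seq_len(nrow(f))) {
    if (length(nbr[[i]])) {
      out[i, ] <- do.call(pmax, c(list(f[i, ]),
                                  lapply(nbr[[i]], function(j) f[j, ])))
    }
  }
  attr(out, "layer_index") <- attr(f, "layer_index")
  out
}

#' Sum-gather readout
#'
#' Sums the feature vectors of all atoms into a single molecule vector;
#' the readout is invariant to any reordering of the atoms.
#'
#' @param f Non-empty atom feature matrix.
#' @return Numeric vector of length `ncol(f)`.
#' @export
gather_molecule <- function(f) {
  f <- as.matrix(f)
  if (nrow(f) < 1L) dimension_error("cannot gather zero atoms")
  colSums(f)
}

#' Per-category classifier head
#'
#' Maps the gathered molecule vector to two logits (positive, negative) for
#' each of K categories.  Categories are scored independently so a compound
#' can be assigned to several categories, or to none.
#'
#' @param weights Matrix (2K x in_dim); rows `2k-1` and `2k` are category
#'   k's positive and negative logit weights.
#' @param bias Optional length-2K bias.
#' @param categories Character vector of K category names.
#' @return Object of class `classifier_head`.
#' @export
classifier_head <- function(weights, bias = NULL, categories = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) %% 2L != 0L) {
    dimension_error("head weight rows must be 2 per category")
  }
  k <- nrow(weights) / 2L
  if (is.null(bias)) bias <- numeric(2L * k)
  if (length(bias) != 2L * k) dimension_error("head bias length must be 2K")
  if (is.null(categories)) categories <- paste0("cat", seq_len(k))
  if (length(categories) != k) dimension_error("need one name per category")
  structure(list(weights = weights, bias = as.numeric(bias),
                 categories = as.character(categories)),
            class = "classifier_head")
}

softmax_pairs <- function(logits) {
  # logits: n x 2K; stable softmax within each (pos, neg) column pair
  k2 <- ncol(logits)
  pos <- logits[, seq(1L, k2, by = 2L), drop = FALSE]
  neg <- logits[, seq(2L, k2, by = 2L), drop = FALSE]
  m <- pmax(pos, neg)
  ep <- exp(pos - m); en <- exp(neg - m)
  p <- ep / (ep + en)
  out <- matrix(0, nrow(logits), k2)
  out[, seq(1L, k2, by = 2L)] <- p
  out[, seq(2L, k2, by = 2L)] <- 1 - p
  out
}

#' Score a molecule vector with the paired-softmax heads
#'
#' @param mol_vec Gathered molecule vector from [gather_molecule()].
#' @param head A [classifier_head()].
#' @return A `prediction_vector`: data frame with one row per category and
#'   columns `category`, `y_pos`, `y_neg`; each pair sums to 1.
#' @export
classify <- function(mol_vec, head) {
  mol_vec <- as.numeric(mol_vec)
  if (length(mol_vec) != ncol(head$weights)) {
    dimension_error(sprintf("molecule vector length (%d) != head input width (%d)",
                            length(mol_vec), ncol(head$weights)))
  }
  logits <- matrix(head$weights %*% mol_vec + head$bias, nrow = 1L)
  probs <- softmax_pairs(logits)
  k <- length(head$categories)
  structure(
    data.frame(category = head$categories,
               y_pos = probs[1L, seq(1L, 2L * k, by = 2L)],
               y_neg = probs[1L, seq(2L, 2L * k, by = 2L)]),
    class = c("prediction_vector", "data.frame")
  )
}

#' Summed paired cross-entropy loss
#'
#' The training loss for one compound is the sum over categories of the
#' cross-entropy between the predicted (positive, negative) pair and the
#' one-hot pair derived from the binary label:
#' `-sum_k [ y_k log(p_k) + (1 - y_k) log(1 - p_k) ]`.
#' Probabilities are clamped below at `epsilon` so the loss stays finite
#' under saturated softmax outputs.
#'
#' @param pred A `prediction_vector` from [classify()] (or any data frame
#'   with `y_pos`/`y_neg` columns).
#' @param label Binary vector of length K (category membership).
#' @param epsilon Lower clamp for log arguments (default 1e-10).
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(pred, label, epsilon = 1e-10) {
  label <- as.numeric(label)
  if (length(label) != nrow(pred)) {
    dimension_error(sprintf("label length (%d) != number of categories (%d)",
                            length(label), nrow(pred)))
  }
  if (!all(label %in% c(0, 1))) format_error("labels must be binary")
  yp <- pmax(pred$y_pos, epsilon)
  yn <- pmax(pred$y_neg, epsilon)
  -sum(label * log(yp) + (1 - label) * log(yn))
}

#' Full forward pass of the MGCNN
#'
#' One-hot encodes the molecule, applies `n_stages` convolution + pooling
#' stages, gathers atom features into a molecule vector and scores it with
#' the paired-softmax heads.  Inference is deterministic (dropout is a
#' training-time operation only).
#'
#' @param g A [mol_graph()].
#' @param model An `mgcnn_model` from [mgcnn_model()] or [train_mgcnn()].
#' @return A `prediction_vector` (see [classify()]).
#' @export
forward <- function(g, model) {
  f <- one_hot_encode(g, model$alphabet)
  for (w in model$stages) {
    f <- convolve(f, g, w)
    f <- max_pool(f, g)
  }
  classify(gather_molecule(f), model$head)
}

#' Initialise an untrained MGCNN
#'
#' Weights use He-style scaled normal initialisation (appropriate for ReLU
#' stages), biases start at zero; all randomness is governed by `seed`.
#'
#' @param alphabet An [atom_alphabet()]; fixes the input width and the
#'   one-hot index of every element.
#' @param categories Character vector of K category names.
#' @param n_stages Number of convolution + pooling stages (default 3).
#' @param stage_dims Output width of each stage (default 128 each).
#' @param use_bias Include a learnable bias per convolution stage
#'   (default TRUE; FALSE gives the strict bias-free convolution).
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `mgcnn_model` with elements `alphabet`,
#'   `categories`, `stages` (list of [conv_stage_weights()]), `head`.
#' @export
mgcnn_model <- function(alphabet, categories, n_stages = 3L,
                        stage_dims = rep(128L, n_stages),
                        use_bias = TRUE, seed = 1L) {
  if (n_stages < 1L) dimension_error("need at least one stage")
  if (length(stage_dims) != n_stages) {
    dimension_error("stage_dims must have one width per stage")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  in_dim <- length(alphabet)
  stages <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    out_dim <- stage_dims[s]
    sd <- sqrt(2 / in_dim)
    stages[[s]] <- conv_stage_weights(
      matrix(stats::rnorm(out_dim * in_dim, sd = sd), out_dim, in_dim),
      matrix(stats::rnorm(out_dim * in_dim, sd = sd), out_dim, in_dim),
      if (use_bias) numeric(out_dim) else NULL
    )
    in_dim <- out_dim
  }
  k <- length(categories)
  # The head starts at zero: every category opens at (0.5, 0.5), the loss at
  # exactly K*ln 2, and the sum-gather readout (whose magnitude grows with
  # molecule size) cannot saturate the softmax before training starts.
  head <- classifier_head(
    matrix(0, 2L * k, in_dim),
    numeric(2L * k),
    categories
  )
  structure(
    list(alphabet = alphabet, categories = as.character(categories),
         n_stages = as.integer(n_stages), stage_dims = as.integer(stage_dims),
         use_bias = isTRUE(use_bias), stages = stages, head = head),
    class = "mgcnn_model"
  )
}

#' @export
print.mgcnn_model <- function(x, ...) {
  cat(sprintf("<mgcnn_model: %d stages (%s), alphabet {%s}, %d categories>\n",
              x$n_stages, paste(x$stage_dims, collapse = ","),
              paste(x$alphabet, collapse = ","), length(x$categories)))
  invisible(x)
}

# Preserve the caller's RNG stream when a function needs its own seed.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
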