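# Internal batched forward/backward engine.
#
# A set of molecules is processed as one disjoint-union graph: atom feature
# matrices are stacked row-wise, bonded neighbourhoods live in one padded
# neighbour-index matrix, and the gather layer becomes a grouped row sum.
# Because
# convolution and pooling are strictly neighbourhood-local, this is exactly
# equivalent to per-molecule computation but turns an epoch into a handful
# of large matrix products.
#
# Pooling uses a padded neighbour-index matrix: column 1 is the atom itself,
# further columns its bonded neighbours, padded with the atom's own index
# (a duplicate never changes a maximum).  The winning column is recorded so
# the backward pass can route gradients to the argmax source.

build_batch <- function(graphs, alphabet) {
  sizes <- vapply(graphs, n_atoms, integer(1))
  offsets <- cumsum(c(0L, sizes))
  n_total <- offsets[length(offsets)]
  atoms_all <- unlist(lapply(graphs, `[[`, "atoms"))
  idx <- match(atoms_all, alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    mol <- findInterval(bad, offsets + 1L)
    unknown_atom_error(atoms_all[bad], graphs[[mol]]$compound_id)
  }
  x0 <- matrix(0, n_total, length(alphabet))
  x0[cbind(seq_len(n_total), idx)] <- 1

  el <- do.call(rbind, lapply(seq_along(graphs), function(m) {
    e <- graphs[[m]]$edges
    if (nrow(e)) e + offsets[m] else e
  }))
  if (is.null(el)) el <- matrix(integer(0), ncol = 2L)

  deg <- tabulate(c(el[, 1L], el[, 2L]), nbins = n_total)
  d_max <- if (length(deg)) max(deg) else 0L
  pool_idx <- matrix(rep(seq_len(n_total), d_max + 1L), n_total, d_max + 1L)
  if (nrow(el)) {
    dst <- c(el[, 1L], el[, 2L])
    src <- c(el[, 2L], el[, 1L])
    o <- order(dst)
    dst <- dst[o]; src <- src[o]
    slot <- sequence(rle(dst)$lengths) + 1L
    pool_idx[cbind(dst, slot)] <- src
  }

  mol_id <- rep(seq_along(graphs), sizes)
  list(n_total = n_total, n_mol = length(graphs), sizes = sizes,
       mol_id = mol_id, x0 = x0, pool_idx = pool_idx,
       compound_ids = vapply(graphs, `[[`, character(1), "compound_id"))
}

# Restrict a prebuilt batch to a subset of its molecules (minibatching
# without rebuilding graph structure).  Neighbour indices are remapped to
# the subset's row numbering; bonds never cross molecules, so the mapping
# is total on every retained row.
subset_batch <- function(batch, mols) {
  keep <- batch$mol_id %in% mols
  rows <- which(keep)
  newpos <- integer(batch$n_total)
  newpos[rows] <- seq_along(rows)
  pool_idx <- matrix(newpos[batch$pool_idx[rows, , drop = FALSE]],
                     nrow = length(rows))
  list(n_total = length(rows), n_mol = length(mols),
       sizes = batch$sizes[mols],
       mol_id = match(batch$mol_id[rows], mols),
       x0 = batch$x0[rows, , drop = FALSE],
       pool_idx = pool_idx,
       compound_ids = batch$compound_ids[mols])
}

pool_forward <- function(h, pool_idx) {
  out <- pool_fwd_cpp(h, pool_idx)
  list(p = out$p, src = out$src)
}

pool_backward <- function(dp, src) {
  pool_bwd_cpp(dp, src)
}

dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

# Full forward pass over a batch.  In training mode dropout masks are drawn
# from the current RNG stream and kept for the backward pass.
batch_forward <- function(params, batch, training = FALSE,
                          dropout_input = 0, dropout_after_pool = 0) {
  x <- batch$x0
  mask0 <- if (training) dropout_mask(nrow(x), ncol(x), dropout_input) else NULL
  if (!is.null(mask0)) x <- x * mask0
  n_stages <- length(params$stages)
  cache <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    w <- params$stages[[s]]
    ax <- nbr_sum_cpp(x, batch$pool_idx)
    z <- tcrossprod(x, w$w_self) + tcrossprod(ax, w$w_neighbor)
    z <- z + rep(w$bias, each = nrow(z))
    h <- relu_cpp(z)
    pool <- pool_forward(h, batch$pool_idx)
    p <- pool$p
    mask <- if (training) dropout_mask(nrow(p), ncol(p), dropout_after_pool) else NULL
    xn <- if (is.null(mask)) p else p * mask
    cache[[s]] <- list(x_in = x, ax = ax, z = z, src = pool$src, mask = mask)
    x <- xn
  }
  g <- rowsum(x, group = batch$mol_id)
  logits <- tcrossprod(g, params$head$weights)
  logits <- logits + rep(params$head$bias, each = nrow(logits))
  probs <- softmax_pairs(logits)
  list(gathered = g, logits = logits, probs = probs,
       cache = cache, mask0 = mask0)
}

# Mean (over molecules) of the per-molecule summed paired cross-entropy.
batch_loss <- function(probs, targets, epsilon) {
  mean(-rowSums(targets * log(pmax(probs, epsilon))))
}

# Targets: n_mol x 2K interleaved (pos, neg) one-hot pairs.
expand_targets <- function(membership) {
  k <- ncol(membership)
  t2 <- matrix(0, nrow(membership), 2L * k)
  t2[, seq(1L, 2L * k, by = 2L)] <- membership
  t2[, seq(2L, 2L * k, by = 2L)] <- 1 - membership
  t2
}

# Gradients of batch_loss wrt every parameter; returns the same nested
# shape as `params`.  Uses the standard softmax + cross-entropy identity
# (probs - targets) for the logit gradient.
batch_backward <- function(params, batch, fwd, targets) {
  n_mol <- batch$n_mol
  dlogits <- (fwd$probs - targets) / n_mol
  d_head_w <- crossprod(dlogits, fwd$gathered)
  d_head_b <- colSums(dlogits)
  dg <- dlogits %*% params$head$weights
  dx <- dg[batch$mol_id, , drop = FALSE]
  n_stages <- length(params$stages)
  d_stages <- vector("list", n_stages)
  for (s in rev(seq_len(n_stages))) {
    cc <- fwd$cache[[s]]
    dp <- if (is.null(cc$mask)) dx else dx * cc$mask
    dh <- pool_backward(dp, cc$src)
    dz <- relu_grad_cpp(dh, cc$z)
    d_stages[[s]] <- list(
      w_self = crossprod(dz, cc$x_in),
      w_neighbor = crossprod(dz, cc$ax),
      bias = colSums(dz)
    )
    if (s > 1L) {
      w <- params$stages[[s]]
      dx <- dz %*% w$w_self +
        nbr_sum_cpp(dz %*% w$w_neighbor, batch$pool_idx)
    }
  }
  list(stages = d_stages, head = list(weights = d_head_w, bias = d_head_b))
}

# --- flat parameter views (Adam, finite differences) ----------------------

params_flatten <- function(params, use_bias = TRUE) {
  out <- list()
  for (s in seq_along(params$stages)) {
    w <- params$stages[[s]]
    out[[sprintf("s%d.w_self", s)]] <- w$w_self
    out[[sprintf("s%d.w_neighbor", s)]] <- w$w_neighbor
    if (use_bias) out[[sprintf("s%d.bias", s)]] <- w$bias
  }
  out[["head.weights"]] <- params$head$weights
  out[["head.bias"]] <- params$head$bias
  out
}

params_unflatten <- function(flat, template) {
  for (s in seq_along(template$stages)) {
    template$stages[[s]]$w_self[] <- flat[[sprintf("s%d.w_self", s)]]
    template$stages[[s]]$w_neighbor[] <- flat[[sprintf("s%d.w_neighbor", s)]]
    key <- sprintf("s%d.bias", s)
    if (!is.null(flat[[key]])) template$stages[[s]]$bias[] <- flat[[key]]
  }
  template$head$weights[] <- flat[["head.weights"]]
  template$head$bias[] <- flat[["head.bias"]]
  template
}

adam_init <- function(flat) {
  list(t = 0L,
       m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0))
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(flat)) {
    gr <- grads[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * gr
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * gr * gr
    flat[[key]] <- flat[[key]] -
      lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}
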