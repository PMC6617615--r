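# Independent reference implementations used as oracles.  Each is written
# as a direct transcription of the defining formula (explicit loops, no
# vectorization) so it shares no code path with the package internals.

# Convolution: for every atom i, ReLU(w0 f_i + sum over bonded j of w1 f_j + b),
# computed entry by entry with a double loop over (i, j in Adj(i)).
oracle_convolve <- function(f, g, w) {
  n <- nrow(f)
  adj <- rep(list(integer(0)), n)
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      i <- g$edges[r, 1]; j <- g$edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  out <- matrix(0, n, nrow(w$w_self))
  for (i in seq_len(n)) {
    z <- w$w_self %*% f[i, ] + w$bias
    for (j in adj[[i]]) {
      z <- z + w$w_neighbor %*% f[j, ]
    }
    out[i, ] <- pmax(as.numeric(z), 0)
  }
  out
}

# Summed paired cross-entropy, accumulated category by category.
oracle_loss <- function(y_pos, y_neg, label, eps = 1e-10) {
  total <- 0
  for (k in seq_along(label)) {
    yp <- max(y_pos[k], eps)
    yn <- max(y_neg[k], eps)
    total <- total - (label[k] * log(yp) + (1 - label[k]) * log(yn))
  }
  total
}

# Plain queue-based BFS distances from one atom; independent of igraph.
oracle_bfs_dist <- function(g, start) {
  n <- length(g$atoms)
  adj <- rep(list(integer(0)), n)
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      i <- g$edges[r, 1]; j <- g$edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  dist <- rep(Inf, n)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

# Independent rule scans (used against the generator's own labels).
oracle_contains <- function(g, sym) as.integer(sym %in% g$atoms)

oracle_pair_dist <- function(g, a, b, d) {
  for (i in which(g$atoms == a)) {
    dist <- oracle_bfs_dist(g, i)
    if (any(dist[g$atoms == b] == d)) return(1L)
  }
  0L
}

# Exact search for a simple cycle of length `size`: DFS over simple paths
# of length size-1 from each edge endpoint back to the start.
oracle_has_ring <- function(g, size) {
  n <- length(g$atoms)
  adj <- rep(list(integer(0)), n)
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      i <- g$edges[r, 1]; j <- g$edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  found <- FALSE
  dfs <- function(path) {
    if (found) return()
    v <- path[length(path)]
    if (length(path) == size) {
      if (path[1] %in% adj[[v]]) found <<- TRUE
      return()
    }
    for (u in adj[[v]]) {
      if (!(u %in% path)) dfs(c(path, u))
    }
  }
  for (s in seq_len(n)) {
    dfs(s)
    if (found) break
  }
  as.integer(found)
}

# Union-find connected components over an edge list on `n` nodes.
oracle_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Small random molecule-like graph for operator tests: a random tree plus
# an optional extra edge, random elements.
random_test_graph <- function(id, n, elements = c("C", "H", "N", "O")) {
  atoms <- sample(elements, n, replace = TRUE)
  edges <- NULL
  if (n > 1) {
    edges <- cbind(2:n, vapply(2:n, function(t) sample.int(t - 1, 1), integer(1)))
    if (n > 3 && stats::runif(1) < 0.5) {
      extra <- sort(sample.int(n, 2))
      edges <- rbind(edges, extra)
    }
  }
  mol_graph(id, atoms, edges)
}

# Apply a vertex permutation to a graph (edges remapped accordingly).
permute_graph <- function(g, perm) {
  inv <- order(perm)
  atoms <- g$atoms[inv]
  edges <- g$edges
  if (nrow(edges)) edges <- matrix(perm[edges], ncol = 2)
  mol_graph(paste0(g$compound_id, "_perm"), atoms, edges)
}
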