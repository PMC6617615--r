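# Seeded synthetic molecule fixtures.
#
# Molecules are random connected graphs over {C,H,N,O,S}: a heavy-atom tree
# grown under approximate valence capacities (C4 N3 O2 S2), an optional
# ring-closing edge, and hydrogens attached to the remaining free valences.
# Graphs are abstract -- chemical validity is approximated, not enforced,
# which matches a model that only consumes topology and element identity.
#
# Labels come from decidable structural rules (element presence, ring of a
# given size, element pair at a given graph distance).  Rules deliberately
# need different receptive-field radii so that deeper convolution stacks
# have something to gain.

VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, H = 1L)

#' Structural label rules
#'
#' A label rule is a decidable predicate on a molecular graph, used both to
#' label synthetic datasets and as the ground truth when evaluating them.
#' `rule_contains(sym)` is true when at least one atom has element `sym`
#' (radius-0 information); `rule_ring(size)` when the graph contains a
#' cycle of exactly `size` vertices; `rule_pair_dist(a, b, d)` when some
#' atom of element `a` lies at graph distance exactly `d` from an atom of
#' element `b` (radius-`d` information).
#'
#' @param symbol,a,b Element symbols.
#' @param size Ring size (>= 3).
#' @param distance Graph distance (>= 1).
#' @param name Optional rule name; a readable default is derived.
#' @return Object of class `label_rule`.
#' @export
rule_contains <- function(symbol, name = paste0("contains_", symbol)) {
  structure(list(name = name, type = "contains", symbol = symbol),
            class = "label_rule")
}

#' @rdname rule_contains
#' @export
rule_ring <- function(size, name = paste0("ring", size)) {
  if (size < 3L) format_error("ring size must be >= 3")
  structure(list(name = name, type = "ring", size = as.integer(size)),
            class = "label_rule")
}

#' @rdname rule_contains
#' @export
rule_pair_dist <- function(a, b, distance,
                           name = sprintf("%s_%s_dist%d", a, b, distance)) {
  if (distance < 1L) format_error("distance must be >= 1")
  structure(list(name = name, type = "pair_dist", a = a, b = b,
                 distance = as.integer(distance)),
            class = "label_rule")
}

#' Evaluate a label rule on a molecular graph
#'
#' @param rule A `label_rule`.
#' @param g A [mol_graph()].
#' @return 0 or 1.
#' @export
evaluate_rule <- function(rule, g) {
  if (!inherits(rule, "label_rule")) format_error("not a label_rule")
  val <- switch(
    rule$type,
    contains = any(g$atoms == rule$symbol),
    ring = {
      if (n_atoms(g) < rule$size || nrow(g$edges) < rule$size) FALSE
      else igraph::subgraph_isomorphic(igraph::make_ring(rule$size),
                                       as_igraph(g), induced = FALSE)
    },
    pair_dist = {
      ia <- which(g$atoms == rule$a)
      ib <- which(g$atoms == rule$b)
      if (!length(ia) || !length(ib)) FALSE
      else {
        dm <- igraph::distances(as_igraph(g), v = ia, to = ib)
        any(dm == rule$distance)
      }
    },
    format_error(sprintf("unknown rule type '%s'", rule$type))
  )
  as.integer(val)
}

# Grow one random molecule; returns NULL when the draw gets stuck so the
# caller can retry (keeps the size invariant strict).
grow_molecule <- function(id, n_total, heavy_frac, element_probs,
                          p_ring, ring_size) {
  n_heavy <- max(1L, round(n_total * heavy_frac))
  elems <- sample(names(element_probs), n_heavy, replace = TRUE,
                  prob = element_probs)
  cap <- VALENCE[elems]
  edges <- matrix(integer(0), ncol = 2L)
  for (t in seq_len(n_heavy)[-1L]) {
    open <- which(cap[seq_len(t - 1L)] > 0L)
    if (!length(open)) return(NULL)
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    edges <- rbind(edges, c(parent, t))
    cap[parent] <- cap[parent] - 1L
    cap[t] <- cap[t] - 1L
  }
  if (stats::runif(1) < p_ring && n_heavy >= ring_size) {
    ig <- igraph::graph_from_edgelist(unname(edges), directed = FALSE)
    dm <- igraph::distances(ig)
    open <- cap > 0L
    cand <- which(dm == ring_size - 1L & outer(open, open, `&`), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand)) {
      pick <- cand[if (nrow(cand) == 1L) 1L else sample(nrow(cand), 1L), ]
      edges <- rbind(edges, pick)
      cap[pick[1L]] <- cap[pick[1L]] - 1L
      cap[pick[2L]] <- cap[pick[2L]] - 1L
    }
  }
  n_h <- n_total - n_heavy
  for (i in seq_len(n_h)) {
    open <- which(cap[seq_len(n_heavy)] > 0L)
    if (!length(open)) return(NULL)
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    elems <- c(elems, "H")
    cap <- c(cap, 0L)
    cap[parent] <- cap[parent] - 1L
    edges <- rbind(edges, c(parent, length(elems)))
  }
  mol_graph(id, elems, edges)
}

#' Generate a seeded synthetic multilabel molecule dataset
#'
#' Produces `n` random connected molecule graphs and labels each by
#' evaluating every rule, so the labels are self-consistent with the
#' structures by construction.  Identical `(n, seed, rules, ...)` give
#' identical datasets.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param rules Non-empty list of `label_rule`s (see [rule_contains()]).
#' @param size_range Inclusive atom-count range per molecule, within
#'   2..60 (hydrogens included).
#' @param heavy_frac Fraction of atoms that are heavy (non-H).
#' @param element_probs Sampling probabilities over heavy elements.
#' @param p_ring Probability of attempting one ring closure.
#' @param ring_size Size of the closed ring.
#' @return Object of class `synthetic_dataset`: list with `graphs`,
#'   `labels` (a [label_matrix()]) and `params`.
#' @examples
#' ds <- generate_molecules(10, seed = 7,
#'                          rules = list(rule_contains("N"), rule_ring(5)))
#' ds$labels
#' @export
generate_molecules <- function(n, seed, rules,
                               size_range = c(6L, 16L),
                               heavy_frac = 0.6,
                               element_probs = c(C = 0.60, N = 0.12,
                                                 O = 0.20, S = 0.08),
                               p_ring = 0.5, ring_size = 5L) {
  if (n < 1L) format_error("n must be >= 1")
  if (!length(rules)) format_error("need at least one rule")
  if (size_range[1L] < 2L || size_range[2L] > 60L ||
      size_range[1L] > size_range[2L]) {
    format_error("size_range must lie within [2, 60]")
  }
  if (ring_size > size_range[2L]) {
    format_error("ring rule unsatisfiable: ring_size exceeds the maximum size")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  graphs <- vector("list", n)
  for (i in seq_len(n)) {
    g <- NULL
    for (try in 1:50) {
      sizes <- seq(size_range[1L], size_range[2L])
      n_total <- sizes[sample.int(length(sizes), 1L)]
      g <- grow_molecule(sprintf("syn%04d", i), n_total, heavy_frac,
                         element_probs, p_ring, ring_size)
      if (!is.null(g)) break
    }
    if (is.null(g)) format_error("generator failed to grow a molecule (50 tries)")
    graphs[[i]] <- g
  }
  membership <- vapply(rules, function(r) {
    vapply(graphs, function(g) evaluate_rule(r, g), integer(1))
  }, integer(n))
  membership <- matrix(membership, nrow = n)
  labels <- label_matrix(vapply(graphs, `[[`, character(1), "compound_id"),
                         vapply(rules, `[[`, character(1), "name"),
                         membership)
  structure(
    list(graphs = graphs, labels = labels,
         params = list(n = n, seed = seed,
                       rules = vapply(rules, `[[`, character(1), "name"),
                       size_range = size_range, heavy_frac = heavy_frac,
                       element_probs = element_probs, p_ring = p_ring,
                       ring_size = ring_size)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d molecules, rules {%s}, seed %d>\n",
              length(x$graphs), paste(x$params$rules, collapse = ","),
              x$params$seed))
  invisible(x)
}

#' Write / read molecular graphs as a plain-text edge-list table
#'
#' One line per molecule: compound id, space-separated atom symbols, and
#' semicolon-separated `i-j` bond pairs (1-based atom indices).  A
#' toolkit-free interchange format for synthetic molecules that are not
#' chemically valid SMILES.
#'
#' @param graphs List of [mol_graph()] objects.
#' @param path File path.
#' @return `read_graph_table` returns a list of [mol_graph()]s.
#' @export
write_graph_table <- function(graphs, path) {
  lines <- vapply(graphs, function(g) {
    ed <- if (nrow(g$edges)) {
      paste(sprintf("%d-%d", g$edges[, 1L], g$edges[, 2L]), collapse = ";")
    } else ""
    paste(g$compound_id, paste(g$atoms, collapse = " "), ed, sep = "\t")
  }, character(1))
  writeLines(c("compound_id\tatoms\tedges", lines), path)
  invisible(path)
}

#' @rdname write_graph_table
#' @export
read_graph_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1L] != "compound_id\tatoms\tedges") {
    format_error("not a graph table (expected header compound_id/atoms/edges)")
  }
  lapply(lines[-1L], function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) format_error("malformed graph table line")
    atoms <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
    edges <- NULL
    if (length(parts) >= 3L && nzchar(parts[3L])) {
      prs <- strsplit(strsplit(parts[3L], ";", fixed = TRUE)[[1L]], "-",
                      fixed = TRUE)
      edges <- do.call(rbind, lapply(prs, as.integer))
    }
    mol_graph(parts[1L], atoms, edges)
  })
}
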