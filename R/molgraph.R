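#' Construct a molecular graph
#'
#' A molecular graph is the abstract (hydrogen-optional) topology of a
#' molecule: atoms are vertices labelled by element symbol, chemical bonds
#' are plain undirected edges.  Bond order, aromaticity, charges, isotopes
#' and stereochemistry are deliberately discarded -- the convolutional model
#' operates on topology and element identity only.
#'
#' @param compound_id Single string identifying the compound.
#' @param atoms Character vector of element symbols, one per atom, in a
#'   fixed order.
#' @param edges Two-column integer matrix of bonds; each row is an unordered
#'   pair of 1-based atom indices.  May have zero rows (single atoms,
#'   hydrogen-stripped water, ...).
#' @return An object of class `mol_graph`.
#' @examples
#' water <- mol_graph("water", c("O", "H", "H"), rbind(c(1, 2), c(1, 3)))
#' water
#' @export
mol_graph <- function(compound_id, atoms, edges = NULL) {
  if (length(compound_id) != 1L || !is.character(compound_id)) {
    format_error("compound_id must be a single string")
  }
  atoms <- as.character(atoms)
  if (length(atoms) < 1L) {
    format_error(sprintf("compound '%s' has no atoms", compound_id))
  }
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  n <- length(atoms)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n)) {
      format_error(sprintf("compound '%s': bond references atom outside 1..%d",
                           compound_id, n))
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      format_error(sprintf("compound '%s': self-bond not allowed", compound_id))
    }
    # canonical unordered form: smaller index first, rows sorted, no duplicates
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE])
  }
  dimnames(edges) <- NULL
  structure(
    list(compound_id = compound_id, atoms = atoms, edges = edges),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph '%s': %d atoms (%s), %d bonds>\n",
              x$compound_id, length(x$atoms),
              paste(names(sort(-table(x$atoms))), collapse = ","),
              nrow(x$edges)))
  invisible(x)
}

n_atoms <- function(g) length(g$atoms)

#' Adjacency list of a molecular graph
#'
#' Returns, for each atom, the integer indices of its bonded neighbours
#' (the vertex itself is not included; the convolution and pooling
#' operators add it where their neighbourhood convention requires it).
#'
#' @param g A [mol_graph()].
#' @return List of integer vectors, one per atom.
#' @export
neighbor_list <- function(g) {
  nbr <- rep(list(integer(0)), n_atoms(g))
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      i <- g$edges[r, 1L]; j <- g$edges[r, 2L]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  lapply(nbr, sort)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = as.data.frame(g$edges),
    directed = FALSE,
    vertices = data.frame(name = seq_along(g$atoms), symbol = g$atoms)
  )
}

# --- structure input -------------------------------------------------------

# OpenBabel writes V2000 molfiles with fixed-position counts/atom/bond lines;
# read one $$$$-terminated record back into a mol_graph.
molfile_to_graph <- function(lines, compound_id = NULL) {
  if (length(lines) < 4L) parse_error("truncated molfile record")
  counts <- lines[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || is.na(nb) || na < 1L) {
    parse_error("unreadable molfile counts line")
  }
  atom_lines <- lines[4L + seq_len(na)]
  atoms <- trimws(substr(atom_lines, 32L, 34L))
  edges <- NULL
  if (nb > 0L) {
    bond_lines <- lines[4L + na + seq_len(nb)]
    edges <- cbind(as.integer(substr(bond_lines, 1L, 3L)),
                   as.integer(substr(bond_lines, 4L, 6L)))
  }
  if (is.null(compound_id) || !nzchar(compound_id)) {
    compound_id <- trimws(lines[1L])
  }
  mol_graph(compound_id, atoms, edges)
}

split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(list(lines))
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) lines[s:(e - 1L)], starts, ends, SIMPLIFY = FALSE)
}

ob_convert <- function(source, from, explicit_h) {
  out <- if (explicit_h) {
    ChemmineOB::convertFormat(from, "SDF", source = source,
                              options = data.frame(names = "h", args = ""))
  } else {
    ChemmineOB::convertFormat(from, "SDF", source = source)
  }
  strsplit(out, "\n", fixed = TRUE)[[1L]]
}

#' Parse a single SMILES line into a molecular graph
#'
#' The line holds a SMILES string optionally followed by whitespace and a
#' compound identifier.  Parsing is delegated to OpenBabel; by default
#' hydrogens are materialised as explicit vertices, since the one-hot atom
#' alphabet treats H like any other element.
#'
#' @param line A SMILES record, e.g. `"CCO ethanol"`.
#' @param explicit_h Materialise hydrogens as graph vertices (default TRUE).
#' @param line_number Carried into parse errors for file-level reporting.
#' @return A [mol_graph()], or `NULL` for an empty/blank line (skip signal).
#' @examples
#' parse_smiles("O water")          # 3 atoms, 2 bonds
#' parse_smiles("C", explicit_h = FALSE)  # 1 atom, 0 bonds
#' @export
parse_smiles <- function(line, explicit_h = TRUE, line_number = NA_integer_) {
  line <- trimws(line)
  if (!nzchar(line)) return(NULL)
  parts <- strsplit(line, "[ \t]+")[[1L]]
  smi <- parts[1L]
  id <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ") else smi
  out <- suppressWarnings(
    tryCatch(ob_convert(paste0(smi, "\n"), "SMI", explicit_h),
             error = function(e) character(0))
  )
  if (!length(out) || !any(grepl("V2000", out, fixed = TRUE))) {
    parse_error(sprintf("line %s: unparseable SMILES '%s'",
                        ifelse(is.na(line_number), "?", line_number), smi),
                line = line_number)
  }
  molfile_to_graph(out, compound_id = id)
}

#' Read a SMILES file
#'
#' One record per line, `SMILES<TAB>compound_id` (any whitespace accepted).
#' Blank lines are skipped; an unparseable line raises a parse error
#' carrying its line number.
#'
#' @inheritParams parse_smiles
#' @param path Path to the SMILES file.
#' @return List of [mol_graph()] objects.
#' @export
read_smiles <- function(path, explicit_h = TRUE) {
  lines <- readLines(path, warn = FALSE)
  graphs <- list()
  for (i in seq_along(lines)) {
    g <- parse_smiles(lines[i], explicit_h = explicit_h, line_number = i)
    if (!is.null(g)) graphs[[length(graphs) + 1L]] <- g
  }
  graphs
}

#' Read a multi-molecule MDL SDF file
#'
#' Compound identifiers come from the molfile title line, or from a named
#' data field when `id_field` is given.  Structures are round-tripped
#' through OpenBabel so that hydrogen materialisation matches the SMILES
#' path.
#'
#' @param path Path to the SDF file.
#' @param explicit_h Materialise hydrogens as vertices (default TRUE).
#' @param id_field Optional name of an SDF data field holding the compound id.
#' @return List of [mol_graph()] objects.
#' @export
read_sdf <- function(path, explicit_h = TRUE, id_field = NULL) {
  raw <- readLines(path, warn = FALSE)
  records <- split_sdf_records(raw)
  records <- Filter(function(r) any(nzchar(trimws(r))), records)
  graphs <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[i][[1L]]
    id <- NULL
    if (!is.null(id_field)) {
      hit <- grep(sprintf("^>.*<%s>", id_field), rec)
      if (length(hit) && length(rec) > hit[1L]) id <- trimws(rec[hit[1L] + 1L])
    }
    src <- paste0(paste(rec, collapse = "\n"), "\n$$$$\n")
    out <- suppressWarnings(
      tryCatch(ob_convert(src, "SDF", explicit_h),
               error = function(e) character(0))
    )
    if (!length(out) || !any(grepl("V2000", out, fixed = TRUE))) {
      parse_error(sprintf("SDF record %d: unparseable structure", i), line = i)
    }
    graphs[[i]] <- molfile_to_graph(out, compound_id = id)
  }
  graphs
}

# --- alphabet and one-hot features ----------------------------------------

#' Infer the atom alphabet from a set of molecular graphs
#'
#' The alphabet is the sorted list of distinct element symbols observed in
#' the training set; its order fixes the one-hot index of every element and
#' is frozen into a trained model.  Sorting uses C locale so the result is
#' identical across machines and input orderings.
#'
#' @param graphs Non-empty list of [mol_graph()] objects.
#' @return Character vector of class `atom_alphabet`.
#' @export
infer_alphabet <- function(graphs) {
  if (!length(graphs)) format_error("cannot infer an alphabet from zero graphs")
  syms <- unique(unlist(lapply(graphs, `[[`, "atoms")))
  structure(sort(syms, method = "radix"), class = "atom_alphabet")
}

#' @rdname infer_alphabet
#' @param symbols Explicit character vector of element symbols (no duplicates).
#' @export
atom_alphabet <- function(symbols) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) format_error("alphabet symbols must be distinct")
  if (!length(symbols)) format_error("alphabet must be non-empty")
  structure(symbols, class = "atom_alphabet")
}

#' One-hot encode the atoms of a molecular graph
#'
#' Produces the layer-0 atom feature matrix: row i is the indicator vector
#' of atom i's element in the alphabet.  An element absent from the
#' alphabet is a hard error -- silently zero-encoding an unknown atom would
#' change the meaning of the convolution sum.
#'
#' @param g A [mol_graph()].
#' @param alphabet An [atom_alphabet()] covering every element in `g`.
#' @return Numeric matrix (atoms x alphabet size) with attribute
#'   `layer_index = 0` and column names from the alphabet.
#' @examples
#' g <- mol_graph("m", c("C", "O"), rbind(c(1, 2)))
#' one_hot_encode(g, atom_alphabet(c("C", "H", "N", "O")))
#' @export
one_hot_encode <- function(g, alphabet) {
  idx <- match(g$atoms, alphabet)
  if (anyNA(idx)) {
    unknown_atom_error(g$atoms[which(is.na(idx))[1L]], g$compound_id)
  }
  m <- matrix(0, nrow = n_atoms(g), ncol = length(alphabet),
              dimnames = list(NULL, as.character(alphabet)))
  m[cbind(seq_len(nrow(m)), idx)] <- 1
  attr(m, "layer_index") <- 0L
  m
}

# --- label table -----------------------------------------------------------

#' Create a multilabel membership table
#'
#' Binary membership of compounds over K categories.  A compound may belong
#' to zero, one or several categories (multilabel); every compound id is
#' unique.
#'
#' @param compound_ids Character vector of unique compound ids.
#' @param categories Character vector of K category names (header order is
#'   preserved and meaningful).
#' @param membership Binary matrix, `length(compound_ids)` x K.
#' @return Object of class `label_matrix`: the membership matrix with
#'   compound ids as row names and categories as column names.
#' @export
label_matrix <- function(compound_ids, categories, membership) {
  compound_ids <- as.character(compound_ids)
  categories <- as.character(categories)
  if (anyDuplicated(compound_ids)) {
    dup <- compound_ids[duplicated(compound_ids)][1L]
    format_error(sprintf("duplicate compound_id '%s'", dup))
  }
  if (length(categories) < 1L) format_error("need at least one category")
  membership <- as.matrix(membership)
  if (nrow(membership) != length(compound_ids) ||
      ncol(membership) != length(categories)) {
    format_error("membership matrix shape does not match ids/categories")
  }
  if (!all(membership %in% c(0, 1))) {
    bad <- which(!(membership %in% c(0, 1)))[1L]
    format_error(sprintf("non-binary membership value '%s'", membership[bad]),
                 row = (bad - 1L) %% nrow(membership) + 1L)
  }
  storage.mode(membership) <- "integer"
  dimnames(membership) <- list(compound_ids, categories)
  structure(membership, class = c("label_matrix", "matrix", "array"))
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf("<label_matrix: %d compounds x %d categories, %d positive cells>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Read a compound-by-category label table
#'
#' Expects delimited text with a header: a `compound_id` column followed by
#' one column per category, cells in \{0, 1\}.  The delimiter is inferred
#' from the header (tab or comma).
#'
#' @param path Path to the TSV/CSV file.
#' @return A [label_matrix()].
#' @export
read_label_table <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (ncol(df) < 2L) format_error("label table needs compound_id plus >= 1 category")
  ids <- df[[1L]]
  cats <- colnames(df)[-1L]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    format_error(
      sprintf("non-binary cell '%s' at row %d, column '%s'",
              vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], cats[bad[1L, 2L]]),
      row = bad[1L, 1L], column = cats[bad[1L, 2L]]
    )
  }
  label_matrix(ids, cats, num)
}

#' Write a label table
#'
#' Inverse of [read_label_table()]: tab-separated, `compound_id` first.
#'
#' @param labels A [label_matrix()].
#' @param path Output path.
#' @export
write_label_table <- function(labels, path) {
  df <- data.frame(compound_id = rownames(labels),
                   unclass(labels)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
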