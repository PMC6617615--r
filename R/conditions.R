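# Structured error conditions so callers can distinguish parse problems,
# format problems and shape problems programmatically.

mgcnn_abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mgcnn_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

parse_error <- function(message, line = NA_integer_) {
  mgcnn_abort("mgcnn_parse_error", message, line = line)
}

format_error <- function(message, row = NA_integer_, column = NA_character_) {
  mgcnn_abort("mgcnn_format_error", message, row = row, column = column)
}

unknown_atom_error <- function(symbol, compound_id) {
  mgcnn_abort(
    "mgcnn_unknown_atom_error",
    sprintf("atom symbol '%s' in compound '%s' is not in the model alphabet",
            symbol, compound_id),
    symbol = symbol, compound_id = compound_id
  )
}

dimension_error <- function(message, ...) {
  mgcnn_abort("mgcnn_dimension_error", message, ...)
}
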