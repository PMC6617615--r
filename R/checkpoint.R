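# Versioned single-file JSON checkpoint: architecture, weights, alphabet,
# category names and training configuration in one library-agnostic text
# archive.  Doubles are written with 17 significant digits, which is enough
# for IEEE-754 binary64 round-tripping, so a reloaded checkpoint reproduces
# inference outputs bit for bit.

num_out <- function(x) {
  # full-precision numeric -> character; dim retained separately
  sprintf("%.17g", as.numeric(x))
}

mat_out <- function(m) {
  list(dim = dim(m), values = num_out(m))
}

mat_in <- function(obj) {
  d <- as.integer(unlist(obj$dim))
  matrix(as.numeric(unlist(obj$values)), d[1L], d[2L])
}

#' Save an MGCNN checkpoint
#'
#' Writes architecture, weights, atom alphabet, category names and training
#' configuration to a single JSON file at full numeric precision.
#'
#' @param checkpoint An `mgcnn_checkpoint` (from [train_mgcnn()]'s
#'   `$checkpoint`) or an `mgcnn_fit`.
#' @param path Output file path.
#' @export
write_checkpoint <- function(checkpoint, path) {
  if (inherits(checkpoint, "mgcnn_fit")) checkpoint <- checkpoint$checkpoint
  model <- checkpoint$model
  payload <- list(
    format = "mgcnn-checkpoint",
    version = checkpoint$version,
    alphabet = as.character(model$alphabet),
    categories = model$categories,
    n_stages = model$n_stages,
    stage_dims = model$stage_dims,
    use_bias = model$use_bias,
    stages = lapply(model$stages, function(w) {
      list(w_self = mat_out(w$w_self), w_neighbor = mat_out(w$w_neighbor),
           bias = num_out(w$bias))
    }),
    head = list(weights = mat_out(model$head$weights),
                bias = num_out(model$head$bias)),
    config = checkpoint$config[setdiff(names(checkpoint$config), "batch_size")],
    batch_size = checkpoint$config$batch_size
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load an MGCNN checkpoint
#'
#' @param path Path to a JSON file written by [write_checkpoint()].
#' @return An `mgcnn_checkpoint`.
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "mgcnn-checkpoint")) {
    format_error(sprintf("'%s' is not an mgcnn checkpoint", path))
  }
  obj$categories <- as.character(unlist(obj$categories))
  obj$alphabet <- as.character(unlist(obj$alphabet))
  obj$stage_dims <- as.integer(unlist(obj$stage_dims))
  stages <- lapply(seq_len(obj$n_stages), function(s) {
    st <- obj$stages[[s]]
    conv_stage_weights(mat_in(st$w_self), mat_in(st$w_neighbor),
                       as.numeric(unlist(st$bias)))
  })
  head <- classifier_head(mat_in(obj$head$weights),
                          as.numeric(unlist(obj$head$bias)),
                          obj$categories)
  model <- structure(
    list(alphabet = atom_alphabet(obj$alphabet),
         categories = obj$categories,
         n_stages = as.integer(obj$n_stages),
         stage_dims = as.integer(obj$stage_dims),
         use_bias = isTRUE(obj$use_bias),
         stages = stages, head = head),
    class = "mgcnn_model"
  )
  cfg_in <- obj$config
  cfg <- training_config(
    n_stages = as.integer(cfg_in$n_stages),
    stage_dims = as.integer(unlist(cfg_in$stage_dims)),
    epochs = as.integer(cfg_in$epochs),
    optimizer = as.character(cfg_in$optimizer),
    learning_rate = as.numeric(cfg_in$learning_rate),
    batch_size = if (is.null(obj$batch_size)) NULL else as.numeric(obj$batch_size),
    dropout_input = as.numeric(cfg_in$dropout_input),
    dropout_after_pool = as.numeric(cfg_in$dropout_after_pool),
    seed = as.integer(cfg_in$seed),
    loss_epsilon = as.numeric(cfg_in$loss_epsilon),
    use_bias = isTRUE(unlist(cfg_in$use_bias))
  )
  structure(list(version = as.integer(obj$version), model = model, config = cfg),
            class = "mgcnn_checkpoint")
}
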