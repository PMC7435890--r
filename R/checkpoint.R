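# Checkpoints are plain JSON with a versioned header, carrying everything
# needed to reproduce encodings exactly: the configuration, the ordered
# vocabulary, the initialisation seed, all parameter arrays and the training
# history.

CHECKPOINT_FORMAT <- "vaesim-checkpoint-1"

serialize_params <- function(p) {
  if (is.list(p)) return(lapply(p, serialize_params))
  list(dim = if (is.null(dim(p))) length(p) else dim(p),
       data = as.numeric(p))
}

deserialize_params <- function(p) {
  if (!is.list(p)) abort("malformed checkpoint parameters")
  if (identical(sort(names(p)), c("data", "dim"))) {
    d <- as.integer(unlist(p$dim))
    x <- as.numeric(unlist(p$data))
    if (length(d) == 1L) return(x)
    return(array(x, dim = d))
  }
  lapply(p, deserialize_params)
}

#' Save an autoencoder checkpoint
#'
#' @param vae A [smiles_vae()].
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(vae, path) {
  stopifnot(inherits(vae, "smiles_vae"))
  obj <- list(
    format = CHECKPOINT_FORMAT,
    config = unclass(vae$config),
    vocabulary = list(characters = vae$vocab$characters,
                      pad_char = vae$vocab$pad_char),
    seed = vae$seed,
    trained = vae$trained,
    history = vae$history,
    params = serialize_params(vae$params)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an autoencoder checkpoint
#'
#' @param path Path to a JSON checkpoint written by [save_checkpoint()].
#' @return A [smiles_vae()].
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, CHECKPOINT_FORMAT)) {
    abort(sprintf("unrecognised checkpoint format: %s",
                  obj$format %||% "<missing>"))
  }
  cfg_fields <- obj$config
  cfg <- vae_config(
    max_len = cfg_fields$max_len, vocab_size = cfg_fields$vocab_size,
    conv_channels = cfg_fields$conv_channels,
    conv_kernels = cfg_fields$conv_kernels,
    latent_dim = cfg_fields$latent_dim, gru_hidden = cfg_fields$gru_hidden,
    gru_layers = cfg_fields$gru_layers,
    learning_rate = cfg_fields$learning_rate,
    batch_size = cfg_fields$batch_size,
    orientation = cfg_fields$orientation, mask_pad = cfg_fields$mask_pad
  )
  vocab <- new_vocabulary(obj$vocabulary$characters, obj$vocabulary$pad_char)
  structure(
    list(config = cfg, vocab = vocab,
         params = deserialize_params(obj$params),
         seed = as.integer(obj$seed), trained = isTRUE(obj$trained),
         history = if (!is.null(obj$history)) as_tibble(obj$history)),
    class = "smiles_vae"
  )
}
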