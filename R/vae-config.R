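#' Architecture and training hyperparameters for the SMILES autoencoder
#'
#' Defaults are the full-scale published configuration: one-hot input of
#' 248 positions x 40 symbols, three 1-d convolutions (9/9/10 output channels,
#' kernels 9/9/11) with ReLU, a SeLU-activated fully connected bottleneck
#' branch feeding 100-dimensional mean and log-variance heads, and a decoder
#' of Linear + SeLU, a 3-layer GRU with 488 hidden units, and a linear/softmax
#' head; binary cross-entropy plus KL divergence loss, ADAM at learning rate
#' 1e-4, batch size 128, Xavier-uniform initialisation.
#'
#' Two axis conventions are supported.  `orientation = "paper"` treats the
#' 248 sequence positions as convolution channels and convolves along the
#' 40-symbol axis — the only reading under which the printed flatten size
#' (10 x 14 = 140) is consistent — and unrolls the decoder GRU over the
#' symbol axis with its per-step linear head emitting one score per sequence
#' position (softmax over positions).  `orientation = "conventional"` is the
#' standard sequence-model layout: convolve along the positions, unroll the
#' GRU over positions, softmax over symbols at each position.
#'
#' @param max_len Padded SMILES length.
#' @param vocab_size Number of vocabulary symbols (pad included).
#' @param conv_channels Integer vector (3): output channels per convolution.
#' @param conv_kernels Integer vector (3): kernel sizes.
#' @param latent_dim Dimension of the latent (bottleneck) vector.
#' @param gru_hidden GRU hidden-state size.
#' @param gru_layers Number of stacked GRU layers.
#' @param learning_rate ADAM learning rate.
#' @param batch_size Minibatch size.
#' @param orientation `"paper"` or `"conventional"` (see Details).
#' @param mask_pad If `TRUE`, pad positions are excluded from the
#'   reconstruction loss; off by default (no masking rule is part of the
#'   reference configuration).
#' @return A `vae_config` list with derived sizes `flatten_dim`,
#'   `conv_out_len`, `dec_steps` and `dec_head_out`.
#' @examples
#' cfg <- vae_config()
#' cfg$flatten_dim  # 140
#' @export
vae_config <- function(max_len = 248L,
                       vocab_size = 40L,
                       conv_channels = c(9L, 9L, 10L),
                       conv_kernels = c(9L, 9L, 11L),
                       latent_dim = 100L,
                       gru_hidden = 488L,
                       gru_layers = 3L,
                       learning_rate = 1e-4,
                       batch_size = 128L,
                       orientation = c("paper", "conventional"),
                       mask_pad = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(length(conv_channels) == 3L, length(conv_kernels) == 3L,
            all(conv_channels >= 1L), all(conv_kernels >= 1L),
            max_len >= 1L, vocab_size >= 2L, latent_dim >= 1L,
            gru_hidden >= 1L, gru_layers >= 1L,
            learning_rate >= 0, batch_size >= 1L)
  conv_axis_len <- if (orientation == "paper") vocab_size else max_len
  conv_out_len <- conv_axis_len - sum(conv_kernels - 1L)
  if (conv_out_len < 1L) {
    abort(sprintf(
      "convolution kernels (%s) do not fit the convolved axis (length %d)",
      paste(conv_kernels, collapse = "/"), conv_axis_len))
  }
  cfg <- list(
    max_len = as.integer(max_len),
    vocab_size = as.integer(vocab_size),
    conv_channels = as.integer(conv_channels),
    conv_kernels = as.integer(conv_kernels),
    latent_dim = as.integer(latent_dim),
    gru_hidden = as.integer(gru_hidden),
    gru_layers = as.integer(gru_layers),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    orientation = orientation,
    mask_pad = isTRUE(mask_pad),
    init_scheme = "xavier_uniform",
    encoder_activation = "relu",
    latent_activation = "selu",
    flatten_dim = as.integer(conv_channels[3] * conv_out_len),
    conv_out_len = as.integer(conv_out_len),
    dec_steps = as.integer(if (orientation == "paper") vocab_size else max_len),
    dec_head_out = as.integer(if (orientation == "paper") max_len else vocab_size)
  )
  structure(cfg, class = "vae_config")
}

#' Reduced configuration for desk-scale experiments
#'
#' A small model over short synthetic molecules: padded length 24, latent
#' dimension 16, light convolutions (kernels 3/3/3) and a single 64-unit GRU
#' layer in the conventional orientation, which at this scale trains to
#' high-validity reconstructions in minutes on one CPU.  The learning rate is
#' raised to 2e-3, appropriate for the much smaller parameter count.
#'
#' @param vocab_size Vocabulary size of the training corpus.
#' @param ... Overrides passed on to [vae_config()].
#' @return A `vae_config`.
#' @export
reduced_vae_config <- function(vocab_size, ...) {
  defaults <- list(max_len = 24L, vocab_size = as.integer(vocab_size),
                   conv_channels = c(8L, 8L, 10L), conv_kernels = c(3L, 3L, 3L),
                   latent_dim = 16L, gru_hidden = 64L, gru_layers = 1L,
                   learning_rate = 2e-3, batch_size = 128L,
                   orientation = "conventional")
  do.call(vae_config, utils::modifyList(defaults, list(...)))
}

#' @export
print.vae_config <- function(x, ...) {
  cat(sprintf(
    paste0("<vae_config> %d x %d one-hot -> conv(%s; k=%s) -> flatten %d",
           " -> latent %d -> GRU %dx%d -> %d (%s orientation)\n"),
    x$max_len, x$vocab_size,
    paste(x$conv_channels, collapse = "/"),
    paste(x$conv_kernels, collapse = "/"),
    x$flatten_dim, x$latent_dim, x$gru_layers, x$gru_hidden,
    x$dec_head_out, x$orientation))
  invisible(x)
}
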