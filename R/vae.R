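# The variational autoencoder: parameter initialisation, batched forward
# passes for encoder and decoder, the BCE+KL loss, and the joint
# forward/backward pass used by the trainer.  All maths is hand-rolled on the
# layer library in nn.R; the backward pass is verified against central finite
# differences in the test suite.

init_vae_params <- function(cfg) {
  in_ch <- if (cfg$orientation == "paper") cfg$max_len else cfg$vocab_size
  ch <- cfg$conv_channels
  k <- cfg$conv_kernels
  H <- cfg$gru_hidden
  gru <- vector("list", cfg$gru_layers)
  for (l in seq_len(cfg$gru_layers)) {
    gru[[l]] <- gru_init(if (l == 1L) cfg$latent_dim else H, H)
  }
  names(gru) <- paste0("layer", seq_len(cfg$gru_layers))
  list(
    conv1 = list(W = xavier_uniform(k[1] * in_ch, ch[1],
                                    c(k[1] * in_ch, ch[1])),
                 b = numeric(ch[1])),
    conv2 = list(W = xavier_uniform(k[2] * ch[1], ch[2],
                                    c(k[2] * ch[1], ch[2])),
                 b = numeric(ch[2])),
    conv3 = list(W = xavier_uniform(k[3] * ch[2], ch[3],
                                    c(k[3] * ch[2], ch[3])),
                 b = numeric(ch[3])),
    enc_fc = list(W = xavier_uniform(cfg$flatten_dim, cfg$latent_dim),
                  b = numeric(cfg$latent_dim)),
    enc_mu = list(W = xavier_uniform(cfg$latent_dim, cfg$latent_dim),
                  b = numeric(cfg$latent_dim)),
    enc_logvar = list(W = xavier_uniform(cfg$latent_dim, cfg$latent_dim),
                      b = numeric(cfg$latent_dim)),
    dec_fc = list(W = xavier_uniform(cfg$latent_dim, cfg$latent_dim),
                  b = numeric(cfg$latent_dim)),
    gru = gru,
    head = list(W = xavier_uniform(H, cfg$dec_head_out),
                b = numeric(cfg$dec_head_out))
  )
}

#' Create an untrained SMILES variational autoencoder
#'
#' Parameters are drawn Xavier-uniform under the given seed, so a model is a
#' pure function of `(vocab, config, seed)`.
#'
#' @param vocab A `smiles_vocabulary`; its size must match
#'   `config$vocab_size`.
#' @param config A [vae_config()]; defaults to the reduced desk-scale
#'   configuration for the given vocabulary.
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `smiles_vae`.
#' @export
smiles_vae <- function(vocab, config = reduced_vae_config(vocab$size),
                       seed = 1L) {
  stopifnot(inherits(vocab, "smiles_vocabulary"),
            inherits(config, "vae_config"))
  if (config$vocab_size != vocab$size) {
    abort(sprintf("config expects %d symbols but vocabulary has %d",
                  config$vocab_size, vocab$size))
  }
  params <- with_local_seed(seed, init_vae_params(config))
  structure(
    list(config = config, vocab = vocab, params = params,
         seed = as.integer(seed), trained = FALSE, history = NULL),
    class = "smiles_vae"
  )
}

#' @export
print.smiles_vae <- function(x, ...) {
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<smiles_vae> %s, %s parameters (seed %d)\n",
              if (x$trained) "trained" else "untrained",
              format(n_par, big.mark = ","), x$seed))
  print(x$config)
  invisible(x)
}

## ---- batched internals ----

vae_encoder_fwd <- function(cfg, params, X) {
  # X: (B, max_len, vocab_size)
  Xc <- if (cfg$orientation == "paper") aperm(X, c(1L, 3L, 2L)) else X
  c1 <- conv1d_fwd(Xc, params$conv1$W, params$conv1$b); a1 <- relu_fwd(c1$out)
  c2 <- conv1d_fwd(a1, params$conv2$W, params$conv2$b); a2 <- relu_fwd(c2$out)
  c3 <- conv1d_fwd(a2, params$conv3$W, params$conv3$b); a3 <- relu_fwd(c3$out)
  B <- dim(X)[1]
  flat <- a3
  dim(flat) <- c(B, cfg$flatten_dim)
  fc <- linear_fwd(flat, params$enc_fc$W, params$enc_fc$b)
  h <- selu_fwd(fc$out)
  mu_l <- linear_fwd(h, params$enc_mu$W, params$enc_mu$b)
  lv_l <- linear_fwd(h, params$enc_logvar$W, params$enc_logvar$b)
  list(mu = mu_l$out, logvar = lv_l$out,
       cache = list(c1 = c1, c2 = c2, c3 = c3, fc = fc,
                    mu_l = mu_l, lv_l = lv_l, B = B))
}

vae_encoder_bwd <- function(cfg, params, cache, dmu, dlogvar) {
  g_mu <- linear_bwd(cache$mu_l, params$enc_mu$W, dmu)
  g_lv <- linear_bwd(cache$lv_l, params$enc_logvar$W, dlogvar)
  dh <- g_mu$dx + g_lv$dx
  dfc_out <- selu_bwd(cache$fc$out, dh)
  g_fc <- linear_bwd(cache$fc, params$enc_fc$W, dfc_out)
  dflat <- g_fc$dx
  dim(dflat) <- c(cache$B, cfg$conv_out_len, cfg$conv_channels[3])
  d3 <- relu_bwd(cache$c3$out, dflat)
  g3 <- conv1d_bwd(cache$c3, params$conv3$W, d3)
  d2 <- relu_bwd(cache$c2$out, g3$dx)
  g2 <- conv1d_bwd(cache$c2, params$conv2$W, d2)
  d1 <- relu_bwd(cache$c1$out, g2$dx)
  g1 <- conv1d_bwd(cache$c1, params$conv1$W, d1)
  list(conv1 = list(W = g1$dW, b = g1$db),
       conv2 = list(W = g2$dW, b = g2$db),
       conv3 = list(W = g3$dW, b = g3$db),
       enc_fc = list(W = g_fc$dW, b = g_fc$db),
       enc_mu = list(W = g_mu$dW, b = g_mu$db),
       enc_logvar = list(W = g_lv$dW, b = g_lv$db))
}

vae_decoder_fwd <- function(cfg, params, Z) {
  B <- nrow(Z)
  fc <- linear_fwd(Z, params$dec_fc$W, params$dec_fc$b)
  u <- selu_fwd(fc$out)
  Tt <- cfg$dec_steps
  xin <- array(0, dim = c(B, Tt, cfg$latent_dim))
  for (t in seq_len(Tt)) xin[, t, ] <- u
  gs <- gru_stack_fwd(xin, params$gru)
  hseq <- gs$out
  dim(hseq) <- c(B * Tt, cfg$gru_hidden)
  hd <- linear_fwd(hseq, params$head$W, params$head$b)
  probs_flat <- softmax_rows(hd$out)
  probs <- probs_flat
  dim(probs) <- c(B, Tt, cfg$dec_head_out)
  if (cfg$orientation == "paper") probs <- aperm(probs, c(1L, 3L, 2L))
  list(probs = probs,
       cache = list(fc = fc, gs = gs, hd = hd, probs_flat = probs_flat,
                    B = B, Tt = Tt))
}

vae_decoder_bwd <- function(cfg, params, cache, dprobs) {
  B <- cache$B; Tt <- cache$Tt
  if (cfg$orientation == "paper") dprobs <- aperm(dprobs, c(1L, 3L, 2L))
  dim(dprobs) <- c(B * Tt, cfg$dec_head_out)
  dlogits <- softmax_rows_bwd(cache$probs_flat, dprobs)
  g_hd <- linear_bwd(cache$hd, params$head$W, dlogits)
  dhseq <- g_hd$dx
  dim(dhseq) <- c(B, Tt, cfg$gru_hidden)
  g_gru <- gru_stack_bwd(cache$gs, params$gru, dhseq)
  du <- apply(g_gru$dx, c(1L, 3L), sum)          # sum over the repeated steps
  dfc_out <- selu_bwd(cache$fc$out, du)
  g_fc <- linear_bwd(cache$fc, params$dec_fc$W, dfc_out)
  gru_grads <- lapply(g_gru$grads, function(g) {
    list(Wi = g$dWi, Wh = g$dWh, bi = g$dbi, bh = g$dbh)
  })
  names(gru_grads) <- names(params$gru)
  list(grads = list(dec_fc = list(W = g_fc$dW, b = g_fc$db),
                    gru = gru_grads,
                    head = list(W = g_hd$dW, b = g_hd$db)),
       dZ = g_fc$dx)
}

# Loss mask: 1 everywhere, or 0 on pad rows when cfg$mask_pad.
loss_mask <- function(cfg, target, pad_col) {
  if (!cfg$mask_pad) return(NULL)
  is_pad <- as.vector(target[, , pad_col] == 1)      # length B*L
  w <- array(1, dim = dim(target))
  w[rep(is_pad, times = dim(target)[3])] <- 0        # zero all symbols of pad rows
  w
}

# One training step: loss and full gradient for a minibatch.
vae_forward_backward <- function(cfg, params, X, eps, pad_col) {
  B <- dim(X)[1]
  enc <- vae_encoder_fwd(cfg, params, X)
  sd_ <- exp(0.5 * enc$logvar)
  Z <- enc$mu + sd_ * eps
  dec <- vae_decoder_fwd(cfg, params, Z)
  w <- loss_mask(cfg, X, pad_col)
  p <- pmin(pmax(dec$probs, BCE_EPS), 1 - BCE_EPS)
  bce_terms <- -(X * log(p) + (1 - X) * log(1 - p))
  if (!is.null(w)) bce_terms <- bce_terms * w
  bce <- sum(bce_terms)
  kl <- kl_standard_normal(enc$mu, enc$logvar)
  loss <- (bce + kl) / B

  dprobs <- (p - X) / (p * (1 - p))
  if (!is.null(w)) dprobs <- dprobs * w
  dprobs <- dprobs / B
  decb <- vae_decoder_bwd(cfg, params, dec$cache, dprobs)
  dZ <- decb$dZ
  dmu <- dZ + enc$mu / B
  dlogvar <- dZ * eps * 0.5 * sd_ + 0.5 * (exp(enc$logvar) - 1) / B
  encg <- vae_encoder_bwd(cfg, params, enc$cache, dmu, dlogvar)
  grads <- c(encg, decb$grads)
  grads <- grads[names(params)]
  list(loss = loss, bce = bce / B, kl = kl / B, grads = grads)
}

## ---- user-facing single-input operations ----

#' Encoder forward pass
#'
#' Maps a one-hot encoded SMILES matrix to the Gaussian posterior over the
#' latent space.
#'
#' @param vae A [smiles_vae()].
#' @param onehot Matrix of shape `(max_len, vocab_size)` from
#'   [encode_one_hot()].
#' @return A `latent_posterior` list with numeric vectors `mu` and `logvar`,
#'   each of length `latent_dim`.
#' @export
encoder_forward <- function(vae, onehot) {
  stopifnot(inherits(vae, "smiles_vae"), is.matrix(onehot))
  cfg <- vae$config
  if (!all(dim(onehot) == c(cfg$max_len, cfg$vocab_size))) {
    abort(sprintf("expected a %d x %d matrix, got %d x %d",
                  cfg$max_len, cfg$vocab_size, nrow(onehot), ncol(onehot)))
  }
  X <- array(onehot, dim = c(1L, dim(onehot)))
  enc <- vae_encoder_fwd(cfg, vae$params, X)
  structure(list(mu = drop(enc$mu), logvar = drop(enc$logvar)),
            class = "latent_posterior")
}

#' Sample a latent vector with the reparameterization trick
#'
#' `z = mu + exp(logvar / 2) * eps` with `eps ~ N(0, I)`.  With a fixed seed
#' the draw is reproducible; in the zero-variance limit `z == mu`.
#'
#' @param posterior A `latent_posterior` from [encoder_forward()].
#' @param seed Optional integer seed for the draw.
#' @return Numeric latent vector of length `latent_dim`.
#' @export
reparameterize <- function(posterior, seed = NULL) {
  stopifnot(inherits(posterior, "latent_posterior"))
  eps <- if (is.null(seed)) {
    rnorm(length(posterior$mu))
  } else {
    with_local_seed(seed, rnorm(length(posterior$mu)))
  }
  posterior$mu + exp(0.5 * posterior$logvar) * eps
}

#' Decoder forward pass
#'
#' Maps a latent vector to per-position symbol scores; the output is a
#' non-negative `(max_len, vocab_size)` matrix whose softmax-normalised axis
#' depends on the configured orientation.  The decoder is deterministic given
#' `z` and the parameters.
#'
#' @param vae A [smiles_vae()].
#' @param z Numeric latent vector of length `latent_dim`.
#' @return Numeric matrix `(max_len, vocab_size)` suitable for
#'   [decode_one_hot()].
#' @export
decoder_forward <- function(vae, z) {
  stopifnot(inherits(vae, "smiles_vae"))
  cfg <- vae$config
  if (length(z) != cfg$latent_dim) {
    abort(sprintf("latent vector has length %d, expected %d",
                  length(z), cfg$latent_dim))
  }
  dec <- vae_decoder_fwd(cfg, vae$params, matrix(z, nrow = 1L))
  matrix(dec$probs[1L, , ], nrow = cfg$max_len,
         dimnames = list(NULL, vae$vocab$characters))
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `-0.5 * sum(1 + logvar - mu^2 - exp(logvar))`.
#'
#' @param mu,logvar Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @examples
#' kl_divergence(rep(0, 100), rep(0, 100))      # 0
#' kl_divergence(c(1, rep(0, 99)), rep(0, 100)) # 0.5
#' @export
kl_divergence <- function(mu, logvar) {
  stopifnot(length(mu) == length(logvar))
  kl_standard_normal(mu, logvar)
}

#' Autoencoder loss: binary cross-entropy plus KL divergence
#'
#' @param probs Decoder output matrix `(max_len, vocab_size)` with entries in
#'   `(0, 1)` (clamped at `1e-7` before the logs).
#' @param target One-hot target matrix of the same shape.
#' @param posterior A `latent_posterior`.
#' @return Scalar loss, with components attached as attributes `bce` and
#'   `kl`.
#' @export
vae_loss <- function(probs, target, posterior) {
  stopifnot(all(dim(probs) == dim(target)),
            inherits(posterior, "latent_posterior"))
  if (any(probs < 0) || any(probs > 1)) {
    abort("probs must lie in [0, 1]")
  }
  bce <- bce_sum(probs, target)
  kl <- kl_standard_normal(posterior$mu, posterior$logvar)
  structure(bce + kl, bce = bce, kl = kl)
}

## ---- batched embedding / reconstruction ----

#' Latent embeddings for a set of molecules
#'
#' Encodes each SMILES and returns the posterior mean `mu` as the molecule's
#' deterministic latent representation (no sampling), the representation used
#' for all similarity work.
#'
#' @param vae A [smiles_vae()].
#' @param smiles Character vector of SMILES, or a tibble with `id` and
#'   `smiles` columns.
#' @param ids Optional identifiers (defaults to the SMILES themselves).
#' @return An embedding tibble: column `id` plus `latent_dim` numeric columns
#'   `d1..dK`, with attribute `normalization = "none"`.
#' @export
encode_latent <- function(vae, smiles, ids = NULL) {
  stopifnot(inherits(vae, "smiles_vae"))
  if (is.data.frame(smiles)) {
    ids <- ids %||% smiles$id
    smiles <- smiles$smiles
  }
  ids <- ids %||% smiles
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  cfg <- vae$config
  n <- length(smiles)
  out <- matrix(0, n, cfg$latent_dim)
  for (start in seq(1L, n, by = 256L)) {
    idx <- start:min(start + 255L, n)
    X <- encode_batch(smiles[idx], vae$vocab, cfg$max_len)
    out[idx, ] <- vae_encoder_fwd(cfg, vae$params, X)$mu
  }
  colnames(out) <- paste0("d", seq_len(cfg$latent_dim))
  emb <- dplyr::bind_cols(tibble(id = ids), as_tibble(out))
  attr(emb, "normalization") <- "none"
  emb
}

#' Reconstruct molecules through the autoencoder
#'
#' Encode to the posterior mean, decode, and read off the argmax SMILES.
#' Deterministic given the model.
#'
#' @param vae A [smiles_vae()].
#' @param smiles Character vector of SMILES.
#' @return Character vector of decoded SMILES strings.
#' @export
reconstruct_smiles <- function(vae, smiles) {
  stopifnot(inherits(vae, "smiles_vae"))
  cfg <- vae$config
  n <- length(smiles)
  out <- character(n)
  for (start in seq(1L, n, by = 256L)) {
    idx <- start:min(start + 255L, n)
    X <- encode_batch(smiles[idx], vae$vocab, cfg$max_len)
    mu <- vae_encoder_fwd(cfg, vae$params, X)$mu
    dec <- vae_decoder_fwd(cfg, vae$params, mu)
    out[idx] <- decode_batch(dec$probs, vae$vocab)
  }
  out
}
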