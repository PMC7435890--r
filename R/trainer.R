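#' Partition records into training, validation and test sets
#'
#' The reference protocol splits the corpus 50/20/30.  Sizes are the floors
#' of the fractions with the remainder assigned to the last (test) partition,
#' which reproduces the published counts: 6,202,415 records split 50/20/30
#' give 3,101,207 / 1,240,483 / 1,860,725.  Shuffling is a pure function of
#' the seed; the three parts are disjoint and cover the input.
#'
#' @param records A vector or data frame of records.
#' @param fractions Named numeric vector of three positive fractions summing
#'   to 1, in order train, validation, test.
#' @param seed Integer shuffling seed.
#' @return Named list `train`, `validation`, `test` of the same type as
#'   `records`.
#' @export
partition_dataset <- function(records,
                              fractions = c(train = 0.5, validation = 0.2,
                                            test = 0.3),
                              seed = 1L) {
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n < 3L) abort("need at least 3 records to partition")
  stopifnot(length(fractions) == 3L, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  sizes <- partition_sizes(n, fractions)
  perm <- with_local_seed(seed, sample.int(n))
  idx <- split(perm, factor(rep(1:3, times = sizes), levels = 1:3))
  take <- function(i) {
    if (is.data.frame(records)) records[i, , drop = FALSE] else records[i]
  }
  list(train = take(idx[[1]]), validation = take(idx[[2]]),
       test = take(idx[[3]]))
}

partition_sizes <- function(n, fractions) {
  head_sizes <- floor(fractions[-length(fractions)] * n)
  c(head_sizes, n - sum(head_sizes))
}

#' Train the autoencoder with ADAM
#'
#' Minibatch gradient descent on the summed-per-molecule BCE+KL loss (averaged
#' over the batch), ADAM at the configured learning rate, fresh reparameterized
#' noise per batch.  When a validation set is supplied, training stops early
#' once validation loss has failed to improve for `patience` consecutive
#' epochs and the best-validation parameters are restored; without one it
#' runs for exactly `epochs` epochs.  The whole run is a pure function of the
#' model and `seed`; a non-finite loss aborts with a diagnostic.
#'
#' @param vae An untrained (or previously trained) [smiles_vae()].
#' @param train_smiles Character vector of training SMILES.
#' @param val_smiles Optional character vector for validation.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs (used only with a
#'   validation set).
#' @param seed Integer seed for shuffling and reparameterization noise.
#' @param verbose Print a line per epoch.
#' @return The trained `smiles_vae`, with a `history` tibble of per-epoch
#'   losses (`epoch`, `train_loss`, `val_loss`).
#' @export
train_vae <- function(vae, train_smiles, val_smiles = NULL,
                      epochs = 30L, patience = 5L, seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(vae, "smiles_vae"), length(train_smiles) >= 1L)
  cfg <- vae$config
  pad_col <- unname(vae$vocab$index_of[vae$vocab$pad_char]) + 1L
  X_all <- encode_batch(train_smiles, vae$vocab, cfg$max_len)
  X_val <- if (!is.null(val_smiles)) {
    encode_batch(val_smiles, vae$vocab, cfg$max_len)
  }
  n <- dim(X_all)[1]
  params <- vae$params
  opt <- adam_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  wait <- 0L
  hist <- vector("list", epochs)

  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        Xb <- X_all[idx, , , drop = FALSE]
        eps <- matrix(rnorm(length(idx) * cfg$latent_dim),
                      nrow = length(idx))
        step <- vae_forward_backward(cfg, params, Xb, eps, pad_col)
        if (!is.finite(step$loss)) {
          abort(sprintf(
            "non-finite loss at epoch %d (batch starting %d); lower the learning rate",
            ep, s))
        }
        ep_loss <- ep_loss + step$loss * length(idx)
        if (cfg$learning_rate > 0) {
          upd <- adam_step(params, step$grads, opt, cfg$learning_rate)
          params <- upd$params
          opt <- upd$state
        }
      }
      train_loss <- ep_loss / n
      val_loss <- NA_real_
      if (!is.null(X_val)) {
        val_loss <- vae_eval_loss(cfg, params, X_val, pad_col)
        if (val_loss < best$val - 1e-9) {
          best <- list(val = val_loss, params = params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      hist[[ep]] <- tibble(epoch = ep, train_loss = train_loss,
                           val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %s", ep, train_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
      }
      if (!is.null(X_val) && wait >= patience) break
    }
  })

  if (!is.null(X_val) && is.finite(best$val)) params <- best$params
  vae$params <- params
  vae$trained <- TRUE
  vae$history <- dplyr::bind_rows(hist)
  vae
}

# Deterministic (mu-based, no sampling) loss on a held-out tensor.
vae_eval_loss <- function(cfg, params, X, pad_col) {
  n <- dim(X)[1]
  total <- 0
  for (s in seq(1L, n, by = 256L)) {
    idx <- s:min(s + 255L, n)
    Xb <- X[idx, , , drop = FALSE]
    enc <- vae_encoder_fwd(cfg, params, Xb)
    dec <- vae_decoder_fwd(cfg, params, enc$mu)
    w <- loss_mask(cfg, Xb, pad_col)
    p <- pmin(pmax(dec$probs, BCE_EPS), 1 - BCE_EPS)
    terms <- -(Xb * log(p) + (1 - Xb) * log(1 - p))
    if (!is.null(w)) terms <- terms * w
    total <- total + sum(terms) + kl_standard_normal(enc$mu, enc$logvar)
  }
  total / n
}

#' Reconstruction-accuracy report
#'
#' Runs every molecule through encode (posterior mean) / decode / argmax and
#' classifies each output as `perfect` (same molecule after
#' canonicalization), `good` (legal SMILES, different molecule) or `invalid`.
#' `accuracy_valid_pct` counts outputs that are legal SMILES
#' (perfect + good); `accuracy_perfect_pct` counts exact reconstructions.
#' Both are reported because published "accuracy" figures for this protocol
#' are stated in terms of valid reconstructed samples.
#'
#' @param vae A trained [smiles_vae()].
#' @param smiles Character vector of valid SMILES to evaluate.
#' @return A one-row tibble: `total`, `valid`, `perfect`, `good`, `invalid`,
#'   `accuracy_valid_pct`, `accuracy_perfect_pct`.
#' @export
evaluate_reconstruction <- function(vae, smiles) {
  decoded <- reconstruct_smiles(vae, smiles)
  cls <- classify_output(smiles, decoded)
  total <- length(smiles)
  perfect <- sum(cls == "perfect")
  good <- sum(cls == "good")
  invalid <- sum(cls == "invalid")
  tibble(
    total = total, valid = perfect + good, perfect = perfect, good = good,
    invalid = invalid,
    accuracy_valid_pct = 100 * (perfect + good) / total,
    accuracy_perfect_pct = 100 * perfect / total
  )
}
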