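#' One-hot encode a SMILES string
#'
#' Produces the fixed-size binary matrix consumed by the autoencoder: one row
#' per sequence position up to `max_len`, one column per vocabulary symbol.
#' Positions beyond the string length are one-hot on the pad character, so
#' every row sums to exactly 1.  The paper-scale configuration uses
#' `max_len = 248` and a 40-symbol vocabulary.
#'
#' @param smiles A single SMILES string (may be empty).
#' @param vocab A `smiles_vocabulary`.
#' @param max_len Maximum (padded) sequence length.
#' @return A binary matrix of dimension `max_len x vocab$size`.
#' @export
encode_one_hot <- function(smiles, vocab, max_len = 248L) {
  stopifnot(is.character(smiles), length(smiles) == 1L,
            inherits(vocab, "smiles_vocabulary"))
  if (nchar(smiles) > max_len) {
    abort(sprintf("SMILES of length %d exceeds max_len %d",
                  nchar(smiles), max_len))
  }
  idx <- vocab_indices(smiles, vocab)
  pad_idx <- unname(vocab$index_of[vocab$pad_char])
  full <- c(idx, rep(pad_idx, max_len - length(idx)))
  m <- matrix(0L, nrow = max_len, ncol = vocab$size,
              dimnames = list(NULL, vocab$characters))
  m[cbind(seq_len(max_len), full + 1L)] <- 1L
  m
}

#' Decode per-position symbol scores back to a SMILES string
#'
#' Inverse of [encode_one_hot()] generalized to real-valued scores such as the
#' decoder's per-position distributions: each row is decoded to its argmax
#' character (ties broken by the lowest vocabulary index) and trailing pad
#' characters are stripped.
#'
#' @param probs Numeric matrix of shape `(max_len, vocab$size)` with
#'   non-negative entries.
#' @param vocab A `smiles_vocabulary`.
#' @return A single SMILES string (possibly empty).
#' @export
decode_one_hot <- function(probs, vocab) {
  stopifnot(is.matrix(probs), inherits(vocab, "smiles_vocabulary"))
  if (ncol(probs) != vocab$size) {
    abort(sprintf("matrix has %d columns but vocabulary has %d characters",
                  ncol(probs), vocab$size))
  }
  if (any(probs < 0)) abort("decode_one_hot: negative entries")
  # max.col breaks ties at random; enforce the lowest-index rule directly
  best <- apply(probs, 1L, which.max)
  chars <- vocab$characters[best]
  s <- paste(chars, collapse = "")
  sub(paste0("[", gsub("([][\\^-])", "\\\\\\1", vocab$pad_char), "]+$"), "", s)
}

# Encode a corpus into the (batch, position, symbol) array used in training.
encode_batch <- function(smiles, vocab, max_len) {
  n <- length(smiles)
  arr <- array(0, dim = c(n, max_len, vocab$size))
  pad_idx <- unname(vocab$index_of[vocab$pad_char])
  for (i in seq_len(n)) {
    idx <- vocab_indices(smiles[[i]], vocab)
    if (length(idx) > max_len) {
      abort(sprintf("SMILES #%d exceeds max_len %d", i, max_len))
    }
    full <- c(idx, rep(pad_idx, max_len - length(idx)))
    arr[cbind(i, seq_len(max_len), full + 1L)] <- 1
  }
  arr
}

decode_batch <- function(probs, vocab) {
  # probs: array (batch, max_len, vocab_size)
  vapply(seq_len(dim(probs)[1]), function(i) {
    decode_one_hot(matrix(probs[i, , ], nrow = dim(probs)[2]), vocab)
  }, character(1))
}
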