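#' Build a character vocabulary from a SMILES corpus
#'
#' Tokenization is strictly character-level: two-letter element symbols such
#' as `Cl` contribute the two characters `C` and `l`.  The vocabulary is the
#' lexicographically sorted set of all characters occurring in the corpus plus
#' a pad character, so encodings are reproducible for any corpus ordering.
#' On the full drug-like training corpus this comes to 40 distinct symbols
#' (pad included); the size is corpus-driven, not a constant.
#'
#' @param corpus Character vector of SMILES strings (non-empty).
#' @param pad_char Single padding character, by default a space (which cannot
#'   occur inside a SMILES string).
#' @return An object of class `smiles_vocabulary`: a list with elements
#'   `characters` (ordered character vector), `index_of` (named integer map,
#'   0-based), `pad_char` and `size`.
#' @examples
#' \dontrun{
#' v <- build_vocabulary(c("CCO", "CN"))
#' v$size  # 4: " " "C" "N" "O"
#' }
#' @export
build_vocabulary <- function(corpus, pad_char = " ") {
  if (length(corpus) == 0L) abort("build_vocabulary: empty corpus")
  if (any(!nzchar(corpus)) || anyNA(corpus)) {
    abort("build_vocabulary: corpus contains empty or missing strings")
  }
  stopifnot(is.character(pad_char), nchar(pad_char) == 1L)
  chars <- sort(unique(c(pad_char, unlist(strsplit(corpus, "", fixed = TRUE)))),
                method = "radix")
  new_vocabulary(chars, pad_char)
}

new_vocabulary <- function(characters, pad_char) {
  stopifnot(!anyDuplicated(characters), pad_char %in% characters)
  idx <- stats::setNames(seq_along(characters) - 1L, characters)
  structure(
    list(characters = characters, index_of = idx,
         pad_char = pad_char, size = length(characters)),
    class = "smiles_vocabulary"
  )
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat(sprintf("<smiles_vocabulary> %d characters (pad = %s)\n", x$size,
              deparse(x$pad_char)))
  cat(" ", paste(vapply(x$characters, deparse, ""), collapse = " "), "\n")
  invisible(x)
}

vocab_indices <- function(smiles, vocab) {
  if (nchar(smiles) == 0L) return(integer(0))
  ch <- strsplit(smiles, "", fixed = TRUE)[[1]]
  unknown <- setdiff(ch, vocab$characters)
  if (length(unknown) > 0L) {
    abort(sprintf("character(s) not in vocabulary: %s",
                  paste(vapply(unknown, deparse, ""), collapse = ", ")))
  }
  unname(vocab$index_of[ch])
}
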