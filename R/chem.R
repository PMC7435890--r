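#' Canonicalize SMILES strings
#'
#' Parses each string with the cheminformatics toolkit and returns its
#' canonical SMILES.  Unparsable strings yield `NA` rather than an error, so
#' the function doubles as a validity filter: `!is.na(canonicalize(x))` counts
#' legal SMILES.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of the same length; canonical SMILES, `NA` where
#'   the input is not legal SMILES.
#' @examples
#' \dontrun{
#' canonicalize(c("OCC", "CCO", "C1CC"))  # first two agree, third is NA
#' }
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  if (anyNA(smiles)) {
    out <- rep(NA_character_, length(smiles))
    ok <- !is.na(smiles)
    out[ok] <- canonicalize(smiles[ok])
    return(out)
  }
  if (any(grepl("[\n\r]", smiles))) {
    abort("SMILES strings must not contain newlines")
  }
  res <- run_chem_tool("canon", input = smiles)
  # a trailing empty line is dropped by system2; pad back
  if (length(res) < length(smiles)) {
    res <- c(res, rep("", length(smiles) - length(res)))
  }
  res[res == ""] <- NA_character_
  res
}

#' Test whether strings are legal SMILES
#'
#' @param smiles Character vector.
#' @return Logical vector: `TRUE` where the string parses as a molecule.
#' @export
smiles_is_valid <- function(smiles) {
  !is.na(canonicalize(smiles))
}

#' Classify decoded SMILES against their inputs
#'
#' An autoencoder run on a SMILES string can return three kinds of output:
#' a string denoting the *same* molecule as the input (`"perfect"`, compared
#' after canonicalization so any legal spelling counts), a legal SMILES for a
#' *different* molecule (`"good"`), or a string that is not legal SMILES at
#' all (`"invalid"`).  The three classes partition all possible outputs.
#'
#' @param input_smiles Character vector of (valid) input SMILES.
#' @param output_smiles Character vector of decoded outputs, same length.
#' @return Character vector with values `"perfect"`, `"good"` or `"invalid"`.
#' @examples
#' \dontrun{
#' classify_output("CCO", c("OCC", "CCN", "C1CC"))
#' #> "perfect" "good" "invalid"
#' }
#' @export
classify_output <- function(input_smiles, output_smiles) {
  if (length(input_smiles) == 1L) {
    input_smiles <- rep(input_smiles, length(output_smiles))
  }
  stopifnot(length(input_smiles) == length(output_smiles))
  n <- length(output_smiles)
  canon <- canonicalize(c(input_smiles, output_smiles))
  can_in <- canon[seq_len(n)]
  can_out <- canon[n + seq_len(n)]
  if (anyNA(can_in)) {
    abort("classify_output: some input SMILES are themselves invalid")
  }
  out <- rep("invalid", n)
  valid <- !is.na(can_out)
  out[valid] <- ifelse(can_out[valid] == can_in[valid], "perfect", "good")
  out
}
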