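# Bridge to the bundled Python helper (RDKit + umap-learn).  Everything is
# batched through a single subprocess per call: spawning the interpreter costs
# ~1 s, so callers pass vectors, never loop over single molecules.

vaesim_python <- function() {
  py <- Sys.getenv("VAESIM_PYTHON", unset = "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) {
    abort("No python interpreter found; set VAESIM_PYTHON or add python to PATH.")
  }
  py
}

chem_tool <- function() {
  system.file("python", "vaesim_tools.py", package = "vaesim", mustWork = TRUE)
}

run_chem_tool <- function(args, input = NULL) {
  out <- suppressWarnings(system2(
    vaesim_python(), c(shQuote(chem_tool()), args),
    stdout = TRUE, stderr = FALSE, input = input
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort(sprintf("chemistry helper failed (subcommand '%s', exit %d)",
                  args[[1]], status))
  }
  out
}

#' Version of the chemistry toolkit backing canonicalization and fingerprints
#'
#' Returned as a string (e.g. `"2024.09.2"`) and recorded in fingerprint and
#' baseline-table outputs so that toolkit-version-sensitive values (notably the
#' Pattern, Avalon and Layered fingerprints) are interpretable later.
#'
#' @return A single character string.
#' @export
rdkit_version <- function() {
  run_chem_tool("version")[[1]]
}
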