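# Shared fixtures, built once per test run.  Everything is generated in code
# under fixed seeds; nothing is read from disk.

# A small synthetic corpus reused across codec / trainer / similarity tests.
test_corpus <- local({
  val <- NULL
  function(n = 300, seed = 101) {
    if (is.null(val)) {
      val <<- generate_synthetic_smiles(synthetic_spec(n, seed = seed))
    }
    val
  }
})

# A tiny untrained model over a fixed alphabet, cheap to build everywhere.
tiny_vae <- function(seed = 7, ...) {
  vocab <- build_vocabulary(c("CCO", "CCN", "CC(C)O", "C1CCCC1", "CS", "CF"))
  smiles_vae(vocab, reduced_vae_config(vocab$size, ...), seed = seed)
}

# Deterministic pseudo-embedding tibble: n points in d dimensions.
fake_embedding <- function(n, d = 4, seed = 1, prefix = "m") {
  m <- vaesim:::with_local_seed(seed, matrix(rnorm(n * d), n, d))
  colnames(m) <- paste0("d", seq_len(d))
  dplyr::bind_cols(tibble::tibble(id = sprintf("%s%03d", prefix, seq_len(n))),
                   tibble::as_tibble(m))
}
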