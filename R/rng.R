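# Evaluate code under a temporary RNG state so that seeded operations are
# reproducible without clobbering the caller's random stream.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# sample() treats a length-1 numeric vector as 1:x; this never does.
sample_one <- function(x) x[[sample.int(length(x), 1L)]]
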