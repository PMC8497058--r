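# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. seed = NULL uses the current
# stream (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Per-unit seed derived from a master seed by counter offset; kept inside
# 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 1000003 * as.double(i)) %% 2147483647)
}
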