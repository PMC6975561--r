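# Run code with a temporary RNG state; the caller's stream is untouched.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Order-independent fingerprint of a peak set's coordinates, used to
# verify that derived results are paired with the set they came from.
.peaks_checksum <- function(gr) {
  c(n = length(gr),
    s = sum(as.numeric(start(gr))) %% 2^40,
    e = sum(as.numeric(end(gr))) %% 2^40)
}

# Deterministic child seed from a master seed and a stream name, < 2^31.
child_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 3001) %% 2147483399 + 1)
}
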