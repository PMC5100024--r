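# internal argument checks and seed plumbing

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Derive a stream-specific 32-bit seed from a global seed so that independent
# stages never share a random stream.  Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is_count(seed, min = 0L))
  offsets <- c(
    genotypes = 101L, phenotypes = 211L, spectra = 307L, mcmc = 401L,
    subsample = 503L, design = 601L, wetchem = 701L, pipeline = 811L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# equal-tailed interval helper
cred_interval <- function(x, level = 0.9) {
  a <- (1 - level) / 2
  unname(quantile(x, probs = c(a, 1 - a), names = FALSE, type = 7))
}
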