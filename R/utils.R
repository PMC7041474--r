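# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# smallest 2^a*3^b >= n (efficient FFT length)
fft_length <- function(n) {
  if (n <= 1) return(1L)
  stats::nextn(as.integer(n), factors = c(2L, 3L))
}

stopifnot_finite <- function(x, name = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a 32-bit sub-seed from a base seed and a stage label (deterministic,
# no external hashing dependency)
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  acc <- as.double(seed %% 2147483647L)
  for (c in codes) acc <- (acc * 31 + c) %% 2147483629
  as.integer(acc)
}
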