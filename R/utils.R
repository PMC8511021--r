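# internal helpers shared across modules

# Coerce a pattern/sequence argument to an integer digit vector.
# Accepts a single string of digit characters or a numeric/integer
# vector.  Digits 0-9 are allowed here; the 1-9 domain restriction is
# enforced where sequences are constructed.
as_digits <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("expected a single digit string", call. = FALSE)
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    d <- match(ch, as.character(0:9)) - 1L
    if (anyNA(d)) stop("non-digit character in '", x, "'", call. = FALSE)
    return(d)
  }
  if (!is.numeric(x)) stop("digits must be a string or a numeric vector", call. = FALSE)
  d <- as.integer(x)
  if (anyNA(d) || any(d != x) || any(d < 0L) || any(d > 9L))
    stop("digits must be whole numbers in 0..9", call. = FALSE)
  d
}

# Deterministic substream seed from a master seed and integer tags.
# Multiplier kept small so products stay exactly representable in
# doubles (2^31 * 69069 < 2^53); adding tags never perturbs streams
# derived from other tag combinations.
substream_seed <- function(master, ...) {
  x <- as.double(master) %% 2147483647
  for (k in as.double(c(...))) {
    x <- (x * 69069 + k + 1) %% 2147483647
  }
  as.integer(x)
}

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
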