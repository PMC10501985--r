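# Internal helpers: classed conditions, seed management, float32 rounding.

hc_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "histocbir_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the caller's RNG
#' state, so deterministic components (the seeded backend, the synthetic
#' generators) never perturb user randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed from a base seed and a string key; stays < 2^31.
seed_from_string <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h + as.numeric(seed)) %% 2147483629)
}

# Round doubles through IEEE single precision (the bank's storage type).
round_to_float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.vector(as.double(x)), raw(), size = 4L),
               "double", n = length(x), size = 4L)
  dim(y) <- d
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
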