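#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a stage seed from a global seed
#'
#' Every stochastic stage draws its seed deterministically from the global
#' experiment seed plus a stage name, so that a single integer reproduces a
#' whole run. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 7919 + h * 131 + 17) %% 2147483647)
}

# Run code with a local RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fingerprint a configuration-like list without external hashing deps.
config_fingerprint <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10)
  v <- utf8ToInt(as.character(s))
  # FNV-1a style rolling hash, reported as hex
  h <- 216613626
  for (ch in v) h <- (bitwXor(h %% 2147483647, ch) * 16777619) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
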