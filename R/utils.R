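# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boltzmann constant in kJ mol^-1 K^-1
#'
#' Value used for all thermal-energy conversions in the package.
#' @export
KB_KJ_MOL_K <- 0.0083145

#' Thermal energy kT in kJ/mol
#'
#' @param temperature Temperature in kelvin.
#' @return kT in kJ/mol.
#' @export
kT <- function(temperature = 300) KB_KJ_MOL_K * temperature

# Numerically stable log(sum(exp(x))) along rows/cols or a vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp for a matrix (returns length-nrow vector).
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  bad <- !is.finite(m)
  out <- m + log(rowSums(exp(x - m)))
  out[bad] <- m[bad]
  out
}

# Column-wise logsumexp for a matrix.
col_logsumexp <- function(x) {
  m <- apply(x, 2L, max)
  bad <- !is.finite(m)
  out <- m + log(colSums(exp(sweep(x, 2L, m))))
  out[bad] <- m[bad]
  out
}

# Evaluate code with a private RNG stream; the caller's RNG state is
# untouched. `code` is a promise, forced only after set.seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Polynomial rolling hash of an R object's serialization; short run
# fingerprint for output headers (not cryptographic). Arithmetic stays below
# 2^53 so plain doubles are exact.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
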