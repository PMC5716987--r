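## Internal helpers shared across modules.

#' Evaluate an expression under an optional scoped seed
#'
#' @param seed integer seed or NULL (use the current RNG stream).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Derive a stream sub-seed from a master seed
#'
#' Deterministic integer mixing so independent pipeline stages get
#' independent, reproducible streams from one master seed. Result is kept
#' within the positive 32-bit integer range.
#'
#' @keywords internal
#' @noRd
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483629
  as.integer(s) + 1L
}

#' FNV-1a hash of a character scalar (provenance fingerprinting)
#' @keywords internal
#' @noRd
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n"))) %% 256
  h <- 2166136261  # kept as a double in [0, 2^32)
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
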