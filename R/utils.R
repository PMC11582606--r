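# Small shared helpers. Hashing goes through the compiled FNV-1a so manifests
# and seed derivation stay identical across platforms.

clip01 <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hash an R object (FNV-1a 64-bit over its serialization)
#'
#' Used for run manifests and for deriving reproducible sub-seeds. Serialization
#' uses format version 2 so hashes are stable across R sessions.
#'
#' @param x any serializable R object
#' @return a 16-character lowercase hex string
#' @export
hash_object <- function(x) {
  fnv1a64(serialize(x, connection = NULL, version = 2))
}

#' Hash a character string
#'
#' @param x a single string
#' @return a 16-character hex string
#' @export
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  fnv1a64(charToRaw(enc2utf8(x)))
}

# Deterministic 31-bit seed from a base seed plus arbitrary string keys.
# Keyed by content (e.g. sample id), not position, so reorderings do not
# perturb downstream random streams.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "\r")
  hex <- substr(hash_string(key), 1, 7)  # 28 bits, comfortably < 2^31
  as.integer(strtoi(hex, base = 16L))
}

stop_input <- function(...) stop(..., call. = FALSE)
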