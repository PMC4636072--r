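`%||%` <- function(a, b) if (is.null(a)) b else a

#' 32-bit FNV-1a hash of a string
#'
#' Used for deterministic identifier shortening and for result-set digests.
#' Operates on the UTF-8 bytes of `x`.
#'
#' @param x A single character string.
#' @return An 8-character lowercase hex string.
#' @export
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  # 32-bit arithmetic via doubles (exact below 2^53)
  h <- 2166136261
  prime <- 16777619
  mod <- 2^32
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * prime) %% mod
  }
  paste0(sprintf("%04x", as.integer(h %/% 2^16)),
         sprintf("%04x", as.integer(h %% 2^16)))
}

# xor of two non-negative doubles interpreted as 32-bit integers
bitwXor32 <- function(a, b) {
  lo_a <- a %% 2^16; hi_a <- a %/% 2^16
  lo_b <- b %% 2^16; hi_b <- b %/% 2^16
  bitwXor(lo_a, lo_b) + bitwXor(hi_a, hi_b) * 2^16
}

# Deterministic key ordering: numeric ascending when every key parses as a
# number, otherwise byte-wise (radix) character order.
sort_keys <- function(keys) {
  if (length(keys) == 0L) return(character(0))
  keys <- as.character(keys)
  num <- suppressWarnings(as.numeric(keys))
  if (!anyNA(num)) keys[order(num, method = "radix")]
  else sort(keys, method = "radix")
}

#' Canonical JSON rendering for structural comparison
#'
#' Stable serialization (unboxed scalars, full numeric precision) used for
#' structural equality checks and result-set digests.
#'
#' @param x Any jsonlite-serializable object.
#' @return A single JSON string.
#' @export
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

abort2 <- function(code, msg, ...) {
  stop(structure(class = c(code, "armpersist_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

compact <- function(x) x[!vapply(x, is.null, logical(1))]
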