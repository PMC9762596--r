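# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit polynomial hash of a character vector, hex encoded.
# Used for content-addressed clade identifiers; exact arithmetic in doubles
# (all intermediates < 2^53).
#' @noRd
content_hash <- function(x) {
  s <- paste(x, collapse = "|")
  bytes <- utf8ToInt(s)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% m
  sprintf("%08x", as.integer(h))
}

# Derive a child seed from a master seed and a stage label, staying < 2^31.
#' @noRd
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(label)
  m <- 2147483587
  h <- seed %% m
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' @noRd
is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) &&
    all(x >= 0) && all(x == round(x))
}
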