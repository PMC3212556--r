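#' @keywords internal
"_PACKAGE"

# Run expr under a temporary RNG seed, restoring global RNG state afterwards.
# seed = NULL leaves the current RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic 31-bit sub-seed from a master seed and a character label, so
# that per-response / per-stage RNG streams are independent of list ordering.
derive_seed <- function(seed, label) {
  stopifnot(length(label) == 1L)
  h <- 0
  for (cp in utf8ToInt(as.character(label))) h <- (h * 131 + cp) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_field <- function(row, field, msg) {
  stop(sprintf("row %d, field '%s': %s", row, field, msg), call. = FALSE)
}
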