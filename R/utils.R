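#' @importFrom rlang abort warn %||% .data .env
#' @importFrom stats pt qt qnorm pnorm median setNames
NULL

# internal error helpers: every user-facing failure carries a subclass so
# callers (and the CLI) can map it to an exit code
stop_value <- function(msg, ...) abort(msg, class = "eparmeta_error_value", ...)
stop_schema <- function(msg, ...) abort(msg, class = "eparmeta_error_schema", ...)
stop_integrity <- function(msg, ...) abort(msg, class = "eparmeta_error_integrity", ...)
stop_io <- function(msg, ...) abort(msg, class = "eparmeta_error_io", ...)

#' Round half away from zero
#'
#' Integer rounding used for all printed percentages. Base `round()` rounds
#' half to even; approval-dossier percentages (e.g. 21/26 = 80.77 -> 81) are
#' conventionally rounded half away from zero.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 0).
#' @return Numeric vector, rounded.
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5, 80.769), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# deterministic per-stream seed derivation: keeps every derived seed a valid
# 32-bit integer and decorrelates substreams from a single root seed
derive_seed <- function(root, stream) {
  x <- (as.double(root) %% 2147483647) + 1
  for (s in as.double(stream)) {
    x <- (x * 48271 + s + 1) %% 2147483647
  }
  as.integer(x)
}

is_missing_val <- function(x) is.na(x)

`%theni%` <- function(a, b) if (!is.null(a) && !all(is.na(a))) a else b
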