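# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Stop with a classed condition so callers can distinguish input/config/data
# errors (mirrored by the CLI exit codes).
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "ccecleanse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

input_error <- function(msg) abort(msg, "ccecleanse_input_error")
config_error <- function(msg) abort(msg, "ccecleanse_config_error")
data_error <- function(msg) abort(msg, "ccecleanse_data_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Round half away from zero (ties like 0.125 -> 0.13), used for the printed
# percentage cells; base round() rounds half to even.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

fmt_pct2 <- function(p) sprintf("%.2f", round_half_up(p, 2))

# "0.10" -> ".10", "-0.20" -> "-.20": the conventional kappa print style.
fmt_k2 <- function(x) sub("^(-?)0\\.", "\\1.", sprintf("%.2f", x))

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is_count(seed + 1)) config_error("`seed` must be a single non-negative integer")
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
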