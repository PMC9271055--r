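#' @importFrom rlang abort warn .data
#' @importFrom stats pnorm qnorm pf pchisq pt cor cov median sd var rnorm
#'   rbinom runif complete.cases quantile prcomp lm lm.fit coef resid
#'   setNames
#' @importFrom utils head
NULL

# error helpers: all package errors carry a "vqtlewis_error" class so callers
# can distinguish input problems from degenerate-data conditions
stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("vqtlewis_input_error", "vqtlewis_error"))
}

stop_degenerate <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("vqtlewis_degenerate_error", "vqtlewis_error"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# p-value floor applied before converting two-sided p to z, so z stays finite
P_FLOOR <- 1e-300

p_to_z <- function(p) {
  qnorm(pmax(p, P_FLOOR) / 2, lower.tail = FALSE)
}
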