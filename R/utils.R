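# shared internal helpers

#' Round half away from zero and clip to a bit depth
#'
#' Quantization used when synthesising or writing integer imagery:
#' round half away from zero, then clip to `[0, 2^bit_depth - 1]`.
#'
#' @param x numeric vector or array.
#' @param bit_depth target quantization in bits.
#' @return `x` quantized, same shape.
#' @keywords internal
#' @noRd
quantize_intensity <- function(x, bit_depth) {
  q <- sign(x) * floor(abs(x) + 0.5)
  pmin(pmax(q, 0), 2^bit_depth - 1)
}

is_integerish_values <- function(x, tol = 0) {
  all(x == round(x))
}

abort_cf <- function(msg, class) {
  rlang::abort(msg, class = paste0("ciliafreq_", class))
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_cf(sprintf("`%s` must be a single finite number.", name), "bad_arg")
  }
  if (positive && x <= 0) {
    abort_cf(sprintf("`%s` must be > 0.", name), "bad_arg")
  }
  invisible(x)
}

# population variance (divisor n); the spectral normalization is stated
# in terms of this quantity
pop_var <- function(x) {
  mean((x - mean(x))^2)
}
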