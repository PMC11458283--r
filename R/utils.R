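#' Round half away from zero
#'
#' Feed-evaluation reports conventionally round 0.5 up (so an ADC of 87.5
#' prints as 88), whereas [base::round()] rounds half to even. Internal
#' computations are always carried at full precision; this helper is applied
#' only when formatting report values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(87.5, 88.5, -0.5))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with a consistent condition class so callers can distinguish
# validation failures from computation errors
abort_feedeval <- function(msg, class) {
  stop(structure(
    class = c(class, "feedeval_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (is.null(x) || length(x) == 0L || (!allow_na && all(is.na(x)))) {
    abort_feedeval(sprintf("'%s' is missing", name), "feedeval_missing_field")
  }
  if (!is.numeric(x)) {
    abort_feedeval(sprintf("'%s' must be numeric", name),
                   "feedeval_validation_error")
  }
  bad <- !is.na(x) & (x < lower | x > upper)
  if (any(bad)) {
    abort_feedeval(
      sprintf("'%s' = %s outside [%g, %g]", name,
              paste(format(x[bad]), collapse = ", "), lower, upper),
      "feedeval_out_of_range"
    )
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
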