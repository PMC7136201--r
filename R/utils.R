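# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# format doubles with fixed decimals for TSV output; integers untouched
fmt_num <- function(x, digits = 4) {
  if (is.double(x)) formatC(x, format = "f", digits = digits) else x
}

#' Integer percentage of a count over a total
#'
#' Rounds `100 * n / total` to the nearest integer percent, the convention
#' used throughout summary reporting (e.g. singleton or annotated fractions
#' of an orthologous-group catalogue).
#'
#' @param n Count (numerator), non-negative.
#' @param total Total (denominator), positive.
#' @return Integer percentage.
#' @examples
#' pct_of(31, 54)  # 57
#' @export
pct_of <- function(n, total) {
  stopifnot(is.numeric(n), is.numeric(total), total > 0, n >= 0)
  as.integer(round(100 * n / total))
}
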