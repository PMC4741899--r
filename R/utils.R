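#' Round half-up to a fixed number of decimals
#'
#' Clinical tables report RMSD values rounded half-up (0.00005 -> 0.0001),
#' whereas base [round()] rounds half-to-even. Used wherever values are
#' formatted for reports; internal arithmetic stays at full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Fixed-point sum at 4 decimals
#'
#' Sums values that are already quantities at 4-decimal precision (table
#' records) on an integer ten-thousandths grid, so totals never drift by
#' floating error and equal the printed sum of their components exactly.
#'
#' @param x numeric vector of 4-decimal quantities.
#' @return their sum, exact at 4 decimals.
#' @keywords internal
fixed_sum4 <- function(x) {
  if (length(x) == 0L) return(0)
  sum(round(x * 1e4)) / 1e4
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() wrapper producing classed conditions so callers/tests can
# distinguish error families
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "hlarmsd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
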