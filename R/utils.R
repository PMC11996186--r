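#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in the published tables this
#' pipeline reproduces: 6,628.5 rounds to 6,629 and 1,657.5 to 1,658, where
#' IEEE round-half-even would give 6,628 and 1,658. A tiny relative epsilon
#' guards against binary representation error in products such as
#' `41319 * 0.85`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(6628.5)      # 6629
#' round_half_up(2.1179, 1)   # 2.1
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  z <- x * s
  sign(z) * floor(abs(z) + 0.5 + 1e-9) / s
}

#' Choose between the table-compatible and exact rounding modes
#'
#' Most operations round at each printed intermediate ("half_up", matching
#' the published tables cell for cell); mode "none" keeps full precision for
#' error-propagation studies.
#' @noRd
apply_rounding <- function(x, digits = 0, rounding = c("half_up", "none")) {
  rounding <- match.arg(rounding)
  if (rounding == "none") x else round_half_up(x, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
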