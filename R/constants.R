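# Physical constants and small shared helpers.

# Boltzmann constant in kcal mol^-1 K^-1 (CODATA value used throughout MD codes)
KB_KCAL <- 0.0019872041

# Ideal tetrahedral angle, degrees, and the tau4 denominator 360 - 2*theta_t.
# The literature quotes the denominator rounded to 141; the exact value is used
# so an ideal tetrahedron scores exactly 1.
TETRAHEDRAL_ANGLE <- acos(-1 / 3) * 180 / pi
TAU4_DENOM <- 360 - 2 * TETRAHEDRAL_ANGLE

kbt <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  KB_KCAL * temperature
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# like %||% but also treats a length-1 NA (e.g. from a config default) as
# missing
value_or <- function(x, default) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) default else x
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_ionprobe <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}
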