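# Wrap-aware angular arithmetic. All directions in the package are degrees,
# counter-clockwise positive, 0 along +x, wrapped to (-180, 180].

#' Wrap angles into (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector with each element wrapped into `(-180, 180]`.
#' @examples
#' wrap_angle(c(0, 190, -190, 360, 180))
#' @export
wrap_angle <- function(x) {
  stopifnot(is.numeric(x))
  w <- (x + 180) %% 360 - 180
  # map the -180 representative onto +180 so the interval is (-180, 180]
  w[w == -180] <- 180
  w
}

# Signed angular difference a - b wrapped to (-180, 180].
ang_diff <- function(a, b) {
  wrap_angle(a - b)
}
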