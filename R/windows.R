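# Meyer-type window functions used to assemble the band-limited shearlet
# filter bank. All windows are built from the classical polynomial smoothing
# function v with v(x) + v(1 - x) = 1, which makes every partition-of-unity
# identity below exact up to floating point.

#' @keywords internal
meyer_smooth <- function(x) {
  y <- pmin(pmax(x, 0), 1)
  y^4 * (35 - 84 * y + 70 * y^2 - 20 * y^3)
}

# Squared Meyer-type wavelet window on the line, supported on
# |w| in [1/4, 1] (inside the [1/4, 5/4] support budget of the classical
# construction). Satisfies the discrete Calderon condition
# sum_j psi1_sq(2^-j w) = 1 for all w != 0.
#' @keywords internal
psi1_sq <- function(w) {
  w <- abs(w)
  out <- numeric(length(w))
  rise <- w >= 0.25 & w < 0.5
  fall <- w >= 0.5 & w <= 1
  out[rise] <- meyer_smooth(4 * w[rise] - 1)
  out[fall] <- 1 - meyer_smooth(2 * w[fall] - 1)
  out
}

# Squared bump window, supported on [-1, 1], with the integer-shift
# partition property: sum_{k in Z} psi2_sq(u - k) = 1 for all u.
#' @keywords internal
psi2_sq <- function(u) {
  out <- numeric(length(u))
  inside <- abs(u) < 1
  out[inside] <- meyer_smooth(1 - abs(u[inside]))
  out
}
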