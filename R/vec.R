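# 2-D vector helpers shared by all behaviour kernels.
# Positions are in pixels (1 px = 0.05 m by default); angles in radians.

.eps <- 1e-12

#' Rotate a 2-D vector anti-clockwise
#'
#' @param v Numeric length-2 vector.
#' @param alpha Rotation angle in radians, anti-clockwise.
#' @return Numeric length-2 vector of the same norm as `v`.
#' @examples
#' rotate_vec(c(1, 0), pi / 2)  # ~ (0, 1)
#' @export
rotate_vec <- function(v, alpha) {
  ca <- cos(alpha)
  sa <- sin(alpha)
  c(ca * v[1] - sa * v[2], sa * v[1] + ca * v[2])
}

#' Normalise a 2-D vector to unit length
#'
#' @param v Numeric length-2 vector; must be nonzero.
#' @return Unit vector in the direction of `v`.
#' @export
normalise_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .eps) {
    stop_degenerate("cannot normalise a (near-)zero vector")
  }
  v / n
}

vec_norm <- function(v) sqrt(sum(v^2))

# Uniformly random unit vector, drawn from the session RNG stream.  Used to
# break ties in degenerate-direction situations (agent exactly on its target,
# coincident agents) so that no configuration can produce NaN, while staying
# reproducible under set.seed().
random_unit <- function() {
  ang <- runif(1, 0, 2 * pi)
  c(cos(ang), sin(ang))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg,
    class = c("crowd_degenerate_error", "error", "condition")))
}

stop_no_neighbours <- function(msg) {
  stop(errorCondition(msg,
    class = c("crowd_no_neighbours_error", "error", "condition")))
}
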