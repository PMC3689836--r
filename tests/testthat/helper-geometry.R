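# Shared helpers for geometric tests.

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigid_motion <- function(points, R = random_rotation(), shift = rnorm(3, sd = 5)) {
  sweep(points %*% t(R), 2, shift, `+`)
}

# planar circle of given radius in the z = 0 plane
unit_circle <- function(n = 128, radius = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(radius * cos(t), radius * sin(t), 0)
}

fixture_measurements <- function() {
  env <- globalenv()
  if (is.null(env$.otomorph_fix)) env$.otomorph_fix <- load_measurements()
  env$.otomorph_fix
}
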