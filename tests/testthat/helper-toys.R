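# shared fixtures for the test suite (all built in code)

# random right-handed orthonormal frame
random_frame <- function(origin_sd = 50) {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  th <- stats::runif(1, 0, pi)
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  bp_frame(stats::rnorm(3, 0, origin_sd), R)
}

random_step <- function() {
  step_params(tilt = stats::rnorm(1, 0, 30), roll = stats::rnorm(1, 0, 30),
              twist = stats::runif(1, -179, 179),
              shift = stats::rnorm(1), slide = stats::rnorm(1),
              rise = stats::rnorm(1, 3.4, 1))
}

# soft toy: n-step chain with inflated fluctuations, bent reference loop
toy_bent_anchor <- function(n = 20) {
  ref <- dna_chain(cbind(tilt = 0, roll = rep(360 / n, n),
                         twist = 360 / 10.5, shift = 0, slide = 0,
                         rise = 3.4))
  loop_anchor(bp_frame(), build_chain_frames(ref)[[n + 1]], "A1")
}

toy_soft_model <- function(n = 20, scale = 4) {
  elastic_model(n, sigma_tilt = 4.84 * scale, sigma_roll = 4.84 * scale,
                sigma_twist = 4.09 * scale)
}

# exactly closed torsionally relaxed ring anchor (first = last frame)
ring_anchor <- function() {
  loop_anchor(bp_frame(), bp_frame(), "A1",
              closing_step = step_params(twist = 0, rise = 0))
}

expect_frames_equal <- function(f1, f2, tol = 1e-9) {
  expect_lt(max(abs(f1$origin - f2$origin)), tol)
  expect_lt(max(abs(f1$axes - f2$axes)), tol)
}
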