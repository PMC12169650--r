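# shared fixtures and small utilities for the test suite

apt_sequence <- "GCATATATATGC"
gpc_sequence <- "GCGCGCGCGCGC"

# apply a global rigid-body transform to every atom of a structure
rigid_transform <- function(structure, R, t) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, t, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

random_rotation <- function() {
  axis <- stats::rnorm(3)
  duplexform:::rot_axis(axis / sqrt(sum(axis^2)), stats::runif(1, 0, pi))
}

random_frame <- function() {
  duplexform:::new_frame(random_rotation(), stats::runif(3, -10, 10))
}

# six random rigid-base parameters within the physical range
random_params <- function(max_angle = 45, max_trans = 3) {
  c(stats::runif(3, -max_angle, max_angle),
    stats::runif(3, -max_trans, max_trans))
}

expect_equal_tol <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
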