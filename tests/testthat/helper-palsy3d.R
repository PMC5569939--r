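# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# A small synthetic model reused across tests (seeded, deterministic).
test_model <- function(m = 150L, k_id = 4L, k_exp = 2L, seed = 1L) {
  key <- sprintf("model_%d_%d_%d_%d", m, k_id, k_exp, seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_model(m = m, k_id = k_id, k_exp = k_exp, seed = seed)
  .fixture_env[[key]]
}

# A toy 5-point scheme with singleton eyes and a 2-point mouth.
toy_scheme <- function() {
  landmark_scheme(5L, "toy5",
                  list(left_eye = 1L, right_eye = 2L, mouth = c(4L, 5L)))
}

random_pose <- function() {
  face_pose(scale = runif(1, 1, 5),
            pitch = runif(1, -0.4, 0.4), yaw = runif(1, -0.4, 0.4),
            roll = runif(1, -0.4, 0.4),
            translation = runif(2, -100, 400))
}

# Geodesic distance between two rotations, in radians, computed through
# the Frobenius norm (||R1 - R2||_F = 2*sqrt(2)*sin(theta/2)), which stays
# accurate for tiny angles where acos of the trace loses all precision.
rotation_geodesic <- function(R1, R2) {
  fn <- sqrt(sum((R1 - R2)^2))
  2 * asin(min(1, fn / (2 * sqrt(2))))
}
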