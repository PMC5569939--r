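test_that("motion is zero for identical meshes and matches the 3-4-5 closed form", {
  model <- test_model()
  mesh <- construct_shape(model, shape_coefficients(numeric(4), numeric(2)))
  regions <- face_regions(model, c("left", "right"))
  ev0 <- motion_magnitude(mesh, mesh, regions)
  expect_true(all(ev0$regions$E_sum == 0))
  expect_true(all(ev0$regions$E_mean == 0))

  v1 <- mesh$vertices
  v1[, 5] <- v1[, 5] + c(3, 4, 0)
  ev <- motion_magnitude(mesh, face_mesh(v1), list(region_index("spot", 5L)))
  expect_identical(ev$regions$E_sum, 25)
  expect_identical(ev$regions$E_mean, 25)
})

test_that("region motion matches a brute-force per-vertex loop", {
  model <- test_model()
  set.seed(70)
  v0 <- matrix(rnorm(3 * model$vertex_count, sd = 10), 3L)
  v1 <- v0 + matrix(rnorm(3 * model$vertex_count), 3L)
  regions <- face_regions(model)  # four quadrants
  ev <- motion_magnitude(v0, v1, regions)
  for (i in seq_along(regions)) {
    idx <- regions[[i]]$indices
    oracle <- vapply(idx, function(v) sum((v1[, v] - v0[, v])^2), 1.0)
    expect_lt(abs(ev$regions$E_sum[i] - sum(oracle)), 1e-12 * max(1, sum(oracle)))
    expect_equal(ev$regions$E_mean[i], mean(oracle), tolerance = 1e-12)
    expect_equal(ev$regions$E_sum[i], ev$regions$E_mean[i] * ev$regions$n_vertices[i],
                 tolerance = 1e-12)
  }
})

test_that("E_sum is additive over disjoint regions", {
  model <- test_model()
  set.seed(71)
  v0 <- matrix(rnorm(3 * model$vertex_count, sd = 5), 3L)
  v1 <- v0 + matrix(rnorm(3 * model$vertex_count), 3L)
  d1 <- region_index("a", 1:40); d2 <- region_index("b", 41:100)
  du <- region_index("ab", 1:100)
  ev <- motion_magnitude(v0, v1, list(d1, d2, du))
  expect_equal(ev$regions$E_sum[3], ev$regions$E_sum[1] + ev$regions$E_sum[2],
               tolerance = 1e-12 * max(1, ev$regions$E_sum[3]))
})

test_that("a pure global translation of S1 yields equal mean motion in all regions", {
  # documents why pose-normalized (model-space) meshes are required upstream
  model <- test_model()
  mesh <- construct_shape(model, sample_face(model, seed = 8))
  shifted <- face_mesh(mesh$vertices + c(2, -1, 3))
  ev <- motion_magnitude(mesh, shifted, face_regions(model))
  expect_equal(diff(range(ev$regions$E_mean)), 0, tolerance = 1e-12)
  expect_equal(ev$regions$E_mean[1], sum(c(2, -1, 3)^2), tolerance = 1e-12)
})

test_that("motion_magnitude validates mesh and region dimensions", {
  model <- test_model()
  mesh <- construct_shape(model, shape_coefficients(numeric(4), numeric(2)))
  expect_error(motion_magnitude(mesh, face_mesh(mesh$vertices[, 1:10]), face_regions(model)),
               "dimensions")
  expect_error(motion_magnitude(mesh, mesh, list(region_index("far", model$vertex_count + 1L))),
               "beyond")
})

test_that("rehab progress is the signed change of mean motion from baseline", {
  model <- test_model()
  regions <- face_regions(model, c("left", "right"))
  coeffs <- sample_face(model, seed = 9)
  ev_at <- function(rho, id) {
    mv <- simulate_movement(model, coeffs, amplitude = 20, side = "left",
                            attenuation = rho)
    motion_magnitude(mv$S0, mv$S1, regions, session_id = id)
  }
  base <- ev_at(0.4, "s1")
  same <- ev_at(0.4, "s2")
  pr <- rehab_progress(list(base, same))
  expect_equal(pr$R[pr$session == "s2"], c(0, 0), tolerance = 1e-12)

  # hand-built evaluations: baseline 4.0 -> 9.0 gives R = 5.0
  mk <- function(id, e) structure(list(session_id = id,
    regions = data.frame(region = "r", n_vertices = 1L, E_sum = e, E_mean = e),
    units = "mm"), class = "face_evaluation")
  expect_equal(rehab_progress(list(mk("a", 4), mk("b", 9)))$R, c(0, 5))

  expect_error(rehab_progress(list(base)), "at least 2")
  expect_error(rehab_progress(list(base, base)), "unique")
  other <- motion_magnitude(construct_shape(model, coeffs),
                            construct_shape(model, coeffs),
                            face_regions(model), session_id = "sX")
  expect_error(rehab_progress(list(base, other)), "region set")
})

test_that("progress grows monotonically through a linear recovery series", {
  model <- test_model()
  regions <- face_regions(model, c("left", "right"))
  coeffs <- sample_face(model, seed = 10)
  rhos <- seq(0.2, 1, length.out = 5)
  series <- lapply(seq_along(rhos), function(i) {
    mv <- simulate_movement(model, coeffs, amplitude = 25, side = "left",
                            attenuation = rhos[i])
    motion_magnitude(mv$S0, mv$S1, regions, session_id = sprintf("s%d", i))
  })
  pr <- rehab_progress(series)
  left <- pr$R[pr$region == "left"]
  expect_true(all(diff(left) > 0))
  expect_true(all(left[-1] > 0))
})

test_that("asymmetry index has the documented extremes and undefined case", {
  mk <- function(l, r) structure(list(session_id = "s",
    regions = data.frame(region = c("L", "R"), n_vertices = c(1L, 1L),
                         E_sum = c(l, r), E_mean = c(l, r)),
    units = "mm"), class = "face_evaluation")
  expect_equal(asymmetry_index(mk(3, 3), "L", "R"), 0)
  expect_equal(asymmetry_index(mk(0, 5), "L", "R"), 1)
  expect_equal(asymmetry_index(mk(5, 0), "L", "R"), -1)
  expect_warning(a <- asymmetry_index(mk(0, 0), "L", "R"), "undefined")
  expect_true(is.na(a))
  expect_error(asymmetry_index(mk(1, 2), "L", "nope"), "not present")
})

test_that("simulated attenuation is recovered through the asymmetry index", {
  model <- test_model(m = 200, k_id = 4, k_exp = 3, seed = 5)
  regions <- face_regions(model, c("left", "right"))
  for (rho in c(0.25, 0.5, 0.75)) {
    a_expect <- (1 - rho^2) / (1 + rho^2)
    for (s in 1:20) {
      coeffs <- sample_face(model, seed = 500 + s)
      mv <- simulate_movement(model, coeffs, amplitude = 15, side = "left",
                              attenuation = rho)
      ev <- motion_magnitude(mv$S0, mv$S1, regions)
      a <- asymmetry_index(ev, "left", "right")
      expect_lt(abs(a - a_expect), 0.05)
      expect_lt(abs(attenuation_from_asymmetry(a) - rho), 0.05)
    }
  }
})

test_that("region configs resolve explicit lists and half-plane rules deterministically", {
  model <- test_model()
  p <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(regions = list(
    picks = list(indices = c(1, 2, 3)),
    upper_left = list(rule = "upper_left"),
    upper_right = list(rule = "upper_right"),
    lower_left = list(rule = "lower_left"),
    lower_right = list(rule = "lower_right"))), p)
  regions <- load_regions(p, model)
  expect_identical(regions$picks$indices, 1:3)

  # quadrants partition all vertices off the split lines
  x <- model$mean_shape[1, ]; y <- model$mean_shape[2, ]
  off <- which(x != mean(x) & y != mean(y))
  quad <- unlist(lapply(regions[c("upper_left", "upper_right", "lower_left", "lower_right")],
                        function(r) r$indices))
  expect_identical(sort(unname(quad)), off)
  expect_identical(anyDuplicated(quad), 0L)

  # the mirror-symmetric model has equally sized left/right halves
  lr <- face_regions(model, c("left", "right"))
  expect_identical(length(lr$left$indices), length(lr$right$indices))

  yaml::write_yaml(list(regions = list(bad = list(rule = "diagonal"))), p)
  expect_error(load_regions(p, model), "unknown region rule")
})
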