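test_that("solve_coefficients recovers generating coefficients exactly at a fixed pose", {
  model <- test_model(m = 150, k_id = 4, k_exp = 2)
  set.seed(14)
  for (i in 1:10) {
    truth <- shape_coefficients(rnorm(4), rnorm(2))
    pose <- random_pose()
    mesh <- construct_shape(model, truth)
    obs <- project_points(mesh$vertices[, model$correspondence], pose)
    est <- solve_coefficients(model, pose, obs, model$correspondence,
                              lambda_id = 1e-8, lambda_exp = 1e-8)
    expect_lt(max(abs(c(est$alpha_id - truth$alpha_id,
                        est$alpha_exp - truth$alpha_exp))), 1e-6)
  }
})

test_that("huge ridge weights shrink the coefficients to zero", {
  model <- test_model()
  pose <- face_pose(scale = 3, translation = c(200, 200))
  obs <- project_points(model$mean_shape[, model$correspondence], pose) +
    matrix(rnorm(136, sd = 3), ncol = 2L)
  est <- solve_coefficients(model, pose, obs, model$correspondence,
                            lambda_id = 1e12, lambda_exp = 1e12)
  expect_lt(sqrt(sum(c(est$alpha_id, est$alpha_exp)^2)), 1e-6)
})

test_that("the closed-form coefficient solution beats 1000 random coefficient vectors", {
  model <- test_model()
  pose <- face_pose(scale = 2, yaw = 0.2, translation = c(150, 180))
  set.seed(77)
  obs <- project_points(model$mean_shape[, model$correspondence], pose) +
    matrix(rnorm(136, sd = 4), ncol = 2L)
  lam <- 1e-3
  objective <- function(cf) {
    mesh <- construct_shape(model, cf)
    pred <- project_points(mesh$vertices[, model$correspondence], pose)
    sum((obs - pred)^2) + lam * sum(cf$alpha_id^2) + lam * sum(cf$alpha_exp^2)
  }
  est <- solve_coefficients(model, pose, obs, model$correspondence, lam, lam)
  best <- objective(est)
  rand <- replicate(1000, objective(shape_coefficients(rnorm(4, sd = 2), rnorm(2, sd = 2))))
  expect_true(all(best <= rand))
})

test_that("a rank-deficient system with zero ridge raises an error advising positive lambda", {
  model <- test_model()
  pose <- face_pose(scale = 3, translation = c(100, 100))
  corr <- model$correspondence[1:2]  # 4 equations for 6 unknowns
  obs <- project_points(model$mean_shape[, corr], pose)
  expect_error(solve_coefficients(model, pose, obs, corr, 0, 0),
               "rank-deficient.*lambda")
})

test_that("fit_face recovers pose and coefficients from noiseless observations", {
  model <- test_model(m = 200, k_id = 8, k_exp = 4, seed = 2)
  set.seed(90)
  for (i in 1:5) {
    truth <- sample_face(model)
    pose <- random_pose()
    mesh <- construct_shape(model, truth)
    obs <- observe(mesh, pose, model$correspondence, noise_sigma = 0)
    fit <- fit_face(model, obs,
                    config = fit_config(max_iters = 200, tol = 1e-14,
                                        lambda_id = 1e-8, lambda_exp = 1e-8))
    expect_lt(fit$residual, 1e-4)  # percent of IOD
    expect_lt(max(abs(c(fit$pose$pitch - pose$pitch, fit$pose$yaw - pose$yaw,
                        fit$pose$roll - pose$roll))), 1e-4)
    err <- coef(fit) - c(truth$alpha_id, truth$alpha_exp)
    expect_lt(sqrt(mean(err^2)), 1e-4)
    expect_true(all(diff(fit$residual_trace) <= 1e-12))
  }
})

test_that("observations equal to the projected mean face are a fixed point", {
  model <- test_model()
  pose <- face_pose(scale = 2.5, pitch = 0.05, yaw = -0.1, translation = c(250, 300))
  obs <- observe(construct_shape(model, shape_coefficients(numeric(4), numeric(2))),
                 pose, model$correspondence, noise_sigma = 0)
  fit <- fit_face(model, obs, config = fit_config(lambda_id = 1e-8, lambda_exp = 1e-8))
  expect_lte(fit$n_iters, 2L)
  expect_true(fit$converged)
  expect_lt(fit$residual, 1e-10)
})

test_that("doubling the landmark noise roughly doubles the mean final residual", {
  model <- test_model()
  truth <- sample_face(model, seed = 6)
  pose <- face_pose(scale = 3, yaw = 0.1, translation = c(300, 300))
  mesh <- construct_shape(model, shape_coefficients(truth$alpha_id, numeric(2)))
  resid_at <- function(sigma, seed) {
    obs <- observe(mesh, pose, model$correspondence, noise_sigma = sigma, seed = seed)
    fit_face(model, obs)$residual
  }
  r1 <- vapply(1:50, function(s) resid_at(1, 1000 + s), 1.0)
  r2 <- vapply(1:50, function(s) resid_at(2, 1000 + s), 1.0)
  ratio <- mean(r2) / mean(r1)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("recovered-coefficient error grows monotonically with landmark noise", {
  model <- test_model()
  truth <- sample_face(model, seed = 16)
  pose <- face_pose(scale = 3, translation = c(300, 300))
  mesh <- construct_shape(model, truth)
  sigmas <- c(0, 0.5, 1, 2)
  mean_err <- vapply(sigmas, function(sig) {
    errs <- vapply(1:50, function(s) {
      obs <- observe(mesh, pose, model$correspondence, noise_sigma = sig, seed = 300 + s)
      fit <- fit_face(model, obs, config = fit_config(lambda_id = 1e-6, lambda_exp = 1e-6))
      sqrt(mean((coef(fit) - c(truth$alpha_id, truth$alpha_exp))^2))
    }, 1.0)
    mean(errs)
  }, 1.0)
  expect_true(all(diff(mean_err) >= 0))
})

test_that("translating all observations only translates the fitted pose", {
  model <- test_model()
  truth <- sample_face(model, seed = 23)
  pose <- face_pose(scale = 2, pitch = 0.1, translation = c(100, 120))
  obs <- observe(construct_shape(model, truth), pose, model$correspondence,
                 noise_sigma = 1, seed = 4)
  fit1 <- fit_face(model, obs)
  shifted <- landmark_set(obs$points + matrix(c(33, -12), 68, 2, byrow = TRUE),
                          obs$scheme)
  fit2 <- fit_face(model, shifted)
  expect_equal(fit2$pose$translation - fit1$pose$translation, c(33, -12),
               tolerance = 1e-6)
  expect_lt(max(abs(coef(fit2) - coef(fit1))), 1e-8)
  expect_equal(c(fit2$pose$scale, fit2$pose$pitch, fit2$pose$yaw, fit2$pose$roll),
               c(fit1$pose$scale, fit1$pose$pitch, fit1$pose$yaw, fit1$pose$roll),
               tolerance = 1e-8)
})

test_that("reprojection_rmse matches the ocular RMSE closed forms", {
  model <- test_model()
  truth <- sample_face(model, seed = 31)
  pose <- face_pose(scale = 3, translation = c(250, 250))
  obs <- observe(construct_shape(model, truth), pose, model$correspondence)
  fit <- fit_face(model, obs, config = fit_config(lambda_id = 1e-8, lambda_exp = 1e-8))
  expect_lt(reprojection_rmse(fit), 1e-6)  # near-perfect fit

  # single landmark off by the interocular distance -> 100/sqrt(n)
  iod <- interocular_distance(obs)
  shifted <- obs$points; shifted[5, 1] <- shifted[5, 1] + iod
  expect_equal(ocular_rmse(landmark_set(shifted, obs$scheme), obs),
               100 / sqrt(68), tolerance = 1e-10)
})

test_that("fit reports serialize and read back losslessly", {
  model <- test_model()
  obs <- observe(construct_shape(model, sample_face(model, seed = 40)),
                 face_pose(scale = 2, translation = c(200, 200)),
                 model$correspondence, noise_sigma = 0.5, seed = 41)
  fit <- fit_face(model, obs)
  p <- withr::local_tempfile(fileext = ".txt")
  write_fit_report(fit, p)
  back <- read_fit_report(p)
  expect_identical(back$pose$scale, fit$pose$scale)
  expect_identical(back$pose$translation, fit$pose$translation)
  expect_identical(back$coefficients$alpha_id, fit$coefficients$alpha_id)
  expect_identical(back$coefficients$alpha_exp, fit$coefficients$alpha_exp)
  expect_identical(back$residual_trace, fit$residual_trace)
  expect_identical(back$n_iters, fit$n_iters)
})

test_that("fit_face warns when the system is under-determined and errors without correspondence", {
  model <- test_model()
  pose <- face_pose(scale = 2, translation = c(100, 100))
  corr <- model$correspondence[1:3]  # 6 equations for 6 coefficients
  obs <- project_points(model$mean_shape[, corr], pose)
  expect_warning(fit_face(model, obs, correspondence = corr), "under-determined")
  # the model's own 68-point correspondence does not match 4 observations
  expect_error(fit_face(model, obs, correspondence = NULL), "does not match")
  bare <- morphable_model(model$mean_shape, model$id_basis, model$exp_basis,
                          model$id_scale, model$exp_scale)
  expect_error(fit_face(bare, obs, correspondence = NULL), "correspondence")
})
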