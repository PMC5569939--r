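#' Fitter configuration
#'
#' Controls the alternating solver of [fit_face()].  The ridge weights act
#' on coefficients in standard-deviation units, so the defaults are
#' scale-free mild shrinkage that keeps the coefficient system
#' well-conditioned with 68 landmarks and larger bases.
#'
#' @param max_iters maximum number of pose/coefficient alternations.
#' @param tol stop when the relative change of the residual falls below
#'   this.
#' @param lambda_id,lambda_exp non-negative ridge weights on the identity
#'   and expression coefficients (sd-unit space).
#' @param init_pose optional [face_pose()] used instead of the closed-form
#'   mean-shape initialization.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(max_iters = 50L, tol = 1e-8,
                       lambda_id = 1e-3, lambda_exp = 1e-3,
                       init_pose = NULL) {
  max_iters <- as.integer(max_iters)
  if (max_iters < 1L) stopf("'max_iters' must be a positive integer")
  if (!is.numeric(tol) || tol <= 0) stopf("'tol' must be positive")
  if (lambda_id < 0 || lambda_exp < 0) stopf("ridge weights must be non-negative")
  if (!is.null(init_pose)) stopifnot(inherits(init_pose, "face_pose"))
  structure(list(max_iters = max_iters, tol = tol,
                 lambda_id = lambda_id, lambda_exp = lambda_exp,
                 init_pose = init_pose),
            class = "fit_config")
}

# Ridge design for the coefficient sub-problem at a fixed pose: the
# projected landmark positions are affine in the (sd-unit) coefficients,
# with design column j = f * P %*% R %*% (basis column j at the landmark
# vertices) * scale_j, stacked landmark-by-landmark as (u_i, v_i).
coefficient_design <- function(model, pose, corr) {
  R <- rotation_from_euler(pose$pitch, pose$yaw, pose$roll)
  PR <- pose$scale * R[1:2, , drop = FALSE]   # 2 x 3
  rows <- as.vector(rbind(3L * corr - 2L, 3L * corr - 1L, 3L * corr))
  B <- cbind(sweep(model$id_basis[rows, , drop = FALSE], 2L, model$id_scale, `*`),
             sweep(model$exp_basis[rows, , drop = FALSE], 2L, model$exp_scale, `*`))
  n <- length(corr); k <- ncol(B)
  A <- matrix(0, 2L * n, k)
  for (i in seq_len(n)) {
    A[(2L * i - 1L):(2L * i), ] <- PR %*% B[(3L * i - 2L):(3L * i), , drop = FALSE]
  }
  A
}

#' Solve the shape-coefficient sub-problem at a fixed pose
#'
#' The projected model landmarks are linear in the coefficients, so the
#' ridge-penalized 2D reprojection objective
#' \deqn{\|s_{2dt} - s_{2d}(c)\|^2 + \lambda_{id}\|\alpha_{id}\|^2 +
#'       \lambda_{exp}\|\alpha_{exp}\|^2}
#' has a unique closed-form minimizer (for positive ridge weights), found
#' here as one least-squares solve over the concatenated coefficients.
#'
#' @param model a [morphable_model()].
#' @param pose a fixed [face_pose()].
#' @param observed `n x 2` matrix or [landmark_set()] of observed pixels.
#' @param corr integer vector of model vertex indices, one per landmark.
#' @param lambda_id,lambda_exp non-negative ridge weights.
#' @return A [shape_coefficients()].
#' @export
solve_coefficients <- function(model, pose, observed, corr,
                               lambda_id = 1e-3, lambda_exp = 1e-3) {
  stopifnot(inherits(model, "morphable_model"), inherits(pose, "face_pose"))
  obs <- landmark_points(observed)
  corr <- as.integer(corr)
  if (nrow(obs) != length(corr))
    stopf("observation count %d does not match correspondence length %d",
          nrow(obs), length(corr))
  if (any(corr < 1L) || any(corr > model$vertex_count))
    stopf("correspondence indices must lie in [1, m = %d]", model$vertex_count)
  k_id <- length(model$id_scale); k_exp <- length(model$exp_scale)
  A <- coefficient_design(model, pose, corr)
  base2d <- project_points(model$mean_shape[, corr, drop = FALSE], pose)
  r <- as.vector(t(obs - base2d))  # (u1, v1, u2, v2, ...)
  lam <- c(rep(lambda_id, k_id), rep(lambda_exp, k_exp))
  k <- k_id + k_exp
  if (all(lam == 0)) {
    qa <- qr(A)
    if (qa$rank < k)
      stopf(paste("coefficient system is rank-deficient (rank %d < %d) with zero ridge weights;",
                  "use positive lambda_id/lambda_exp"), qa$rank, k)
    cf <- qr.coef(qa, r)
  } else {
    aug <- rbind(A, diag(sqrt(lam), k))
    cf <- qr.coef(qr(aug), c(r, rep(0, k)))
  }
  shape_coefficients(cf[seq_len(k_id)], cf[k_id + seq_len(k_exp)])
}

# Residual used for the fit trace: ocular-scaled reprojection RMSE
# (percent of the observed set's interocular distance) when the scheme
# defines eye subsets, otherwise plain pixel RMSE.
fit_residual <- function(model, pose, coeffs, obs_set, corr) {
  mesh <- construct_shape(model, coeffs)
  pred <- project_points(mesh$vertices[, corr, drop = FALSE], pose)
  if (!is.null(obs_set$scheme)) {
    ocular_rmse(landmark_set(pred, obs_set$scheme, source = "fit"), obs_set)
  } else {
    sqrt(mean(rowSums((pred - obs_set$points)^2)))
  }
}

#' Fit a 3D morphable face model to observed 2D landmarks
#'
#' Estimates pose, identity and expression coefficients that minimize the
#' 2D distance between the projected model landmarks and the observations,
#' by block-coordinate descent with two closed-form sub-solves per
#' iteration: scaled-orthographic Procrustes for the pose
#' ([estimate_pose()]) and ridge least squares for the coefficients
#' ([solve_coefficients()]).  Iteration starts from the mean face (all
#' coefficients zero) with the pose estimated against the mean-shape
#' landmarks, so the fit is fully deterministic.  If a step would increase
#' the residual (a floating-point effect near a fixed point), the previous
#' iterate is kept and iteration stops, which guarantees a non-increasing
#' residual trace.
#'
#' @param model a [morphable_model()].
#' @param observed a [landmark_set()] (preferred; enables the ocular-scaled
#'   residual) or an `n x 2` pixel matrix.
#' @param correspondence model vertex indices, one per landmark; defaults
#'   to the observed scheme's correspondence, then the model's own.
#' @param config a [fit_config()].
#' @return An object of class `face_fit` with components `pose`,
#'   `coefficients`, `residual_trace`, `residual`, `converged`, `n_iters`.
#'   Methods: `print`, `summary`, `coef`, `fitted` (the dense fitted
#'   mesh), `predict` (reprojected landmarks), `residuals`, `plot`.
#' @examples
#' model <- make_model(m = 150, k_id = 4, k_exp = 2, seed = 1)
#' truth <- sample_face(model, seed = 2)
#' pose <- face_pose(scale = 3, yaw = 0.2, translation = c(250, 300))
#' obs <- observe(construct_shape(model, truth), pose, model$correspondence,
#'                noise_sigma = 0, seed = 3)
#' fit <- fit_face(model, obs)
#' fit
#' @export
fit_face <- function(model, observed, correspondence = NULL,
                     config = fit_config()) {
  stopifnot(inherits(model, "morphable_model"), inherits(config, "fit_config"))
  if (!inherits(observed, "landmark_set"))
    observed <- landmark_set(landmark_points(observed), scheme = NULL, source = "matrix")
  corr <- correspondence %||% observed$scheme$correspondence %||% model$correspondence
  if (is.null(corr))
    stopf("no correspondence available: pass 'correspondence' or use a scheme/model that carries one")
  corr <- as.integer(corr)
  n <- nrow(observed$points)
  if (length(corr) != n)
    stopf("correspondence length %d does not match %d observed landmarks", length(corr), n)
  if (n < 3L) stopf("fitting needs at least 3 landmarks, got %d", n)
  k <- length(model$id_scale) + length(model$exp_scale)
  if (2L * n <= k)
    warning(sprintf("only %d landmarks for %d coefficients; fit is under-determined", n, k),
            call. = FALSE)

  coeffs <- shape_coefficients(numeric(length(model$id_scale)),
                               numeric(length(model$exp_scale)))
  mesh <- construct_shape(model, coeffs)
  pose <- config$init_pose %||%
    estimate_pose(mesh$vertices[, corr, drop = FALSE], observed$points)
  res <- fit_residual(model, pose, coeffs, observed, corr)
  trace <- res
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(config$max_iters)) {
    coeffs_new <- solve_coefficients(model, pose, observed$points, corr,
                                     config$lambda_id, config$lambda_exp)
    mesh_new <- construct_shape(model, coeffs_new)
    pose_new <- estimate_pose(mesh_new$vertices[, corr, drop = FALSE], observed$points)
    res_new <- fit_residual(model, pose_new, coeffs_new, observed, corr)
    if (res_new > res * (1 + 1e-12) + 1e-300) {
      # floating-point stall near the fixed point: keep the previous iterate
      converged <- TRUE
      break
    }
    iters <- it
    coeffs <- coeffs_new; pose <- pose_new
    trace <- c(trace, res_new)
    rel <- if (res > 0) (res - res_new) / res else 0
    res <- res_new
    if (rel < config$tol || res == 0) { converged <- TRUE; break }
  }
  structure(
    list(pose = pose, coefficients = coeffs,
         residual = res, residual_trace = trace,
         residual_unit = if (is.null(observed$scheme)) "px (RMSE)" else "% interocular distance",
         converged = converged, n_iters = iters,
         model = model, observed = observed, correspondence = corr,
         config = config),
    class = "face_fit")
}

#' @export
print.face_fit <- function(x, ...) {
  cat(sprintf("Morphable-model fit: %d landmarks, %d iterations (%s)\n",
              nrow(x$observed$points), x$n_iters,
              if (x$converged) "converged" else "max_iters reached"))
  cat(sprintf("  reprojection residual: %.6g %s\n", x$residual, x$residual_unit))
  cat(sprintf("  pose: f = %.4g, (pitch, yaw, roll) = (%.4g, %.4g, %.4g) rad\n",
              x$pose$scale, x$pose$pitch, x$pose$yaw, x$pose$roll))
  invisible(x)
}

#' @export
summary.face_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.face_fit")
}

#' @export
print.summary.face_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  print(f$pose)
  cat("  identity coefficients (sd units):\n   ")
  cat(sprintf(" %.4g", f$coefficients$alpha_id), "\n")
  cat("  expression coefficients (sd units):\n   ")
  cat(sprintf(" %.4g", f$coefficients$alpha_exp), "\n")
  cat(sprintf("  residual trace (%s): %s\n", f$residual_unit,
              paste(sprintf("%.4g", f$residual_trace), collapse = " -> ")))
  invisible(x)
}

#' @export
coef.face_fit <- function(object, ...) {
  c(stats::setNames(object$coefficients$alpha_id,
                    sprintf("id%d", seq_along(object$coefficients$alpha_id))),
    stats::setNames(object$coefficients$alpha_exp,
                    sprintf("exp%d", seq_along(object$coefficients$alpha_exp))))
}

#' @export
fitted.face_fit <- function(object, ...) construct_shape(object$model, object$coefficients)

#' Reproject the fitted landmarks
#'
#' @param object a [face_fit()] result.
#' @param ... unused.
#' @return A [landmark_set()] of the fitted model landmarks projected with
#'   the fitted pose (same scheme as the observations).
#' @export
predict.face_fit <- function(object, ...) {
  mesh <- fitted(object)
  pred <- project_points(mesh$vertices[, object$correspondence, drop = FALSE], object$pose)
  landmark_set(pred, object$observed$scheme, source = "face_fit")
}

#' @export
residuals.face_fit <- function(object, ...) {
  object$observed$points - predict(object)$points
}

#' @export
plot.face_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  obs <- x$observed$points
  pred <- predict(x)$points
  graphics::plot(obs[, 1L], -obs[, 2L], pch = 1, col = "grey40", asp = 1,
                 xlab = "u (px)", ylab = "-v (px)", main = "observed vs fitted landmarks", ...)
  graphics::points(pred[, 1L], -pred[, 2L], pch = 3, col = "firebrick")
  graphics::legend("topright", legend = c("observed", "fitted"), pch = c(1, 3),
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::plot(seq_along(x$residual_trace) - 1L, x$residual_trace, type = "b",
                 xlab = "iteration", ylab = sprintf("residual (%s)", x$residual_unit),
                 main = "residual trace", log = if (all(x$residual_trace > 0)) "y" else "")
  invisible(x)
}

#' Ocular-scaled reprojection error of a fit
#'
#' @param fit a [face_fit()] result.
#' @param observed optional [landmark_set()] to evaluate against (default:
#'   the observations the fit used).
#' @param indices optional landmark subset.
#' @return Percent-of-IOD RMSE, via [ocular_rmse()].
#' @export
reprojection_rmse <- function(fit, observed = NULL, indices = NULL) {
  stopifnot(inherits(fit, "face_fit"))
  observed <- observed %||% fit$observed
  ocular_rmse(predict(fit), observed, indices = indices)
}

#' Serialize a fit result as a flat key-value report
#'
#' @param fit a [face_fit()] result.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "face_fit"))
  con <- file(path, "wb")
  on.exit(close(con))
  kv <- c(sprintf("scale: %s", fmt_num(fit$pose$scale)),
          sprintf("pitch: %s", fmt_num(fit$pose$pitch)),
          sprintf("yaw: %s", fmt_num(fit$pose$yaw)),
          sprintf("roll: %s", fmt_num(fit$pose$roll)),
          sprintf("translation: %s", paste(fmt_num(fit$pose$translation), collapse = " ")),
          sprintf("alpha_id: %s", paste(fmt_num(fit$coefficients$alpha_id), collapse = " ")),
          sprintf("alpha_exp: %s", paste(fmt_num(fit$coefficients$alpha_exp), collapse = " ")),
          sprintf("residual: %s", fmt_num(fit$residual)),
          sprintf("residual_unit: %s", fit$residual_unit),
          sprintf("converged: %s", fit$converged),
          sprintf("n_iters: %d", fit$n_iters),
          sprintf("residual_trace: %s", paste(fmt_num(fit$residual_trace), collapse = " ")))
  writeLines(kv, con)
  invisible(path)
}

#' @rdname write_fit_report
#' @return `read_fit_report` returns a list with `pose`
#'   (a [face_pose()]), `coefficients` ([shape_coefficients()]),
#'   `residual`, `converged`, `n_iters` and `residual_trace`.
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stopf("fit report not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1L], collapse = ": "), ""),
                          vapply(kv, `[[`, "", 1L))
  nums <- function(key) as.numeric(strsplit(vals[[key]], " ", fixed = TRUE)[[1L]])
  list(pose = face_pose(scale = nums("scale"), pitch = nums("pitch"),
                        yaw = nums("yaw"), roll = nums("roll"),
                        translation = nums("translation")),
       coefficients = shape_coefficients(nums("alpha_id"), nums("alpha_exp")),
       residual = nums("residual"),
       converged = as.logical(vals[["converged"]]),
       n_iters = as.integer(vals[["n_iters"]]),
       residual_trace = nums("residual_trace"))
}
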