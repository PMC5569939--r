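# Synthetic morphable models and cohorts.
#
# Everything a private patient dataset and a licensed trained 3DMM would
# otherwise provide is generated here: small mirror-symmetric face models
# with designated eye/mouth landmark vertices, ground-truth faces and
# poses, palsy-like side-attenuated movement, noisy landmark observations,
# and multi-session cohorts with a recovery schedule.  Every generator is
# a pure function of its arguments and seed.

# 68-landmark 3D template in the iBUG ordering, mirror-symmetric about
# x = 0 by construction (left-half coordinates are reflected onto their
# partners, so symmetry is exact in floating point).  Units: mm; x lateral
# (+x = subject's right as seen in the image), y up, z towards the camera.
face68_template <- function() {
  mid <- list(  # index, y, z
    c(9, -76, 2), c(28, 30, 30), c(29, 20, 36), c(30, 10, 42), c(31, 0, 48),
    c(34, -11, 34), c(52, -30, 34), c(58, -47, 30), c(63, -35, 32), c(67, -41, 30))
  pairs <- list(  # left index, right index, x(<0), y, z
    c(1, 17, -72, 30, -40), c(2, 16, -70, 8, -36), c(3, 15, -66, -14, -32),
    c(4, 14, -59, -34, -26), c(5, 13, -48, -50, -18), c(6, 12, -34, -62, -10),
    c(7, 11, -19, -70, -4), c(8, 10, -7, -74, 0),
    c(18, 27, -52, 38, 8), c(19, 26, -43, 44, 14), c(20, 25, -33, 46, 18),
    c(21, 24, -23, 44, 20), c(22, 23, -13, 40, 22),
    c(32, 36, -12, -8, 26), c(33, 35, -6, -10, 30),
    c(37, 46, -45, 28, 10), c(38, 45, -38, 32, 14), c(39, 44, -30, 32, 15),
    c(40, 43, -24, 28, 14), c(41, 48, -30, 24, 14), c(42, 47, -38, 24, 13),
    c(49, 55, -26, -38, 22), c(50, 54, -16, -32, 28), c(51, 53, -7, -29, 32),
    c(60, 56, -16, -44, 26), c(59, 57, -7, -46, 28),
    c(61, 65, -20, -37, 24), c(62, 64, -7, -35, 30), c(68, 66, -7, -40, 29))
  v <- matrix(NA_real_, 3L, 68L)
  for (p in mid) v[, p[1L]] <- c(0, p[2L], p[3L])
  for (p in pairs) {
    v[, p[1L]] <- c(p[3L], p[4L], p[5L])
    v[, p[2L]] <- c(-p[3L], p[4L], p[5L])
  }
  mirror <- seq_len(68L)
  for (p in pairs) { mirror[p[1L]] <- p[2L]; mirror[p[2L]] <- p[1L] }
  list(vertices = v, mirror = as.integer(mirror))
}

# Gram-Schmidt a set of candidate columns against fixed columns and each
# other; returns an orthonormal matrix [fixed | new].
orthonormalize_against <- function(fixed, candidates) {
  Q <- fixed
  for (j in seq_len(ncol(candidates))) {
    w <- candidates[, j]
    for (pass in 1:2) w <- w - Q %*% crossprod(Q, w)  # twice for stability
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stopf("degenerate random basis draw; change the seed")
    Q <- cbind(Q, w / nw)
  }
  Q
}

#' Generate a synthetic morphable face model
#'
#' Builds a small mirror-symmetric face-like model: the first 68 vertices
#' follow the iBUG landmark layout (with eye and mouth clusters), the rest
#' fill the face in mirrored pairs, and the whole mean shape is exactly
#' symmetric about `x = 0`.  Identity and expression bases have
#' orthonormal columns with per-component standard deviations decaying
#' geometrically (ratio 0.8).  The first two expression components are
#' mirror-image lateralized displacement fields (supported on the left
#' and right half only, zero on the midline), so that side-attenuated
#' movement — the palsy simulation of [simulate_movement()] — stays
#' exactly inside the model span and remains fittable; this requires
#' `k_exp >= 2`.
#'
#' The model carries a 68-point landmark `correspondence` (the first 68
#' vertices) and a `mirror` attribute mapping each vertex to its mirror
#' partner (itself on the midline).
#'
#' @param m vertex count, at least 68.
#' @param k_id,k_exp identity / expression basis sizes (`k_exp >= 2`).
#' @param seed integer seed; the same seed reproduces the model
#'   bit-exactly.
#' @param name model label.
#' @return A [morphable_model()] (units mm).
#' @export
make_model <- function(m = 250L, k_id = 8L, k_exp = 4L, seed = 1L,
                       name = sprintf("synthetic-seed%d", seed)) {
  m <- as.integer(m)
  if (m < 68L) stopf("m = %d is too small to host the 68-point correspondence", m)
  if (k_id < 1L) stopf("'k_id' must be at least 1")
  if (k_exp < 2L)
    stopf("'k_exp' must be at least 2 (two lateralized expression components)")
  tpl <- face68_template()
  n_fill <- m - 68L
  n_pair <- n_fill %/% 2L
  with_seed(seed, {
    mean_shape <- matrix(0, 3L, m)
    mean_shape[, 1:68] <- tpl$vertices
    mirror <- c(tpl$mirror, rep(NA_integer_, n_fill))
    if (n_pair > 0L) {
      lx <- -stats::runif(n_pair, 5, 70)
      ly <- stats::runif(n_pair, -75, 45)
      lz <- stats::runif(n_pair, -40, 48)
      li <- 68L + seq_len(n_pair)
      ri <- 68L + n_pair + seq_len(n_pair)
      mean_shape[, li] <- rbind(lx, ly, lz)
      mean_shape[, ri] <- rbind(-lx, ly, lz)
      mirror[li] <- ri; mirror[ri] <- li
    }
    if (n_fill %% 2L == 1L) {
      i <- m
      mean_shape[, i] <- c(0, stats::runif(1, -75, 45), stats::runif(1, -40, 48))
      mirror[i] <- i
    }

    left <- which(mean_shape[1L, ] < 0)
    u1 <- numeric(3L * m)
    lrows <- as.vector(rbind(3L * left - 2L, 3L * left - 1L, 3L * left))
    u1[lrows] <- stats::rnorm(length(lrows))
    u1 <- u1 / sqrt(sum(u1^2))
    u2 <- numeric(3L * m)
    for (v in left) {
      p <- mirror[v]
      u2[3L * p - 2L] <- -u1[3L * v - 2L]  # x component flips under mirroring
      u2[3L * p - 1L] <- u1[3L * v - 1L]
      u2[3L * p] <- u1[3L * v]
    }
    exp_basis <- cbind(u1, u2)
    if (k_exp > 2L)
      exp_basis <- orthonormalize_against(exp_basis,
                                          matrix(stats::rnorm(3L * m * (k_exp - 2L)), ncol = k_exp - 2L))
    colnames(exp_basis) <- NULL

    id_basis <- qr.Q(qr(matrix(stats::rnorm(3L * m * k_id), ncol = k_id)))

    model <- morphable_model(
      mean_shape, id_basis, exp_basis,
      id_scale = 4 * 0.8^(seq_len(k_id) - 1L),
      exp_scale = 4 * 0.8^(seq_len(k_exp) - 1L),
      correspondence = 1:68, name = name, units = "mm")
    attr(model, "mirror") <- mirror
    model
  })
}

#' @noRd
sample_face_impl <- function(model) {
  shape_coefficients(stats::rnorm(length(model$id_scale)),
                     stats::rnorm(length(model$exp_scale)))
}

#' Draw a random face from the model prior
#'
#' Identity and expression coefficients are drawn i.i.d. standard normal
#' in sd units.
#'
#' @param model a [morphable_model()].
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @return A [shape_coefficients()].
#' @export
sample_face <- function(model, seed = NULL) {
  stopifnot(inherits(model, "morphable_model"))
  if (is.null(seed)) sample_face_impl(model)
  else with_seed(seed, sample_face_impl(model))
}

#' Simulate a prescribed facial movement with palsy-like asymmetry
#'
#' Produces a neutral mesh `S0` (the identity face: `alpha_exp = 0`) and
#' an end-range mesh `S1` displaced by the model's symmetric movement
#' field — the sum of the two lateralized expression components of
#' [make_model()], scaled to total L2 magnitude `amplitude`.  The
#' displacement of every vertex on the affected side is multiplied by the
#' attenuation factor `rho` (mirror vertices are unaffected; midline
#' vertices get the mean factor `(1 + rho) / 2`), emulating the one-sided
#' weakness of facial palsy.  With `rho = 1` (or `side = "none"`) the
#' movement is exactly mirror-symmetric.
#'
#' @param model a [make_model()] morphable model.
#' @param coeffs identity [shape_coefficients()] (the expression part is
#'   ignored: the neutral face has none).
#' @param amplitude total L2 magnitude of the movement field over the
#'   mesh, in model units; 0 gives `S1 == S0`.
#' @param side `"left"`, `"right"` or `"none"`: which side is affected.
#' @param attenuation `rho` in `[0, 1]`: 0 = no movement on the affected
#'   side, 1 = full movement.
#' @return `list(S0 = , S1 = )` of [face_mesh()] objects.
#' @export
simulate_movement <- function(model, coeffs, amplitude,
                              side = c("left", "right", "none"),
                              attenuation = 1) {
  stopifnot(inherits(model, "morphable_model"))
  side <- match.arg(side)
  if (amplitude < 0) stopf("'amplitude' must be non-negative")
  if (attenuation < 0 || attenuation > 1) stopf("'attenuation' must lie in [0, 1]")
  neutral <- shape_coefficients(coeffs$alpha_id, numeric(length(model$exp_scale)))
  S0 <- construct_shape(model, neutral)
  d <- amplitude * (model$exp_basis[, 1L] + model$exp_basis[, 2L])
  if (side != "none") {
    x <- model$mean_shape[1L, ]
    fac <- rep(1, model$vertex_count)
    affected <- if (side == "left") x < 0 else x > 0
    fac[affected] <- attenuation
    fac[x == 0] <- (1 + attenuation) / 2
    d <- d * rep(fac, each = 3L)
  }
  S1 <- face_mesh(S0$vertices + unflatten_vertices(d, model$vertex_count),
                  model$triangulation)
  list(S0 = S0, S1 = S1)
}

#' Observe a mesh as noisy 2D landmarks
#'
#' Projects the corresponded vertices with the given pose and adds i.i.d.
#' Gaussian pixel noise to each coordinate.
#'
#' @param mesh a [face_mesh()].
#' @param pose a [face_pose()].
#' @param corr model vertex indices of the landmarks (e.g.
#'   `model$correspondence`).
#' @param noise_sigma noise standard deviation in pixels (`>= 0`).
#' @param seed integer seed; `NULL` uses the current RNG.
#' @param scheme scheme for the returned set; defaults to the packaged
#'   iBUG-68 scheme when `length(corr) == 68`.
#' @return A [landmark_set()].
#' @export
observe <- function(mesh, pose, corr, noise_sigma = 0, seed = NULL, scheme = NULL) {
  stopifnot(inherits(mesh, "face_mesh"), inherits(pose, "face_pose"))
  if (noise_sigma < 0) stopf("'noise_sigma' must be non-negative")
  corr <- as.integer(corr)
  pts <- project_points(mesh$vertices[, corr, drop = FALSE], pose)
  add_noise <- function() {
    if (noise_sigma > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), sd = noise_sigma), ncol = 2L)
    pts
  }
  pts <- if (is.null(seed)) add_noise() else with_seed(seed, add_noise())
  if (is.null(scheme) && length(corr) == 68L) scheme <- ibug68_scheme(correspondence = corr)
  landmark_set(pts, scheme, source = "synthetic observation")
}

#' Generate a synthetic patient cohort on disk
#'
#' Stands in for a clinical dataset: `n_subjects` synthetic patients, each
#' with an identity drawn from the model prior and a fixed affected side
#' (alternating left/right by subject), observed over `n_sessions`
#' evaluation sessions.  The attenuation of the affected side increases
#' linearly from `rho0` at the baseline session to 1 at the last
#' (simulated recovery), so region motion grows monotonically.  Each
#' session has its own head pose; neutral and end-range captures within a
#' session share it.
#'
#' Layout written under `dir`: `model.txt` (the morphable model),
#' `regions.yaml` (quadrant rules), per subject/session
#' `subject_SS/session_K/{neutral.pts, endrange.pts,
#' neutral_truth_synthetic.obj, endrange_truth_synthetic.obj}` (the OBJ
#' files are the synthetic ground-truth meshes), and `manifest.csv`.
#'
#' @param dir output directory (created if needed).
#' @param n_subjects,n_sessions cohort dimensions (each `>= 1`).
#' @param seed master seed; the whole cohort is reproducible from it.
#' @param m,k_id,k_exp model dimensions passed to [make_model()].
#' @param amplitude movement-field magnitude (see [simulate_movement()]).
#' @param rho0 baseline attenuation of the affected side.
#' @param noise_sigma landmark observation noise in pixels.
#' @return The manifest `data.frame`, invisibly.
#' @export
make_cohort <- function(dir, n_subjects = 6L, n_sessions = 3L, seed = 1L,
                        m = 250L, k_id = 8L, k_exp = 4L,
                        amplitude = 30, rho0 = 0.4, noise_sigma = 0) {
  if (n_subjects < 1L || n_sessions < 1L) stopf("need at least 1 subject and 1 session")
  if (rho0 < 0 || rho0 > 1) stopf("'rho0' must lie in [0, 1]")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create output directory: %s", dir)

  model <- make_model(m = m, k_id = k_id, k_exp = k_exp, seed = seed)
  save_model(model, file.path(dir, "model.txt"))
  quad <- c("upper_left", "upper_right", "lower_left", "lower_right")
  yaml::write_yaml(list(regions = stats::setNames(
    lapply(c(quad, "left", "right"), function(r) list(rule = r)),
    c(quad, "left", "right"))), file.path(dir, "regions.yaml"))

  rows <- list()
  for (s in seq_len(n_subjects)) {
    side <- if (s %% 2L == 1L) "left" else "right"
    coeffs <- sample_face(model, seed = seed * 1000L + s)
    sdir <- file.path(dir, sprintf("subject_%02d", s))
    for (k in seq_len(n_sessions)) {
      rho <- if (n_sessions == 1L) rho0 else rho0 + (1 - rho0) * (k - 1) / (n_sessions - 1)
      kdir <- file.path(sdir, sprintf("session_%d", k))
      dir.create(kdir, recursive = TRUE, showWarnings = FALSE)
      pose <- with_seed(seed * 1000L + s * 37L + k, {
        face_pose(scale = stats::runif(1, 2.5, 3.5),
                  pitch = stats::runif(1, -0.15, 0.15),
                  yaw = stats::runif(1, -0.2, 0.2),
                  roll = stats::runif(1, -0.1, 0.1),
                  translation = stats::runif(2, 200, 400))
      })
      mv <- simulate_movement(model, coeffs, amplitude, side, rho)
      obs0 <- observe(mv$S0, pose, model$correspondence, noise_sigma,
                      seed = seed * 1000L + s * 97L + 2L * k)
      obs1 <- observe(mv$S1, pose, model$correspondence, noise_sigma,
                      seed = seed * 1000L + s * 97L + 2L * k + 1L)
      write_pts(obs0, file.path(kdir, "neutral.pts"))
      write_pts(obs1, file.path(kdir, "endrange.pts"))
      export_mesh(mv$S0, file.path(kdir, "neutral_truth_synthetic.obj"))
      export_mesh(mv$S1, file.path(kdir, "endrange_truth_synthetic.obj"))
      rel <- function(f) file.path(sprintf("subject_%02d", s), sprintf("session_%d", k), f)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("subject_%02d", s), session = k, side = side,
        attenuation = rho, amplitude = amplitude, noise_sigma = noise_sigma,
        neutral_pts = rel("neutral.pts"), endrange_pts = rel("endrange.pts"),
        neutral_mesh = rel("neutral_truth_synthetic.obj"),
        endrange_mesh = rel("endrange_truth_synthetic.obj"),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
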