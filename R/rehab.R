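#' Clinician-defined mesh regions
#'
#' A region is a named set of model vertex indices over which facial
#' motion is aggregated.  Facial palsy affects movement asymmetrically
#' between the left and right side, and often unequally between the upper
#' (eye/brow) and lower (mouth) face, so regions are typically halves or
#' quadrants.
#'
#' @param name region label (e.g. `"upper_left"`, `"lower_right"`).
#' @param indices unique 1-based vertex indices, non-empty.
#' @return An object of class `region_index`.
#' @export
region_index <- function(name, indices) {
  indices <- as.integer(indices)
  if (!length(indices)) stopf("region '%s' is empty", name)
  if (anyNA(indices) || any(indices < 1L)) stopf("region '%s' has invalid indices", name)
  if (anyDuplicated(indices)) stopf("region '%s' has duplicate indices", name)
  structure(list(name = name, indices = indices), class = "region_index")
}

#' @export
print.region_index <- function(x, ...) {
  cat(sprintf("Region '%s': %d vertices\n", x$name, length(x$indices)))
  invisible(x)
}

# Resolve a half-plane / quadrant rule against a mesh or model.  x is the
# lateral axis (the models here are mirror-symmetric about x = 0, so the
# lateral centroid is 0); the vertical split is relative to the centroid.
# Boundary vertices (exactly on a split) belong to no side.
resolve_rule <- function(rule, vertices) {
  cx <- mean(vertices[1L, ]); cy <- mean(vertices[2L, ])
  x <- vertices[1L, ]; y <- vertices[2L, ]
  sel <- switch(rule,
    left        = x < cx,
    right       = x > cx,
    upper       = y > cy,
    lower       = y < cy,
    upper_left  = x < cx & y > cy,
    upper_right = x > cx & y > cy,
    lower_left  = x < cx & y < cy,
    lower_right = x > cx & y < cy,
    stopf("unknown region rule '%s'", rule))
  which(sel)
}

#' Build standard regions from a model's geometry
#'
#' @param model a [morphable_model()] or [face_mesh()].
#' @param rules character vector of rule names among `left`, `right`,
#'   `upper`, `lower` and the four quadrants.
#' @return A named list of [region_index()] objects.
#' @export
face_regions <- function(model,
                         rules = c("upper_left", "upper_right",
                                   "lower_left", "lower_right")) {
  vertices <- if (inherits(model, "morphable_model")) model$mean_shape
              else if (inherits(model, "face_mesh")) model$vertices
              else stopf("'model' must be a morphable_model or face_mesh")
  out <- lapply(rules, function(r) {
    idx <- resolve_rule(r, vertices)
    if (!length(idx)) stopf("region rule '%s' selects no vertices", r)
    region_index(r, idx)
  })
  stats::setNames(out, rules)
}

#' Load clinician-defined regions from a YAML config
#'
#' Each entry under `regions:` is either an explicit 1-based index list
#' (`indices: [..]`) or a half-plane rule (`rule: lower_left`), resolved
#' deterministically against the model geometry.
#'
#' @param path YAML file.
#' @param model a [morphable_model()] or [face_mesh()] rules are resolved
#'   against.
#' @return A named list of [region_index()] objects.
#' @export
load_regions <- function(path, model) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions) || !length(cfg$regions))
    stopf("region config has no 'regions' entries: %s", path)
  vertices <- if (inherits(model, "morphable_model")) model$mean_shape
              else if (inherits(model, "face_mesh")) model$vertices
              else stopf("'model' must be a morphable_model or face_mesh")
  out <- lapply(names(cfg$regions), function(nm) {
    e <- cfg$regions[[nm]]
    idx <- if (!is.null(e$indices)) as.integer(e$indices)
           else if (!is.null(e$rule)) resolve_rule(e$rule, vertices)
           else stopf("region '%s' defines neither 'indices' nor 'rule'", nm)
    if (!length(idx)) stopf("region '%s' resolves to no vertices", nm)
    if (any(idx > ncol(vertices)))
      stopf("region '%s' has indices beyond m = %d", nm, ncol(vertices))
    region_index(nm, idx)
  })
  stats::setNames(out, names(cfg$regions))
}

#' Region-based facial motion between two meshes
#'
#' Measures a prescribed movement as the per-vertex squared Euclidean
#' displacement between the neutral mesh `S0` and the end-range mesh `S1`,
#' aggregated over each region as a sum and a mean (the mean is the
#' headline statistic: it is invariant to region size).  Both meshes must
#' be expressed in model space — fitted meshes from [fit_face()] are
#' pose-free by construction — so rigid head motion between captures does
#' not contaminate the measurement; a residual global translation shows up
#' as equal motion in every region.
#'
#' @param S0 neutral-expression [face_mesh()] (or `3 x m` matrix).
#' @param S1 end-range [face_mesh()] of the prescribed movement.
#' @param regions list of [region_index()] objects (see [face_regions()]).
#' @param session_id label for this evaluation session.
#' @param units units label for reports (squared displacement is in these
#'   units squared).
#' @return An object of class `face_evaluation`: a per-region table with
#'   `n_vertices`, `E_sum` and `E_mean`.
#' @export
motion_magnitude <- function(S0, S1, regions, session_id = "session_1",
                             units = "model units") {
  v0 <- if (inherits(S0, "face_mesh")) S0$vertices else as.matrix(S0)
  v1 <- if (inherits(S1, "face_mesh")) S1$vertices else as.matrix(S1)
  if (!identical(dim(v0), dim(v1)))
    stopf("meshes have different dimensions (%s vs %s)",
          paste(dim(v0), collapse = "x"), paste(dim(v1), collapse = "x"))
  m <- ncol(v0)
  d2 <- colSums((v1 - v0)^2)  # per-vertex squared displacement
  rows <- lapply(regions, function(r) {
    stopifnot(inherits(r, "region_index"))
    if (any(r$indices > m))
      stopf("region '%s' has indices beyond m = %d", r$name, m)
    e <- d2[r$indices]
    data.frame(region = r$name, n_vertices = length(e),
               E_sum = sum(e), E_mean = mean(e), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(session_id = session_id, regions = tab, units = units),
            class = "face_evaluation")
}

#' @export
print.face_evaluation <- function(x, ...) {
  cat(sprintf("Motion evaluation '%s' (squared %s):\n", x$session_id, x$units))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

region_table <- function(ev) {
  stopifnot(inherits(ev, "face_evaluation"))
  ev$regions
}

#' Rehabilitation progress across evaluation sessions
#'
#' For each session after the pre-rehabilitation baseline and each region,
#' the progress measure is the change in mean motion relative to baseline,
#' `R = E_mean(session) - E_mean(baseline)`.  Positive `R` means the
#' region moves more than it did before rehabilitation; the sign is
#' reported without clinical interpretation (hyperkinetic recovery can
#' legitimately reduce motion).
#'
#' @param series list of [motion_magnitude()] evaluations in session
#'   order; the first is the baseline.  All sessions must share the same
#'   region set.
#' @return A `data.frame` with columns `session`, `region`, `E_mean`, `R`
#'   (baseline rows have `R = 0`).
#' @export
rehab_progress <- function(series) {
  if (!is.list(series) || length(series) < 2L)
    stopf("'series' needs at least 2 sessions (baseline + follow-up)")
  base <- region_table(series[[1L]])
  ids <- vapply(series, function(e) e$session_id, "")
  if (anyDuplicated(ids)) stopf("session ids must be unique")
  out <- lapply(series, function(ev) {
    tab <- region_table(ev)
    if (!identical(tab$region, base$region))
      stopf("session '%s' has a different region set than the baseline", ev$session_id)
    data.frame(session = ev$session_id, region = tab$region,
               E_mean = tab$E_mean, R = tab$E_mean - base$E_mean,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Left/right motion asymmetry index
#'
#' A dimensionless lateralization summary,
#' `(E_mean(right) - E_mean(left)) / (E_mean(right) + E_mean(left))`:
#' 0 for symmetric motion, +1 for fully right-lateralized, -1 for fully
#' left-lateralized.  Because motion is measured as squared displacement,
#' a side whose movement amplitude is attenuated by a factor `rho`
#' contributes `rho^2` of the healthy side's motion, giving an index of
#' `(1 - rho^2) / (1 + rho^2)` for mirrored regions.
#'
#' @param evaluation a [motion_magnitude()] result.
#' @param left_region,right_region region names present in the evaluation.
#' @return Scalar in `[-1, 1]`, or `NA` with a warning when both regions
#'   show zero motion (asymmetry is undefined, not zero).
#' @export
asymmetry_index <- function(evaluation, left_region, right_region) {
  tab <- region_table(evaluation)
  pick <- function(nm) {
    i <- match(nm, tab$region)
    if (is.na(i)) stopf("region '%s' not present in evaluation", nm)
    tab$E_mean[[i]]
  }
  l <- pick(left_region); r <- pick(right_region)
  if (l + r <= 0) {
    warning("both regions show zero motion: asymmetry is undefined", call. = FALSE)
    return(NA_real_)
  }
  (r - l) / (r + l)
}

#' Recover an attenuation factor from an asymmetry index
#'
#' Inverts the `(1 - rho^2) / (1 + rho^2)` relationship of
#' [asymmetry_index()]: `rho_hat = sqrt((1 - |a|) / (1 + |a|))` estimates
#' by how much the affected side's movement amplitude is attenuated
#' relative to the healthy side.
#'
#' @param a asymmetry index in `[-1, 1]`.
#' @return Estimated attenuation in `[0, 1]`.
#' @export
attenuation_from_asymmetry <- function(a) {
  check_finite(a, "a")
  if (any(abs(a) > 1)) stopf("asymmetry index must lie in [-1, 1]")
  sqrt((1 - abs(a)) / (1 + abs(a)))
}
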