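#' Landmark schemes
#'
#' A scheme names an ordered set of 2D facial landmarks and its semantic
#' subsets.  The subsets `"left_eye"`, `"right_eye"` and `"mouth"` are
#' required: the eyes define the interocular distance used for error
#' normalization, and the mouth subset drives the hybrid merge of two
#' fitters' outputs.  All indices are 1-based.
#'
#' @param size number of landmarks.
#' @param name scheme label.
#' @param subsets named list of integer index vectors into `1:size`;
#'   must contain non-empty `mouth` and non-empty, disjoint `left_eye`
#'   and `right_eye`.
#' @param correspondence optional integer vector of model vertex indices,
#'   one per landmark.
#' @return An object of class `landmark_scheme`.
#' @export
landmark_scheme <- function(size, name, subsets, correspondence = NULL) {
  size <- as.integer(size)
  if (size < 1L) stopf("'size' must be positive")
  if (!is.list(subsets) || is.null(names(subsets)))
    stopf("'subsets' must be a named list of index vectors")
  subsets <- lapply(subsets, as.integer)
  for (nm in names(subsets)) {
    s <- subsets[[nm]]
    if (anyNA(s) || any(s < 1L) || any(s > size))
      stopf("subset '%s' has indices outside [1, %d]", nm, size)
    if (anyDuplicated(s)) stopf("subset '%s' has duplicate indices", nm)
  }
  for (nm in c("mouth", "left_eye", "right_eye")) {
    if (is.null(subsets[[nm]]) || !length(subsets[[nm]]))
      stopf("scheme must define a non-empty '%s' subset", nm)
  }
  if (length(intersect(subsets$left_eye, subsets$right_eye)))
    stopf("'left_eye' and 'right_eye' subsets must be disjoint")
  if (!is.null(correspondence)) {
    correspondence <- as.integer(correspondence)
    if (length(correspondence) != size)
      stopf("'correspondence' length %d does not match scheme size %d",
            length(correspondence), size)
  }
  structure(list(size = size, name = name, subsets = subsets,
                 correspondence = correspondence),
            class = "landmark_scheme")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat(sprintf("Landmark scheme '%s': %d points; subsets: %s\n", x$name, x$size,
              paste(sprintf("%s(%d)", names(x$subsets),
                            lengths(x$subsets)), collapse = ", ")))
  invisible(x)
}

#' Read a landmark scheme from a YAML config
#'
#' The file holds `name`, `size` and a `subsets` map of 1-based index
#' lists.  The packaged default (`scheme_ibug68.yaml`) is the 68-point
#' iBUG convention with mouth 49-68 and eyes 37-42 / 43-48.
#'
#' @param path YAML file; see `system.file("extdata", "scheme_ibug68.yaml",
#'   package = "palsy3d")` for the layout.
#' @param correspondence optional correspondence passed through.
#' @return A [landmark_scheme()].
#' @export
scheme_from_yaml <- function(path, correspondence = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$size) || is.null(cfg$subsets))
    stopf("scheme config must define 'size' and 'subsets': %s", path)
  landmark_scheme(cfg$size, cfg$name %||% basename(path), cfg$subsets,
                  correspondence = correspondence)
}

#' The 68-point iBUG landmark scheme
#'
#' @param correspondence optional model-vertex correspondence (e.g.
#'   `model$correspondence` from [make_model()]).
#' @return A [landmark_scheme()] of size 68.
#' @export
ibug68_scheme <- function(correspondence = NULL) {
  path <- system.file("extdata", "scheme_ibug68.yaml", package = "palsy3d")
  scheme_from_yaml(path, correspondence = correspondence)
}

#' An ordered set of observed 2D landmarks
#'
#' @param points `n x 2` numeric matrix of pixel coordinates (u right,
#'   v down, origin top-left).
#' @param scheme a [landmark_scheme()] with `size == nrow(points)`, or
#'   `NULL` for a bare point set (subset-based operations then error).
#' @param source free-text label recording which fitter produced the set.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, scheme = NULL, source = "unknown") {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stopf("'points' must have two columns (u, v)")
  storage.mode(points) <- "double"
  check_finite(points, "points")
  colnames(points) <- c("u", "v")
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "landmark_scheme"))
    if (nrow(points) != scheme$size)
      stopf("point count %d does not match scheme '%s' size %d",
            nrow(points), scheme$name, scheme$size)
  }
  structure(list(points = points, scheme = scheme, source = source),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set: %d points (%s), source: %s\n", nrow(x$points),
              if (is.null(x$scheme)) "no scheme" else x$scheme$name, x$source))
  invisible(x)
}

check_same_scheme <- function(a, b) {
  stopifnot(inherits(a, "landmark_set"), inherits(b, "landmark_set"))
  if (nrow(a$points) != nrow(b$points))
    stopf("landmark sets have different sizes (%d vs %d)", nrow(a$points), nrow(b$points))
  an <- if (is.null(a$scheme)) NA_character_ else a$scheme$name
  bn <- if (is.null(b$scheme)) NA_character_ else b$scheme$name
  if (!identical(an, bn))
    stopf("landmark sets use different schemes ('%s' vs '%s')", an, bn)
  invisible(TRUE)
}

#' Hybrid merge of two landmark fitters' outputs
#'
#' Takes the points of `secondary` on the named subset (the mouth by
#' default, where mouth-specialised fitters do better) and the points of
#' `primary` everywhere else.  Scheme, ordering and all non-subset points
#' are exactly those of `primary`.
#'
#' @param primary,secondary [landmark_set()]s on the same scheme.
#' @param subset_name subset of the scheme to take from `secondary`.
#' @return A merged [landmark_set()]; `source` records both inputs.
#' @export
merge_hybrid <- function(primary, secondary, subset_name = "mouth") {
  check_same_scheme(primary, secondary)
  if (is.null(primary$scheme)) stopf("hybrid merge requires a scheme")
  idx <- primary$scheme$subsets[[subset_name]]
  if (is.null(idx)) stopf("scheme '%s' has no subset '%s'", primary$scheme$name, subset_name)
  pts <- primary$points
  pts[idx, ] <- secondary$points[idx, ]
  landmark_set(pts, primary$scheme,
               source = sprintf("hybrid(%s on %s, else %s)",
                                secondary$source, subset_name, primary$source))
}

# ---- .pts I/O --------------------------------------------------------------

#' Read / write iBUG-style .pts landmark files
#'
#' The dialect is: a `version: 1` header, `n_points: N`, then `N`
#' whitespace-separated coordinate lines between `{` and `}`.  The reader
#' tolerates CRLF line endings and trailing whitespace; coordinates are
#' stored as written (points are positional, no index shifting).  The
#' writer prints 6 decimals, so a round trip preserves coordinates to
#' better than 1e-6.
#'
#' @param path file path.
#' @param scheme optional [landmark_scheme()]; if `NULL` and the file has
#'   68 points, the packaged iBUG-68 scheme is attached.
#' @return `read_pts` returns a [landmark_set()]; `write_pts` returns
#'   `path` invisibly.
#' @export
read_pts <- function(path, scheme = NULL) {
  if (!file.exists(path)) stopf("landmark file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE), which = "right")
  if (length(lines) < 4L || !grepl("^version:", lines[[1L]]))
    stopf("%s: line 1: expected 'version: 1' header", path)
  if (!grepl("^n_points:", lines[[2L]]))
    stopf("%s: line 2: expected 'n_points: N'", path)
  n <- as.integer(trimws(sub("^n_points:", "", lines[[2L]])))
  if (is.na(n) || n < 1L) stopf("%s: line 2: invalid point count", path)
  if (trimws(lines[[3L]]) != "{") stopf("%s: line 3: expected '{'", path)
  if (length(lines) < 3L + n + 1L)
    stopf("%s: declared n_points: %d but file ends at line %d", path, n, length(lines))
  body <- lines[4:(3L + n)]
  if (trimws(lines[[3L + n + 1L]]) != "}")
    stopf("%s: line %d: expected '}' after %d points", path, 3L + n + 1L, n)
  coords <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[[i]]), "[ \t]+")[[1L]]))
    if (length(v) != 2L || anyNA(v))
      stopf("%s: line %d: expected two numeric coordinates", path, i + 3L)
    v
  })
  pts <- do.call(rbind, coords)
  if (is.null(scheme) && n == 68L) scheme <- ibug68_scheme()
  landmark_set(pts, scheme, source = basename(path))
}

#' @rdname read_pts
#' @param set a [landmark_set()] (or bare `n x 2` matrix).
#' @export
write_pts <- function(set, path) {
  pts <- landmark_points(set)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("version: 1", sprintf("n_points: %d", nrow(pts)), "{",
               sprintf("%.6f %.6f", pts[, 1L], pts[, 2L]), "}"), con)
  invisible(path)
}

# ---- error evaluation ------------------------------------------------------

#' Interocular distance of a landmark set
#'
#' Euclidean distance between the centroids of the `left_eye` and
#' `right_eye` subsets.  Centroids (rather than single corner landmarks)
#' make the measure robust to noise in any one landmark; alternative
#' conventions are expressible by redefining the eye subsets.
#'
#' @param set a [landmark_set()] whose scheme defines eye subsets.
#' @return Positive scalar, in pixels.
#' @export
interocular_distance <- function(set) {
  stopifnot(inherits(set, "landmark_set"))
  if (is.null(set$scheme)) stopf("interocular distance requires a scheme with eye subsets")
  le <- colMeans(set$points[set$scheme$subsets$left_eye, , drop = FALSE])
  re <- colMeans(set$points[set$scheme$subsets$right_eye, , drop = FALSE])
  d <- sqrt(sum((le - re)^2))
  if (d <= 0) stopf("degenerate geometry: eye centroids coincide")
  d
}

#' Ocular-scaled landmark RMSE
#'
#' Root-mean-square Euclidean landmark error normalized by the truth's
#' interocular distance and expressed as a percentage, which makes errors
#' comparable across images with different face sizes:
#' \deqn{100 \cdot \sqrt{\tfrac{1}{n}\sum_i \|p_i - t_i\|^2} / \mathrm{IOD}(t)}
#'
#' @param pred,truth [landmark_set()]s on the same scheme.
#' @param indices optional subset of landmark indices to evaluate
#'   (default: all); the IOD always comes from the full truth set.
#' @return Non-negative scalar, percent of interocular distance.
#' @export
ocular_rmse <- function(pred, truth, indices = NULL) {
  check_same_scheme(pred, truth)
  iod <- interocular_distance(truth)
  indices <- indices %||% seq_len(nrow(truth$points))
  d2 <- rowSums((pred$points[indices, , drop = FALSE] -
                 truth$points[indices, , drop = FALSE])^2)
  100 * sqrt(mean(d2)) / iod
}

#' Per-landmark ocular-scaled error
#'
#' Euclidean error of each landmark as a percentage of the truth's
#' interocular distance.  The quadratic mean of this vector equals
#' [ocular_rmse()] over all landmarks.
#'
#' @inheritParams ocular_rmse
#' @return Numeric vector of length `scheme$size`.
#' @export
per_landmark_error <- function(pred, truth) {
  check_same_scheme(pred, truth)
  iod <- interocular_distance(truth)
  100 * sqrt(rowSums((pred$points - truth$points)^2)) / iod
}

#' Per-subject landmark accuracy report
#'
#' One row per subject with its ocular-scaled RMSE, plus a `"total"` row.
#' The headline total pools the per-landmark errors of all subjects (each
#' normalized by its own subject's IOD) into one quadratic mean; the
#' `subject_mean` column of the total row is the unweighted mean of the
#' per-subject RMSEs, since either convention is found in practice.
#'
#' @param pairs non-empty list, each element `list(pred = , truth = )` of
#'   [landmark_set()]s; element names become subject ids.
#' @param file optional path: the report is also written as CSV.
#' @return A `data.frame` with columns `subject`, `n_landmarks`,
#'   `ocular_rmse`, `subject_mean`.
#' @export
per_subject_report <- function(pairs, file = NULL) {
  if (!is.list(pairs) || !length(pairs)) stopf("'pairs' must be a non-empty list")
  ids <- names(pairs) %||% sprintf("subject_%d", seq_along(pairs))
  if (any(ids == "")) ids[ids == ""] <- sprintf("subject_%d", which(ids == ""))
  per <- lapply(pairs, function(p) per_landmark_error(p$pred, p$truth))
  rmse <- vapply(per, function(e) sqrt(mean(e^2)), 1.0)
  pooled <- sqrt(mean(unlist(per)^2))
  out <- data.frame(subject = c(ids, "total"),
                    n_landmarks = c(lengths(per), sum(lengths(per))),
                    ocular_rmse = c(rmse, pooled),
                    subject_mean = c(rep(NA_real_, length(per)), mean(rmse)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
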