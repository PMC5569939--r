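#' Linear 3D morphable face model
#'
#' A morphable model represents 3D face shape as a mean mesh plus linear
#' identity and expression variation:
#' \deqn{S = \bar{S} + A_{id} (\alpha_{id} \odot \sigma_{id})
#'           + A_{exp} (\alpha_{exp} \odot \sigma_{exp})}
#' where the columns of `id_basis` and `exp_basis` are principal axes of
#' shape variation and `id_scale` / `exp_scale` are the per-component
#' standard deviations.  Coefficients are therefore dimensionless,
#' expressed in standard-deviation units, which makes ridge penalties in
#' the fitter scale-free.
#'
#' Basis matrices are stored flattened: row `3*(v-1)+c` of a basis holds
#' coordinate `c` (1 = x, 2 = y, 3 = z) of vertex `v`, i.e. the column-major
#' flattening of a `3 x m` vertex matrix.
#'
#' @param mean_shape `3 x m` numeric matrix of mean vertex coordinates
#'   (model units; x is the lateral axis, y vertical, z depth).
#' @param id_basis `(3m) x k_id` matrix of identity principal axes.
#' @param exp_basis `(3m) x k_exp` matrix of expression principal axes.
#' @param id_scale,exp_scale strictly positive per-component standard
#'   deviations, lengths `k_id` / `k_exp`.
#' @param triangulation optional integer matrix with 3 columns of 1-based
#'   vertex indices (one triangle per row).
#' @param correspondence optional integer vector of model vertex indices,
#'   one per landmark of a 2D landmark scheme.
#' @param name,units metadata labels carried through reports.
#' @return An object of class `morphable_model`.
#' @seealso [construct_shape()], [fit_face()], [make_model()]
#' @export
morphable_model <- function(mean_shape, id_basis, exp_basis, id_scale, exp_scale,
                            triangulation = NULL, correspondence = NULL,
                            name = "morphable model", units = "model units") {
  mean_shape <- as.matrix(mean_shape)
  if (nrow(mean_shape) != 3L) stopf("'mean_shape' must be a 3 x m matrix, got %d rows", nrow(mean_shape))
  m <- ncol(mean_shape)
  id_basis <- as.matrix(id_basis); exp_basis <- as.matrix(exp_basis)
  id_scale <- as.numeric(id_scale); exp_scale <- as.numeric(exp_scale)
  check_finite(mean_shape, "mean_shape")
  check_finite(id_basis, "id_basis"); check_finite(exp_basis, "exp_basis")
  check_finite(id_scale, "id_scale"); check_finite(exp_scale, "exp_scale")
  if (nrow(id_basis) != 3L * m) stopf("'id_basis' has %d rows; expected 3*m = %d", nrow(id_basis), 3L * m)
  if (nrow(exp_basis) != 3L * m) stopf("'exp_basis' has %d rows; expected 3*m = %d", nrow(exp_basis), 3L * m)
  if (ncol(id_basis) != length(id_scale))
    stopf("'id_scale' length %d does not match id_basis columns (%d)", length(id_scale), ncol(id_basis))
  if (ncol(exp_basis) != length(exp_scale))
    stopf("'exp_scale' length %d does not match exp_basis columns (%d)", length(exp_scale), ncol(exp_basis))
  if (any(id_scale <= 0)) stopf("'id_scale' must be strictly positive")
  if (any(exp_scale <= 0)) stopf("'exp_scale' must be strictly positive")
  if (!is.null(triangulation)) {
    triangulation <- matrix(as.integer(triangulation), ncol = 3L)
    if (anyNA(triangulation) || any(triangulation < 1L) || any(triangulation > m))
      stopf("'triangulation' indices must lie in [1, m = %d]", m)
  }
  if (!is.null(correspondence)) {
    correspondence <- as.integer(correspondence)
    if (anyNA(correspondence) || any(correspondence < 1L) || any(correspondence > m))
      stopf("'correspondence' indices must lie in [1, m = %d]", m)
  }
  structure(
    list(vertex_count = m, mean_shape = mean_shape,
         id_basis = id_basis, exp_basis = exp_basis,
         id_scale = id_scale, exp_scale = exp_scale,
         triangulation = triangulation, correspondence = correspondence,
         name = name, units = units),
    class = "morphable_model")
}

#' @export
print.morphable_model <- function(x, ...) {
  cat(sprintf("Morphable face model '%s': %d vertices, %d identity + %d expression components (%s)\n",
              x$name, x$vertex_count, length(x$id_scale), length(x$exp_scale), x$units))
  if (!is.null(x$triangulation)) cat(sprintf("  triangulation: %d faces\n", nrow(x$triangulation)))
  if (!is.null(x$correspondence)) cat(sprintf("  landmark correspondence: %d points\n", length(x$correspondence)))
  invisible(x)
}

#' Shape coefficients for a morphable model
#'
#' Coefficients are in standard-deviation units: a value of 1 moves the
#' shape one trained standard deviation along that component.
#'
#' @param alpha_id numeric vector of identity coefficients.
#' @param alpha_exp numeric vector of expression coefficients.
#' @return An object of class `shape_coefficients`.
#' @export
shape_coefficients <- function(alpha_id, alpha_exp) {
  alpha_id <- as.numeric(alpha_id); alpha_exp <- as.numeric(alpha_exp)
  check_finite(alpha_id, "alpha_id"); check_finite(alpha_exp, "alpha_exp")
  structure(list(alpha_id = alpha_id, alpha_exp = alpha_exp),
            class = "shape_coefficients")
}

#' @export
print.shape_coefficients <- function(x, ...) {
  cat(sprintf("Shape coefficients: %d identity, %d expression (sd units)\n",
              length(x$alpha_id), length(x$alpha_exp)))
  invisible(x)
}

#' A concrete 3D face mesh
#'
#' @param vertices `3 x m` numeric matrix of vertex coordinates.
#' @param triangulation optional triangle index matrix (see
#'   [morphable_model()]), usually inherited from the generating model.
#' @return An object of class `face_mesh`.
#' @export
face_mesh <- function(vertices, triangulation = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != 3L) stopf("'vertices' must be a 3 x m matrix")
  check_finite(vertices, "vertices")
  structure(list(vertices = vertices, triangulation = triangulation),
            class = "face_mesh")
}

#' @export
print.face_mesh <- function(x, ...) {
  cat(sprintf("Face mesh: %d vertices%s\n", ncol(x$vertices),
              if (is.null(x$triangulation)) "" else sprintf(", %d faces", nrow(x$triangulation))))
  invisible(x)
}

#' Evaluate the morphable model at given coefficients
#'
#' Computes `mean_shape + id_basis %*% (alpha_id * id_scale) +
#' exp_basis %*% (alpha_exp * exp_scale)`, reshaped back to a `3 x m`
#' vertex matrix.  The map is affine in the coefficients and exactly the
#' mean shape at zero.
#'
#' @param model a [morphable_model()].
#' @param coeffs a [shape_coefficients()] whose lengths match the model's
#'   basis dimensions.
#' @return A [face_mesh()].
#' @export
construct_shape <- function(model, coeffs) {
  stopifnot(inherits(model, "morphable_model"), inherits(coeffs, "shape_coefficients"))
  if (length(coeffs$alpha_id) != length(model$id_scale))
    stopf("alpha_id length %d does not match model k_id = %d",
          length(coeffs$alpha_id), length(model$id_scale))
  if (length(coeffs$alpha_exp) != length(model$exp_scale))
    stopf("alpha_exp length %d does not match model k_exp = %d",
          length(coeffs$alpha_exp), length(model$exp_scale))
  flat <- flatten_vertices(model$mean_shape) +
    as.numeric(model$id_basis %*% (coeffs$alpha_id * model$id_scale)) +
    as.numeric(model$exp_basis %*% (coeffs$alpha_exp * model$exp_scale))
  face_mesh(unflatten_vertices(flat, model$vertex_count), model$triangulation)
}

#' @rdname construct_shape
#' @param object a [morphable_model()].
#' @param ... unused.
#' @export
predict.morphable_model <- function(object, coeffs, ...) construct_shape(object, coeffs)

#' Draw random plausible faces from a morphable model
#'
#' Coefficient vectors are i.i.d. standard normal in sd units, the model's
#' own prior.
#'
#' @param object a [morphable_model()].
#' @param nsim number of faces to draw.
#' @param seed integer seed fixing the draw; the caller's RNG state is
#'   left untouched.
#' @param ... unused.
#' @return A list of [shape_coefficients()] of length `nsim`.
#' @export
simulate.morphable_model <- function(object, nsim = 1, seed = 1L, ...) {
  with_seed(seed, replicate(nsim, sample_face_impl(object), simplify = FALSE))
}

# ---- serialization ---------------------------------------------------------

container_magic <- "palsy3d-model"
container_version <- 1L

write_array_block <- function(con, name, x, integer = FALSE) {
  x <- as.matrix(x)
  writeLines(sprintf("array %s %d %d %s", name, nrow(x), ncol(x),
                     if (integer) "int" else "num"), con)
  lines <- apply(x, 1L, function(row)
    paste(if (integer) sprintf("%d", as.integer(row)) else fmt_num(row),
          collapse = " "))
  writeLines(lines, con)
}

#' Save / load a morphable model
#'
#' The container is a self-describing plain-text archive: a small header
#' (format version, metadata, dimensions) followed by named numeric arrays
#' (`mean_shape`, `id_basis`, `exp_basis`, `id_scale`, `exp_scale`, and
#' optionally `triangulation` and `correspondence`).  Values are written at
#' 17 significant digits, so a save/load round trip reproduces every field
#' bit-exactly, and two saves of the same model are byte-identical.
#'
#' @param model a [morphable_model()].
#' @param path file path to write to / read from.
#' @return `load_model` returns a [morphable_model()]; `save_model`
#'   returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "morphable_model"))
  con <- file(path, "wb")  # binary mode: LF line endings on every platform
  on.exit(close(con))
  writeLines(c(sprintf("%s %d", container_magic, container_version),
               sprintf("name: %s", model$name),
               sprintf("units: %s", model$units),
               sprintf("m: %d", model$vertex_count)), con)
  write_array_block(con, "mean_shape", model$mean_shape)
  write_array_block(con, "id_basis", model$id_basis)
  write_array_block(con, "exp_basis", model$exp_basis)
  write_array_block(con, "id_scale", matrix(model$id_scale, nrow = 1L))
  write_array_block(con, "exp_scale", matrix(model$exp_scale, nrow = 1L))
  if (!is.null(model$triangulation))
    write_array_block(con, "triangulation", model$triangulation, integer = TRUE)
  if (!is.null(model$correspondence))
    write_array_block(con, "correspondence", matrix(model$correspondence, nrow = 1L), integer = TRUE)
  writeLines("end", con)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L) stopf("corrupt model file (too short): %s", path)
  head1 <- strsplit(lines[[1L]], " ", fixed = TRUE)[[1L]]
  if (length(head1) != 2L || head1[[1L]] != container_magic)
    stopf("not a %s container: %s", container_magic, path)
  if (as.integer(head1[[2L]]) != container_version)
    stopf("unsupported container version %s (expected %d)", head1[[2L]], container_version)
  field <- function(i, key) {
    if (!startsWith(lines[[i]], paste0(key, ": ")))
      stopf("corrupt model header at line %d: expected field '%s'", i, key)
    sub(paste0("^", key, ": "), "", lines[[i]])
  }
  name <- field(2L, "name"); units <- field(3L, "units")
  m <- as.integer(field(4L, "m"))
  arrays <- list(); i <- 5L
  while (i <= length(lines) && lines[[i]] != "end") {
    hdr <- strsplit(lines[[i]], " ", fixed = TRUE)[[1L]]
    if (length(hdr) != 5L || hdr[[1L]] != "array")
      stopf("corrupt model file at line %d: expected array header", i)
    nr <- as.integer(hdr[[3L]]); nc <- as.integer(hdr[[4L]]); int <- identical(hdr[[5L]], "int")
    if (i + nr > length(lines)) stopf("truncated model file: array '%s' incomplete", hdr[[2L]])
    body <- lines[(i + 1L):(i + nr)]
    vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), " +")[[1L]]))
    if (any(vapply(vals, length, 1L) != nc))
      stopf("corrupt model file: array '%s' row width mismatch", hdr[[2L]])
    a <- matrix(unlist(vals), nrow = nr, ncol = nc, byrow = TRUE)
    if (int) a <- matrix(as.integer(a), nrow = nr, ncol = nc)
    arrays[[hdr[[2L]]]] <- a
    i <- i + nr + 1L
  }
  if (i > length(lines)) stopf("truncated model file (missing end marker): %s", path)
  need <- c("mean_shape", "id_basis", "exp_basis", "id_scale", "exp_scale")
  miss <- setdiff(need, names(arrays))
  if (length(miss)) stopf("model file missing required array(s): %s", paste(miss, collapse = ", "))
  morphable_model(arrays$mean_shape, arrays$id_basis, arrays$exp_basis,
                  as.numeric(arrays$id_scale), as.numeric(arrays$exp_scale),
                  triangulation = arrays$triangulation,
                  correspondence = if (!is.null(arrays$correspondence)) as.integer(arrays$correspondence),
                  name = name, units = units)
}

#' Export a mesh as Wavefront OBJ
#'
#' Writes one `v` line per vertex (order preserved) and, when the mesh has
#' a triangulation, one `f` line per triangle with 1-based indices.
#' Coordinates are printed with 6 decimals, so re-parsing recovers them to
#' better than 1e-6.
#'
#' @param mesh a [face_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "face_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  v <- mesh$vertices
  writeLines(sprintf("v %.6f %.6f %.6f", v[1L, ], v[2L, ], v[3L, ]), con)
  if (!is.null(mesh$triangulation)) {
    tr <- mesh$triangulation
    writeLines(sprintf("f %d %d %d", tr[, 1L], tr[, 2L], tr[, 3L]), con)
  }
  invisible(path)
}

# Minimal OBJ reader (v and f records only), used to reload meshes written
# by export_mesh, e.g. in the evaluation pipeline.
#' @rdname export_mesh
#' @export
import_mesh <- function(path) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines)) stopf("no vertex records in OBJ file: %s", path)
  v <- vapply(strsplit(vlines, " +"), function(p) as.numeric(p[2:4]), numeric(3L))
  tr <- NULL
  if (length(flines))
    tr <- t(vapply(strsplit(flines, " +"), function(p) as.integer(p[2:4]), integer(3L)))
  face_mesh(v, tr)
}
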