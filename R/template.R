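#' Similarity transform
#'
#' Rotation, uniform scale and translation, applied as
#' `p -> scale * R p + translation`.  Non-uniform scaling is deliberately not
#' supported: template alignment uses similarities only.
#'
#' @param rotation 3x3 rotation matrix.
#' @param scale positive uniform scale factor.
#' @param translation length-3 numeric (mm).
#' @return an object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation = diag(3), scale = 1,
                                 translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(crossprod(rotation), diag(3), tolerance = 1e-8)) ||
      det(rotation) < 0)
    stop("rotation must be a proper orthonormal 3x3 matrix")
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  structure(list(rotation = rotation, scale = as.numeric(scale),
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#'
#' @param transform a [similarity_transform()].
#' @param points `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
transform_points <- function(transform, points) {
  points <- as.matrix(points)
  sweep(transform$scale * (points %*% t(transform$rotation)), 2L,
        transform$translation, `+`)
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Template: mesh + cage + harmonic binding
#'
#' The deformable unit: a watertight rest mesh, its enclosing rest cage, and
#' the harmonic-coordinate weight matrix that makes every mesh vertex a fixed
#' affine combination of cage vertices.  Mesh vertices are never edited
#' directly; all deformation goes through the cage (see [deform_mesh()]).
#'
#' @param mesh a [triangle_mesh()] (rest pose).
#' @param cage a [cage()] enclosing the mesh (rest pose).
#' @param binding a `harmonic_binding` from [bind_mesh()], or `NULL` for an
#'   unbound template.
#' @return an object of class `template_model`.
#' @export
template_model <- function(mesh, cage, binding = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(cage, "cage"))
  if (nrow(cage$vertices) > nrow(mesh$vertices))
    stop("cage must be coarser than the mesh (N_c <= N_m)")
  if (!is.null(binding)) {
    stopifnot(inherits(binding, "harmonic_binding"))
    if (nrow(binding$weights) != nrow(mesh$vertices) ||
        ncol(binding$weights) != nrow(cage$vertices))
      stop("binding dimensions do not match mesh/cage vertex counts")
  }
  structure(list(mesh = mesh, cage = cage, binding = binding),
            class = "template_model")
}

#' @export
print.template_model <- function(x, ...) {
  cat(sprintf("<template_model> mesh %d vertices, cage %d vertices, %s\n",
              nrow(x$mesh$vertices), nrow(x$cage$vertices),
              if (is.null(x$binding)) "unbound" else "bound"))
  invisible(x)
}

#' Deform the template mesh from cage vertices
#'
#' Evaluates the harmonic-coordinate FFD: output vertex `i` is
#' `sum_j a_ji c_j` where `a_ji` are the binding weights and `c_j` the given
#' cage vertex positions.  The triangle list is carried over unchanged.
#'
#' @param template a bound [template_model()].
#' @param cage_vertices `N_c x 3` matrix of cage vertex positions (mm);
#'   defaults to the rest cage.
#' @return a [triangle_mesh()] with deformed vertices.
#' @export
deform_mesh <- function(template, cage_vertices = template$cage$vertices) {
  if (is.null(template$binding)) stop("template is not bound; run bind_template()")
  cage_vertices <- as.matrix(cage_vertices)
  if (nrow(cage_vertices) != ncol(template$binding$weights) ||
      ncol(cage_vertices) != 3L)
    stop("cage_vertices must be N_c x 3 (binding dimension mismatch)")
  v <- template$binding$weights %*% cage_vertices
  out <- template$mesh
  out$vertices <- as.matrix(v)
  out
}

#' Per-frame state of a template
#'
#' Holds, for one time frame, the similarity alignment and the current cage
#' vertex positions.  Cage topology never changes across frames; only vertex
#' positions do.
#'
#' @param frame 0-based frame index.
#' @param cage_vertices `N_c x 3` matrix of current cage vertex positions.
#' @param alignment the [similarity_transform()] this state was initialized
#'   with (kept for provenance; it is already baked into `cage_vertices`).
#' @return an object of class `frame_state`.
#' @export
frame_state <- function(frame, cage_vertices,
                        alignment = similarity_transform()) {
  stopifnot(frame >= 0, inherits(alignment, "similarity_transform"))
  cage_vertices <- as.matrix(cage_vertices)
  structure(list(frame = as.integer(frame), alignment = alignment,
                 cage_vertices = cage_vertices),
            class = "frame_state")
}

#' Align the template cage
#'
#' Applies a similarity transform to the rest cage.  Alignment is baked into
#' cage vertex positions so that Eq.-style FFD remains the single mesh-update
#' path and curve fitting can start from any aligned or hand-edited cage.
#'
#' @param template a [template_model()].
#' @param transform a [similarity_transform()].
#' @return `N_c x 3` matrix of transformed cage vertices.
#' @export
apply_alignment <- function(template, transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  transform_points(transform, template$cage$vertices)
}

#' Edit individual cage vertices
#'
#' The scriptable counterpart of interactive FFD cage dragging: replaces the
#' positions of selected cage vertices in a frame state.
#'
#' @param state a [frame_state()].
#' @param edits named list or list of `index = position` pairs: names are
#'   1-based cage vertex indices, values length-3 positions (mm).
#' @return the updated [frame_state()].
#' @export
set_cage_vertices <- function(state, edits) {
  stopifnot(inherits(state, "frame_state"))
  if (length(edits) == 0L) return(state)
  idx <- as.integer(names(edits))
  if (anyNA(idx) || any(idx < 1L) || any(idx > nrow(state$cage_vertices)))
    stop("invalid cage vertex index in edits")
  for (i in seq_along(idx))
    state$cage_vertices[idx[i], ] <- as.numeric(edits[[i]])
  state
}

#' Initial frame states for a sequence
#'
#' Creates `n_frames` contiguous frame states, each starting from the rest
#' cage with the given alignment applied — the batch equivalent of aligning
#' the template once and copying the alignment to all frames.
#'
#' @param template a [template_model()].
#' @param n_frames number of frames `T >= 1`.
#' @param alignment a single [similarity_transform()] shared by all frames, or
#'   a list of length `T` with one transform per frame.
#' @return list of [frame_state()] objects for frames `0 ... T-1`.
#' @export
init_frame_states <- function(template, n_frames,
                              alignment = similarity_transform()) {
  stopifnot(n_frames >= 1)
  if (inherits(alignment, "similarity_transform"))
    alignment <- rep(list(alignment), n_frames)
  stopifnot(length(alignment) == n_frames)
  lapply(seq_len(n_frames), function(i) {
    frame_state(i - 1L, apply_alignment(template, alignment[[i]]),
                alignment[[i]])
  })
}
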