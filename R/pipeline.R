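#' Reference voxel grid
#'
#' Geometry of the label-volume raster: dimensions, spacing, and the world
#' position of the first voxel center.  Volumes are consumed only for this
#' geometry — the fitting algorithm never reads intensities.
#'
#' @param dims integer length-3 voxel counts.
#' @param spacing_mm voxel spacing (mm), all > 0.
#' @param origin_mm world position of voxel (1,1,1)'s center (mm).
#' @return an object of class `reference_grid`.
#' @export
reference_grid <- function(dims, spacing_mm, origin_mm = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L),
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  structure(list(dims = dims, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "reference_grid")
}

#' Read / write grid.json
#'
#' `{dims:[nx,ny,nz], spacing_mm:[sx,sy,sz], origin_mm:[ox,oy,oz]}`.
#'
#' @param path JSON file path.
#' @return `read_grid_json`: a [reference_grid()].
#' @export
read_grid_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  reference_grid(js$dims, js$spacing_mm, js$origin_mm)
}

#' @rdname read_grid_json
#' @param grid a [reference_grid()].
#' @export
write_grid_json <- function(grid, path) {
  jsonlite::write_json(list(dims = grid$dims, spacing_mm = grid$spacing_mm,
                            origin_mm = grid$origin_mm),
                       path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Voxelize a watertight mesh into a label volume
#'
#' A voxel is labeled iff its center is inside the mesh, decided by even-odd
#' parity of a `+x` ray through the voxel center (with a deterministic
#' sub-voxel perturbation so edge-aligned hits are generic).
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param grid a [reference_grid()].
#' @param label positive integer label value (default 1).
#' @return a `label_volume`: `data` (3D integer array in {0, label}), `grid`,
#'   `label`.
#' @export
voxelize_mesh <- function(mesh, grid, label = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(grid, "reference_grid"))
  if (!is_watertight(mesh))
    stop(sprintf("mesh '%s' is not watertight; cannot voxelize", mesh$id))
  mask <- cpp_voxelize(mesh$vertices, mesh$triangles - 1L, grid$dims,
                       grid$spacing_mm, grid$origin_mm)
  structure(list(data = array(as.integer(label) * mask, grid$dims),
                 grid = grid, label = as.integer(label)),
            class = "label_volume")
}

#' Segmentation job
#'
#' Everything needed to segment a whole frame sequence: a bound template,
#' per-frame and shared constraint curves, initial frame states (alignment /
#' manual cage edits already applied), fitting parameters, and the reference
#' grid for label export.
#'
#' @param template a bound [template_model()].
#' @param n_frames frame count `T >= 1`.
#' @param curves list of frame-local [curve_constraint()] objects.
#' @param shared list of [shared_curve()] objects.
#' @param states list of `T` [frame_state()] objects for frames `0..T-1`, or
#'   `NULL` to start every frame at the rest cage.
#' @param params a [fitting_parameters()].
#' @param grid a [reference_grid()] for label export, or `NULL` to skip
#'   voxelization.
#' @param interval resampling interval `d` in mm.
#' @param curve_method curve model (see [interpolate_curve()]).
#' @return an object of class `segmentation_job`.
#' @export
segmentation_job <- function(template, n_frames, curves = list(),
                             shared = list(), states = NULL,
                             params = fitting_parameters(), grid = NULL,
                             interval = 1.0, curve_method = "kappa") {
  stopifnot(inherits(template, "template_model"), n_frames >= 1L)
  if (is.null(template$binding)) stop("template must be bound")
  if (is.null(states)) states <- init_frame_states(template, n_frames)
  stopifnot(length(states) == n_frames)
  fidx <- vapply(states, `[[`, 1L, "frame")
  if (!identical(fidx, 0:(n_frames - 1L)))
    stop("frame states must be contiguous 0..T-1")
  if (!is.null(grid)) stopifnot(inherits(grid, "reference_grid"))
  structure(list(template = template, n_frames = as.integer(n_frames),
                 curves = curves, shared = shared, states = states,
                 params = params, grid = grid, interval = interval,
                 curve_method = curve_method),
            class = "segmentation_job")
}

#' Run a segmentation job
#'
#' For each frame: assemble constraint points ([collect_frame_constraints()]),
#' fit the template ([fit_template_to_curves()]) starting from the frame's
#' current cage, and record diagnostics.  Frames are processed in ascending
#' order but are mutually independent, so results do not depend on order.
#' Frames with no applicable curves keep their initial cage and are flagged
#' (`skipped`), with a warning.
#'
#' @param job a [segmentation_job()].
#' @param voxelize also rasterize each frame's result on the job grid.
#' @return list with `meshes` (per-frame deformed [triangle_mesh()]),
#'   `states`, `labels` (per-frame `label_volume` or `NULL`), and
#'   `report` (per-frame diagnostics).
#' @export
run_job <- function(job, voxelize = !is.null(job$grid)) {
  stopifnot(inherits(job, "segmentation_job"))
  if (voxelize && is.null(job$grid)) stop("job has no reference grid")
  meshes <- states <- labels <- vector("list", job$n_frames)
  report <- vector("list", job$n_frames)
  for (t in 0:(job$n_frames - 1L)) {
    st <- job$states[[t + 1L]]
    cps <- tryCatch(
      collect_frame_constraints(job$curves, job$shared, t, job$n_frames,
                                interval = job$interval,
                                method = job$curve_method),
      error = function(e) NULL)
    if (is.null(cps)) {
      warning(sprintf("frame %d has no constraints; keeping aligned cage", t))
      meshes[[t + 1L]] <- deform_mesh(job$template, st$cage_vertices)
      states[[t + 1L]] <- st
      report[[t + 1L]] <- list(frame = t, skipped = TRUE, n_constraints = 0L)
    } else {
      fit <- fit_template_to_curves(job$template, st, cps, job$params)
      meshes[[t + 1L]] <- fit$mesh
      states[[t + 1L]] <- fit$state
      report[[t + 1L]] <- c(list(frame = t, skipped = FALSE), fit$diagnostics)
    }
    if (voxelize)
      labels[[t + 1L]] <- voxelize_mesh(meshes[[t + 1L]], job$grid)
  }
  list(meshes = meshes, states = states,
       labels = if (voxelize) labels else NULL, report = report)
}

#' Export segmentation results
#'
#' Writes, per frame, the deformed mesh (`<name>_frame{t:03d}.ply` by
#' default), the label volume (`<name>_frame{t:03d}.nii.gz`, grid geometry in
#' the header), and one JSON diagnostics report (`<name>_report.json`) with
#' per-frame residual curves and flags.  Output is deterministic: identical
#' inputs reproduce byte-identical reports.
#'
#' @param job the [segmentation_job()] that produced the results.
#' @param result the [run_job()] output.
#' @param out_dir output directory (created if missing).
#' @param name organ/result base name.
#' @param mesh_format "ply" or "obj".
#' @return character vector of written paths, invisibly.
#' @export
export_results <- function(job, result, out_dir, name = "organ",
                           mesh_format = c("ply", "obj")) {
  mesh_format <- match.arg(mesh_format)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (t in 0:(job$n_frames - 1L)) {
    mp <- file.path(out_dir, sprintf("%s_frame%03d.%s", name, t, mesh_format))
    write_mesh(result$meshes[[t + 1L]], mp)
    paths <- c(paths, mp)
    if (!is.null(result$labels)) {
      lp <- file.path(out_dir, sprintf("%s_frame%03d.nii.gz", name, t))
      write_nifti(result$labels[[t + 1L]]$data, lp,
                  spacing = job$grid$spacing_mm, origin = job$grid$origin_mm)
      paths <- c(paths, lp)
    }
  }
  rp <- file.path(out_dir, sprintf("%s_report.json", name))
  report <- lapply(result$report, function(r) {
    if (isTRUE(r$skipped))
      list(frame = r$frame, skipped = TRUE, n_constraints = 0L)
    else
      list(frame = r$frame, skipped = FALSE, n_constraints = r$n_constraints,
           initial_mean = r$initial_mean, final_mean = r$final_mean,
           final_max = r$final_max, converged = r$converged,
           mean_residuals = r$per_iteration$mean_residual,
           max_residuals = r$per_iteration$max_residual)
  })
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  paths <- c(paths, rp)
  invisible(paths)
}

#' Read / write a frame-state sequence as JSON
#'
#' `{frames: T, states: [{frame, alignment: {rotation (row-major 3x3),
#' scale, translation_mm}, cage_vertices_mm: [[x,y,z],...]}, ...]}`.
#'
#' @param path JSON file path.
#' @return `read_states_json`: list of [frame_state()] objects.
#' @export
read_states_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(js$states, function(st) {
    rot <- do.call(rbind, lapply(st$alignment$rotation,
                                 function(r) as.numeric(unlist(r))))
    cg <- do.call(rbind, lapply(st$cage_vertices_mm,
                                function(v) as.numeric(unlist(v))))
    frame_state(st$frame, cg,
                similarity_transform(rot, st$alignment$scale,
                                     as.numeric(unlist(st$alignment$translation_mm))))
  })
}

#' @rdname read_states_json
#' @param states list of [frame_state()] objects, frames contiguous from 0.
#' @export
write_states_json <- function(states, path) {
  js <- list(
    frames = length(states),
    states = lapply(states, function(st)
      list(frame = st$frame,
           alignment = list(
             rotation = lapply(1:3, function(r) st$alignment$rotation[r, ]),
             scale = st$alignment$scale,
             translation_mm = st$alignment$translation),
           cage_vertices_mm = lapply(seq_len(nrow(st$cage_vertices)),
                                     function(i) st$cage_vertices[i, ]))))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Overlap (Dice) coefficient of two label volumes
#'
#' @param a,b `label_volume` objects on the same grid.
#' @return Dice coefficient `2|A∩B| / (|A| + |B|)` in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a$data), dim(b$data)))
  ia <- a$data != 0L
  ib <- b$data != 0L
  denom <- sum(ia) + sum(ib)
  if (denom == 0L) return(1.0)
  2 * sum(ia & ib) / denom
}

#' Mean surface distance between two meshes
#'
#' Mean distance from `a`'s vertices to the surface of `b` (one-sided; use
#' the maximum of both directions for a symmetric measure).
#'
#' @param a,b [triangle_mesh()] objects.
#' @return mean distance in mm.
#' @export
mean_surface_distance <- function(a, b) {
  mean(closest_point_on_mesh(b, a$vertices)$dist)
}
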