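#' Fitting parameters
#'
#' Cost weights and iteration count of the alternating curve-fitting
#' algorithm.  Defaults are the empirically chosen values `alpha = 1`,
#' `beta = 1`, `gamma = 5` with `iterations = 20`: `alpha` weighs the
#' constraint data term, `beta` the per-iteration cage displacement penalty,
#' and `gamma` the change of the cage's graph-Laplacian coordinates (shape
#' preservation).  Cost terms are used exactly as written — no normalization
#' by the number of constraint points or cage vertices — so the data term
#' strengthens with denser resampling.
#'
#' @param alpha data-term weight (> 0).
#' @param beta cage-displacement weight (>= 0).
#' @param gamma Laplacian shape weight (>= 0).
#' @param iterations number of outer alternations `n`.
#' @param early_stop_tol if positive, stop early once the mean residual
#'   changes by less than this many mm between iterations (off by default to
#'   reproduce the fixed-n procedure).
#' @return an object of class `fitting_parameters`.
#' @export
fitting_parameters <- function(alpha = 1, beta = 1, gamma = 5,
                               iterations = 20L, early_stop_tol = 0) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0 (data term)")
  if (beta < 0 || gamma < 0) stop("beta and gamma must be non-negative")
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 iterations = as.integer(iterations),
                 early_stop_tol = early_stop_tol),
            class = "fitting_parameters")
}

#' Closest points on a mesh
#'
#' For each query point, the globally nearest point on the mesh surface —
#' face interior, edge, or vertex — with its barycentric representation
#' (edge/vertex cases have zero barycentric components).  Exact: every
#' triangle is considered, with bounding-box rejection for speed.  Ties are
#' broken toward the lowest triangle index.
#'
#' @param mesh a [triangle_mesh()].
#' @param queries `n x 3` matrix of query points (a single point may be given
#'   as a length-3 vector).
#' @return a `closest_point_association`: `triangle` (1-based index),
#'   `bary` (`n x 3`), `foot` (`n x 3` footpoints), `dist`.
#' @export
closest_point_on_mesh <- function(mesh, queries) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is.null(dim(queries))) queries <- matrix(queries, ncol = 3L)
  queries <- as.matrix(queries)
  a <- mesh$vertices[mesh$triangles[, 1L], , drop = FALSE]
  b <- mesh$vertices[mesh$triangles[, 2L], , drop = FALSE]
  cc <- mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]
  areas <- 0.5 * sqrt(rowSums(cross3(b - a, cc - a)^2))
  if (any(areas < 1e-12))
    stop(sprintf("degenerate (zero-area) triangle %d", which.min(areas)))
  res <- cpp_closest_point_mesh(mesh$vertices, mesh$triangles - 1L, queries)
  structure(list(triangle = res$tri + 1L, bary = res$bary, foot = res$foot,
                 dist = res$dist),
            class = "closest_point_association")
}

#' Graph Laplacian of a cage
#'
#' Uniform (combinatorial) degree-normalized graph Laplacian on the cage's
#' original polygon edge graph:
#' `L(c_j) = c_j - mean of the neighbours of j`, applied per coordinate axis.
#' Row sums are zero, so the operator kills constants and the shape penalty of
#' the fitting cost is translation invariant.
#'
#' @param cage a [cage()].
#' @return a sparse `N_c x N_c` [Matrix::Matrix()].
#' @export
graph_laplacian <- function(cage) {
  stopifnot(inherits(cage, "cage"))
  n <- nrow(cage$vertices)
  deg <- tabulate(as.vector(cage$edges), n)
  if (any(deg == 0L)) stop("isolated cage vertex")
  i <- c(cage$edges[, 1L], cage$edges[, 2L])
  j <- c(cage$edges[, 2L], cage$edges[, 1L])
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1 / deg[i], dims = c(n, n))
  Matrix::Diagonal(n) - A
}

#' One regularized cage update (the quadratic optimization step)
#'
#' Solves, per coordinate axis, the exact minimizer of
#' \deqn{\alpha \sum_k \|p_k - p^c_k\|^2 + \beta \sum_j \|c_j - c^0_j\|^2 +
#'       \gamma \sum_j \|L(c_j) - L(c^0_j)\|^2}
#' where each mesh footpoint `p_k` is the barycentric combination of deformed
#' mesh vertices and therefore — through the harmonic binding — a fixed linear
#' function `w_k^T C` of the unknown cage vertices.  Because every operator is
#' linear and isotropic, the problem decouples over x/y/z into three sparse
#' symmetric positive-definite systems sharing one factorization.
#'
#' @param binding a `harmonic_binding`.
#' @param cage0 `N_c x 3` current cage vertices `c^0`.
#' @param assoc a `closest_point_association` for the current deformed mesh.
#' @param targets a `constraint_point_set` (the `p^c_k`), same length as
#'   `assoc`.
#' @param params a [fitting_parameters()].
#' @param L the cage graph Laplacian ([graph_laplacian()]).
#' @param triangles the mesh triangle matrix (defaults are filled in by
#'   [fit_template_to_curves()]).
#' @return updated `N_c x 3` cage vertex matrix.
#' @export
solve_cage_update <- function(binding, cage0, assoc, targets, params, L,
                              triangles) {
  np <- length(assoc$triangle)
  if (np == 0L || targets$n == 0L) stop("no constraint points")
  if (np != targets$n) stop("association and targets differ in length")
  A <- binding$weights
  if (!all(is.finite(cage0)) || !all(is.finite(targets$points)))
    stop("non-finite input to cage update")
  nc <- ncol(A)
  # w_k = sum_s bary_ks * A[vertex_ks, ] : constraint rows in cage space
  tri <- triangles[assoc$triangle, , drop = FALSE]
  W <- assoc$bary[, 1L] * A[tri[, 1L], , drop = FALSE] +
    assoc$bary[, 2L] * A[tri[, 2L], , drop = FALSE] +
    assoc$bary[, 3L] * A[tri[, 3L], , drop = FALSE]
  W <- Matrix::Matrix(W, sparse = TRUE)
  LtL <- Matrix::crossprod(L)
  H <- params$alpha * Matrix::crossprod(W) +
    params$beta * Matrix::Diagonal(nc) + params$gamma * LtL
  rhs <- params$alpha * Matrix::crossprod(W, targets$points) +
    params$beta * cage0 + params$gamma * (LtL %*% cage0)
  as.matrix(Matrix::solve(H, rhs))
}

# Objective value of the quadratic cost for a given association (diagnostic;
# used to assert per-iteration descent).
cage_objective <- function(binding, cageC, cage0, assoc, targets, params, L,
                           triangles) {
  A <- binding$weights
  V <- A %*% cageC
  tri <- triangles[assoc$triangle, , drop = FALSE]
  P <- assoc$bary[, 1L] * V[tri[, 1L], , drop = FALSE] +
    assoc$bary[, 2L] * V[tri[, 2L], , drop = FALSE] +
    assoc$bary[, 3L] * V[tri[, 3L], , drop = FALSE]
  dL <- as.matrix(L %*% (cageC - cage0))
  params$alpha * sum((P - targets$points)^2) +
    params$beta * sum((cageC - cage0)^2) + params$gamma * sum(dL^2)
}

#' Fit the template to constraint points (alternating algorithm)
#'
#' Runs `n` alternations of: deform the mesh from the current cage, associate
#' every constraint point with its closest point on the deformed mesh, and
#' solve the regularized quadratic cage update.  The association is recomputed
#' from the freshly deformed mesh in every iteration.  Starting point is the
#' frame state's current cage, which may already carry an alignment or manual
#' cage edits.
#'
#' Diagnostics record, per iteration, the mean and max constraint residual
#' `||p_k - p^c_k||` at association time, plus a final residual after the last
#' update.  The fit is flagged non-converged when the final mean residual
#' exceeds 25% of the initial one — the characteristic signature of wrong
#' closest-point associations when the target shape is far from the template
#' (e.g. globally bent targets).
#'
#' @param template a bound [template_model()].
#' @param state a [frame_state()].
#' @param constraints a `constraint_point_set`.
#' @param params a [fitting_parameters()].
#' @return list with `state` (updated [frame_state()]), `mesh` (final
#'   deformed [triangle_mesh()]), and `diagnostics`: data frame of
#'   per-iteration residuals plus `final_mean`, `final_max`, `initial_mean`,
#'   `converged`.
#' @export
fit_template_to_curves <- function(template, state, constraints,
                                   params = fitting_parameters()) {
  stopifnot(inherits(template, "template_model"), inherits(state, "frame_state"),
            inherits(constraints, "constraint_point_set"),
            inherits(params, "fitting_parameters"))
  if (is.null(template$binding)) stop("template is not bound")
  if (constraints$n < 1L) stop("no constraint points")
  L <- graph_laplacian(template$cage)
  tris <- template$mesh$triangles
  cageC <- state$cage_vertices
  mean_res <- max_res <- numeric(params$iterations)
  prev_mean <- Inf
  used <- 0L
  for (it in seq_len(params$iterations)) {
    mesh_t <- deform_mesh(template, cageC)
    assoc <- closest_point_on_mesh(mesh_t, constraints$points)
    mean_res[it] <- mean(assoc$dist)
    max_res[it] <- max(assoc$dist)
    cageC <- solve_cage_update(template$binding, cageC, assoc, constraints,
                               params, L, tris)
    used <- it
    if (params$early_stop_tol > 0 &&
        abs(prev_mean - mean_res[it]) < params$early_stop_tol) break
    prev_mean <- mean_res[it]
  }
  mesh_t <- deform_mesh(template, cageC)
  final <- closest_point_on_mesh(mesh_t, constraints$points)
  out_state <- state
  out_state$cage_vertices <- cageC
  diagnostics <- list(
    per_iteration = data.frame(iteration = seq_len(used),
                               mean_residual = mean_res[seq_len(used)],
                               max_residual = max_res[seq_len(used)]),
    initial_mean = mean_res[1L],
    final_mean = mean(final$dist),
    final_max = max(final$dist),
    n_constraints = constraints$n,
    converged = mean(final$dist) <= 0.25 * mean_res[1L])
  list(state = out_state, mesh = mesh_t, diagnostics = diagnostics)
}
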