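#' Attraction-Repulsion configuration
#'
#' Constants of the iterative node relaxation that maps a closed surface mesh
#' to the unit sphere: `c_a1` and `c_a2` weight the cubic and unit-vector
#' attraction terms, `c_r` the global repulsion term. Iteration stops when
#' the maximum per-node displacement in a cycle drops below `tol` or after
#' `max_cycles` cycles.
#'
#' @param c_a1,c_a2,c_r positive displacement constants.
#' @param tol convergence threshold on the max per-node displacement.
#' @param max_cycles cycle budget.
#' @return An `ar_config` list.
#' @export
ar_config <- function(c_a1 = 0.3, c_a2 = 0.02, c_r = 1.0, tol = 1e-4,
                      max_cycles = 200L) {
  stopifnot(c_a1 >= 0, c_a2 >= 0, c_r >= 0, tol > 0, max_cycles >= 0)
  structure(list(c_a1 = c_a1, c_a2 = c_a2, c_r = c_r, tol = tol,
                 max_cycles = as.integer(max_cycles)),
            class = "ar_config")
}

#' One attraction cycle
#'
#' Jacobi-style update from the previous cycle's coordinates: each node moves
#' toward its mesh neighbors by
#' \deqn{C'_i = C_i + \sum_{j \in N(i)} [\, c_{A1}\, d_{ji} |d_{ji}|^2 +
#'   c_{A2}\, d_{ji} / |d_{ji}| \,], \quad d_{ji} = C_j - C_i.}
#' Coincident neighbor pairs contribute nothing.
#'
#' @param nodes I x 3 coordinate matrix.
#' @param neighbors per-node list of neighbor indices.
#' @param config an [ar_config()].
#' @return Updated I x 3 coordinate matrix.
#' @export
attraction_step <- function(nodes, neighbors, config = ar_config()) {
  stopifnot(is.matrix(nodes), ncol(nodes) == 3,
            length(neighbors) == nrow(nodes))
  if (any(lengths(neighbors) == 0))
    nf_value_error("every node needs at least one neighbor")
  cpp_attraction(nodes, neighbors, config$c_a1, config$c_a2)
}

#' One repulsion cycle with back-projection to the unit sphere
#'
#' Every node is pushed away from all other nodes,
#' \deqn{C^\circ_i = C'_i + \frac{c_R}{2I} \sum_{j \ne i}
#'   \frac{C_i - C_j}{|C_i - C_j|^2},}
#' and then back-projected onto the unit sphere along the ray from the
#' origin. Coincident node pairs are skipped; a node whose updated vector is
#' exactly zero is nudged by a 1e-9 jitter before normalization.
#'
#' @inheritParams attraction_step
#' @return I x 3 matrix of unit vectors.
#' @export
repulsion_step <- function(nodes, config = ar_config()) {
  stopifnot(is.matrix(nodes), ncol(nodes) == 3, nrow(nodes) >= 2)
  out <- cpp_repulsion(nodes, config$c_r)
  nrm <- sqrt(rowSums(out^2))
  bad <- which(abs(nrm - 1) > 1e-12)
  if (length(bad)) {
    nf_msg(length(bad), " node(s) needed a jitter in the repulsion step")
    out[bad, ] <- out[bad, , drop = FALSE] +
      matrix(1e-9 * c(1, 2, 3), length(bad), 3, byrow = TRUE)
    out[bad, ] <- out[bad, , drop = FALSE] /
      sqrt(rowSums(out[bad, , drop = FALSE]^2))
  }
  out
}

# coefficient of variation of the neighbor (edge) distances
.neighbor_cv <- function(nodes, edges) {
  d <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                       nodes[edges[, 2], , drop = FALSE])^2))
  stats::sd(d) / mean(d)
}

.mesh_edges <- function(mesh) {
  tris <- mesh$triangles
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

#' Map a surface mesh to the unit sphere (Attraction-Repulsion)
#'
#' Initializes the spherical image of each node as its centered coordinate
#' normalized to unit length, then alternates [attraction_step()] and
#' [repulsion_step()] until the maximum per-node displacement of a full cycle
#' falls below `config$tol` or the cycle budget is exhausted. The relaxation
#' drives neighbors toward equal spacing on the sphere; the coefficient of
#' variation (CV) of neighbor distances is tracked every cycle.
#'
#' @param mesh a [extract_mesh()] result.
#' @param config an [ar_config()].
#' @return A `spherical_map` with fields `original_nodes`, `sphere_nodes`
#'   (unit vectors, index-aligned), `cycles_run`, `converged`, `cv_initial`,
#'   `cv_final`, `cv_history`, and the source `mesh`.
#' @export
map_to_sphere <- function(mesh, config = ar_config()) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nodes <- mesh$nodes
  nrm <- sqrt(rowSums(nodes^2))
  zero <- nrm == 0
  if (any(zero)) {
    nodes[zero, ] <- matrix(1e-9 * c(1, 2, 3), sum(zero), 3, byrow = TRUE)
    nrm[zero] <- sqrt(sum((1e-9 * c(1, 2, 3))^2))
  }
  cur <- nodes / nrm
  edges <- .mesh_edges(mesh)
  cv0 <- .neighbor_cv(cur, edges)
  cv_hist <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  while (cycles < config$max_cycles) {
    cycles <- cycles + 1L
    nxt <- repulsion_step(attraction_step(cur, mesh$neighbors, config), config)
    disp <- max(sqrt(rowSums((nxt - cur)^2)))
    cur <- nxt
    cv_hist <- c(cv_hist, .neighbor_cv(cur, edges))
    if (!is.finite(disp))
      nf_value_error("non-finite displacement in cycle %d", cycles)
    if (disp < config$tol) { converged <- TRUE; break }
  }
  structure(list(original_nodes = mesh$nodes, sphere_nodes = cur,
                 mesh = mesh, cycles_run = cycles, converged = converged,
                 cv_initial = cv0,
                 cv_final = if (length(cv_hist)) cv_hist[length(cv_hist)] else cv0,
                 cv_history = cv_hist),
            class = "spherical_map")
}

#' @export
print.spherical_map <- function(x, ...) {
  cat(sprintf("<spherical_map> %d nodes, %d cycles, converged=%s, CV %.4f -> %.4f\n",
              nrow(x$sphere_nodes), x$cycles_run, x$converged,
              x$cv_initial, x$cv_final))
  invisible(x)
}
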