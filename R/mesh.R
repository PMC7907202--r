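# ---- small 3-D field utilities ---------------------------------------------

# separable Gaussian smoothing, zero-padded, kernel truncated at 3 sigma
gaussian_smooth_3d <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  for (axis in 1:3) {
    sg <- sigma_vox[axis]
    if (sg <= 0) next
    r <- max(1L, ceiling(3 * sg))
    w <- stats::dnorm(-r:r, sd = sg)
    w <- w / sum(w)
    out <- array(0, dim(arr))
    for (t in -r:r) out <- out + w[t + r + 1] * .shift_axis(arr, t, axis)
    arr <- out
  }
  arr
}

.shift_axis <- function(a, k, axis) {
  if (k == 0) return(a)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  si <- list(1:d[1], 1:d[2], 1:d[3]); di <- si
  si[[axis]] <- src; di[[axis]] <- dst
  out[di[[1]], di[[2]], di[[3]]] <- a[si[[1]], si[[2]], si[[3]]]
  out
}

# linear-interpolation resampling of a 3-D field onto an isotropic step (mm)
.resample_iso <- function(arr, spacing, step_mm) {
  d <- dim(arr)
  interp_w <- function(n, dx) {
    old <- (seq_len(n) - 1) * dx
    new <- seq(0, old[n], by = step_mm)
    W <- matrix(0, length(new), n)
    for (i in seq_along(new)) {
      j <- min(max(findInterval(new[i], old), 1L), n - 1L)
      u <- (new[i] - old[j]) / dx
      W[i, j] <- 1 - u
      W[i, j + 1] <- u
    }
    W
  }
  W1 <- interp_w(d[1], spacing[1])
  W2 <- interp_w(d[2], spacing[2])
  W3 <- interp_w(d[3], spacing[3])
  a <- W1 %*% matrix(arr, d[1], d[2] * d[3])                # axis 1
  a <- array(a, c(nrow(W1), d[2], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- W2 %*% matrix(a, d[2], nrow(W1) * d[3])              # axis 2
  a <- aperm(array(a, c(nrow(W2), nrow(W1), d[3])), c(2, 1, 3))
  a <- matrix(a, nrow(W1) * nrow(W2), d[3]) %*% t(W3)       # axis 3
  array(a, c(nrow(W1), nrow(W2), nrow(W3)))
}

# ---- surface mesh -----------------------------------------------------------

#' Triangulated surface mesh of a nodule
#'
#' Extracts the closed triangulated iso-surface of a binary nodule mask by
#' marching tetrahedra at iso-level 0.5. The binary grid is first smoothed
#' with a small Gaussian so the 0.5 level set tracks the true surface with
#' sub-voxel accuracy, and optionally resampled to an isotropic step to
#' control mesh resolution. Nodes are returned in mm, translated so their
#' centroid is at the origin; per-node neighbor lists are derived from shared
#' triangle edges.
#'
#' @param mask a [nodule_mask()] (single 26-connected component).
#' @param spacing voxel spacing in mm (defaults to the mask's).
#' @param smooth_sigma_mm Gaussian pre-smoothing bandwidth in mm (0 disables).
#' @param step_mm optional isotropic resampling step in mm; `NULL` keeps the
#'   native grid.
#' @return A `surface_mesh` with fields `nodes` (I x 3 mm), `triangles`
#'   (M x 3 indices), `neighbors` (list of integer vectors).
#' @export
extract_mesh <- function(mask, spacing = NULL, smooth_sigma_mm = 1.2,
                         step_mm = NULL) {
  stopifnot(inherits(mask, "nodule_mask"))
  if (is.null(spacing)) spacing <- mask$spacing
  field <- array(as.numeric(mask$voxels), dim(mask$voxels))
  pad <- pmax(2L, ceiling((3 * smooth_sigma_mm +
                             ifelse(is.null(step_mm), 0, step_mm)) / spacing))
  d <- dim(field)
  padded <- array(0, d + 2 * pad)
  padded[pad[1] + 1:d[1], pad[2] + 1:d[2], pad[3] + 1:d[3]] <- field
  field <- padded
  if (smooth_sigma_mm > 0)
    field <- gaussian_smooth_3d(field, smooth_sigma_mm / spacing)
  sp <- spacing
  if (!is.null(step_mm)) {
    field <- .resample_iso(field, spacing, step_mm)
    sp <- rep(step_mm, 3)
  }
  if (max(field) <= 0.5)
    nf_mesh_error("mask too thin: smoothed field never exceeds the iso-level")
  field[abs(field - 0.5) < 1e-9] <- 0.5 + 1e-6
  mt <- cpp_march_tets(as.numeric(field), dim(field), 0.5)
  if (nrow(mt$triangles) == 0)
    nf_mesh_error("no iso-surface found in mask")
  nodes <- sweep(mt$vertices, 2, sp, `*`)
  tris <- mt$triangles

  # keep the largest connected shell (satellite shells can arise from
  # smoothing very thin masks)
  comp <- .vertex_components(nrow(nodes), tris)
  if (max(comp) > 1) {
    main <- which.max(tabulate(comp))
    keep_v <- comp == main
    remap <- cumsum(keep_v)
    keep_t <- keep_v[tris[, 1]]
    tris <- matrix(remap[tris[keep_t, , drop = FALSE]], ncol = 3)
    nodes <- nodes[keep_v, , drop = FALSE]
  }

  edges <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  ecount <- table(ekey)
  if (any(ecount != 2))
    nf_mesh_error(paste0("extracted surface is not 2-manifold (",
                         sum(ecount != 2), " bad edges); try a larger ",
                         "smooth_sigma_mm or finer step_mm"))
  nb <- vector("list", nrow(nodes))
  ue <- unique(cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
  for (i in seq_len(nrow(ue))) {
    a <- ue[i, 1]; b <- ue[i, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nodes <- sweep(nodes, 2, colMeans(nodes))
  structure(list(nodes = nodes, triangles = tris, neighbors = nb,
                 spacing_used = sp),
            class = "surface_mesh")
}

.vertex_components <- function(nv, tris) {
  adj <- vector("list", nv)
  for (k in 1:3) {
    a <- tris[, k]; b <- tris[, k %% 3 + 1]
    for (i in seq_along(a)) adj[[a[i]]] <- c(adj[[a[i]]], b[i])
  }
  comp <- integer(nv)
  cur <- 0L
  for (s in seq_len(nv)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; stack <- c(stack, w) }
    }
  }
  comp
}

#' Surface area of a triangulated mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @export
mesh_area <- function(mesh) {
  p1 <- mesh$nodes[mesh$triangles[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$triangles[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$triangles[, 3], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a `surface_mesh`.
#' @export
mesh_euler_characteristic <- function(mesh) {
  tris <- mesh$triangles
  edges <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  ne <- nrow(unique(cbind(pmin(edges[, 1], edges[, 2]),
                          pmax(edges[, 1], edges[, 2]))))
  nrow(mesh$nodes) - ne + nrow(tris)
}

#' Export a mesh as OFF (for external inspection)
#' @param mesh a `surface_mesh`.
#' @param path destination path.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$nodes), nrow(mesh$triangles)), con)
  utils::write.table(format(mesh$nodes, digits = 9), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
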