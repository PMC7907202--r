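#' Real spherical-harmonic basis
#'
#' Evaluates the real, fully orthonormalized spherical-harmonic basis
#' \eqn{Y_{lm}} (Condon-Shortley phase omitted) at the given angles for all
#' degrees `0..L`. Associated Legendre values are computed with the standard
#' fully-normalized recurrences, which stay finite at high degree where the
#' unnormalized polynomials overflow.
#'
#' @param theta polar angle from the +z axis, in `[0, pi]`.
#' @param phi azimuth, `atan2(y, x)`.
#' @param L maximum degree.
#' @return Matrix `length(theta) x (L+1)^2`; columns ordered degree-major,
#'   within degree `m = -l..l`.
#' @export
real_sh_basis <- function(theta, phi, L) {
  stopifnot(length(theta) == length(phi), L >= 0)
  n <- length(theta)
  x <- cos(theta)
  s <- sin(theta)
  B <- matrix(0, n, (L + 1)^2)
  col_of <- function(l, m) l^2 + (m + l) + 1L

  # P[, l] holds fully-normalized P-bar_l^m for the current m
  pmm <- rep(sqrt(1 / (4 * pi)), n)           # m = 0 seed
  for (m in 0:L) {
    if (m > 0) pmm <- sqrt((2 * m + 1) / (2 * m)) * s * pmm
    # l = m
    plm2 <- pmm
    vals <- list(plm2)
    if (m < L) {
      plm1 <- sqrt(2 * m + 3) * x * pmm       # l = m + 1
      vals[[2]] <- plm1
      if (m + 2 <= L) for (l in (m + 2):L) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        pl <- a * (x * plm1 - b * plm2)
        vals[[l - m + 1]] <- pl
        plm2 <- plm1
        plm1 <- pl
      }
    }
    if (m == 0) {
      for (l in m:L) B[, col_of(l, 0)] <- vals[[l - m + 1]]
    } else {
      cm <- sqrt(2) * cos(m * phi)
      sm <- sqrt(2) * sin(m * phi)
      for (l in m:L) {
        B[, col_of(l, m)] <- vals[[l - m + 1]] * cm
        B[, col_of(l, -m)] <- vals[[l - m + 1]] * sm
      }
    }
  }
  B
}

.sphere_angles <- function(unit_nodes) {
  z <- pmin(pmax(unit_nodes[, 3], -1), 1)
  list(theta = acos(z), phi = atan2(unit_nodes[, 2], unit_nodes[, 1]))
}

#' Fit spherical harmonics to a mapped nodule surface
#'
#' Least-squares approximation of the original (centered) surface node
#' coordinates by real spherical harmonics evaluated at each node's image on
#' the unit sphere. Solved by rank-revealing QR (tolerance 1e-10).
#'
#' @param map a [map_to_sphere()] result.
#' @param L maximum harmonic degree.
#' @return An `sh_model` with fields `max_degree`, `coefficients`
#'   (`(L+1)^2 x 3`, one column per coordinate function) and `rank`.
#' @export
fit_sh <- function(map, L) {
  stopifnot(inherits(map, "spherical_map"))
  Y <- map$original_nodes
  if (nrow(Y) < (L + 1)^2)
    nf_rank_error("%d nodes cannot determine a degree-%d fit (needs >= %d)",
                  nrow(Y), L, (L + 1)^2)
  ang <- .sphere_angles(map$sphere_nodes)
  B <- real_sh_basis(ang$theta, ang$phi, L)
  dec <- qr(B, tol = 1e-10)
  if (dec$rank < ncol(B))
    nf_msg("SH design matrix rank ", dec$rank, " < ", ncol(B))
  coef <- qr.coef(dec, Y)
  coef[is.na(coef)] <- 0
  structure(list(max_degree = L, coefficients = coef, rank = dec$rank),
            class = "sh_model")
}

#' Reconstruct surface coordinates from a truncated harmonic model
#'
#' @param model an [fit_sh()] result.
#' @param map the spherical map supplying each node's angles.
#' @param k reconstruction order, `0 <= k <= model$max_degree`.
#' @return Matrix of reconstructed node coordinates.
#' @export
reconstruct <- function(model, map, k) {
  stopifnot(inherits(model, "sh_model"))
  if (k > model$max_degree || k < 0)
    nf_bounds_error("order k = %d outside fitted range 0..%d", k,
                    model$max_degree)
  ang <- .sphere_angles(map$sphere_nodes)
  B <- real_sh_basis(ang$theta, ang$phi, k)
  p <- (k + 1)^2
  B %*% model$coefficients[seq_len(p), , drop = FALSE]
}

#' Shape-complexity feature: per-order reconstruction-error curve
#'
#' `errors[k]` is the normalized RMS residual of the best degree-`k`
#' least-squares harmonic fit of the surface, for `k = 1..70`. Smooth
#' (benign-like) surfaces are captured by low degrees and the curve drops
#' fast; spiculated (malignant-like) surfaces keep residual energy in high
#' degrees. Residuals are computed by incremental block Gram-Schmidt over
#' degree blocks, which is algebraically identical to refitting at every
#' order and is therefore monotone non-increasing by construction.
#'
#' When the mesh has fewer nodes than a degree needs (or more than
#' `n_max_fit`, in which case a deterministic subsample is used), the curve
#' is computed up to the largest feasible order and padded with its last
#' value; the feasible order is recorded in the `feasible_order` attribute.
#'
#' @param map a [map_to_sphere()] result.
#' @param max_order length of the feature vector (default 70).
#' @param n_max_fit node budget for the least-squares systems.
#' @return Numeric vector of length `max_order`, class `shape_feature`.
#' @export
shape_feature_vector <- function(map, max_order = 70L, n_max_fit = 1200L) {
  stopifnot(inherits(map, "spherical_map"))
  Y <- map$original_nodes
  S <- map$sphere_nodes
  n_all <- nrow(Y)
  if (n_all > n_max_fit) {
    keep <- unique(round(seq(1, n_all, length.out = n_max_fit)))
    Y <- Y[keep, , drop = FALSE]
    S <- S[keep, , drop = FALSE]
  }
  n <- nrow(Y)
  if (n < 4) nf_rank_error("too few nodes (%d) for any harmonic fit", n)
  Lfit <- min(max_order, floor(sqrt(n)) - 1L)
  if (Lfit < 1) nf_rank_error("too few nodes (%d) for an order-1 fit", n)
  if (Lfit < max_order)
    nf_msg("node deficit: fitting to order ", Lfit, ", padding to ", max_order)

  ang <- .sphere_angles(S)
  denom <- sqrt(sum(Y^2) / (3 * n))
  r <- Y
  Q <- matrix(0, n, 0)
  errs <- numeric(Lfit)
  for (l in 0:Lfit) {
    Bl <- .sh_degree_block(ang$theta, ang$phi, l)
    # orthogonalize the new degree block against everything fitted so far
    if (ncol(Q) > 0) {
      Bl <- Bl - Q %*% crossprod(Q, Bl)
      Bl <- Bl - Q %*% crossprod(Q, Bl)   # reorthogonalize for stability
    }
    dec <- qr(Bl)
    Ql <- qr.Q(dec)
    keep <- abs(diag(qr.R(dec))) > 1e-10 * sqrt(n)
    Ql <- Ql[, keep, drop = FALSE]
    if (ncol(Ql) > 0) {
      r <- r - Ql %*% crossprod(Ql, r)
      Q <- cbind(Q, Ql)
    }
    if (l >= 1) errs[l] <- sqrt(sum(r^2) / (3 * n)) / denom
  }
  errs <- cummin(pmax(errs, 0))  # guard rounding at the 1e-16 level
  out <- c(errs, rep(errs[Lfit], max_order - Lfit))
  structure(setNames(out, sprintf("sh_err_%03d", seq_len(max_order))),
            class = "shape_feature", feasible_order = Lfit)
}

# columns of the real SH basis for a single degree l
.sh_degree_block <- function(theta, phi, l) {
  B <- real_sh_basis(theta, phi, l)
  B[, (l^2 + 1):((l + 1)^2), drop = FALSE]
}
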