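# Shared fixture builders (all generated in code; no stored data).

# voxelized ball of given radius (voxels), in an n^3 grid
ball_mask <- function(radius = 8, n = 2 * ceiling(radius) + 9,
                      spacing = c(1, 1, 1)) {
  ctr <- (n + 1) / 2
  ax <- ((1:n) - ctr)
  R <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  nodule_mask(array(as.integer(R <= radius), c(n, n, n)), spacing = spacing)
}

ellipsoid_mask <- function(semi = c(8, 4, 4), spacing = c(1, 1, 1)) {
  n <- 2 * ceiling(max(semi)) + 9
  ctr <- (n + 1) / 2
  ax <- (1:n) - ctr
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  Q <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2
  nodule_mask(array(as.integer(Q <= 1), c(n, n, n)), spacing = spacing)
}

# a geodesic icosphere: subdivided icosahedron projected to the unit sphere
icosphere <- function(subdiv = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ue <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                     pmax(edges[, 1], edges[, 2])))
  nb <- vector("list", nrow(v))
  for (i in seq_len(nrow(ue))) {
    nb[[ue[i, 1]]] <- c(nb[[ue[i, 1]]], ue[i, 2])
    nb[[ue[i, 2]]] <- c(nb[[ue[i, 2]]], ue[i, 1])
  }
  structure(list(nodes = v, triangles = f, neighbors = nb,
                 spacing_used = c(1, 1, 1)),
            class = "surface_mesh")
}

# a spherical_map with identity parameterization: original nodes transformed
# by `transform` of the unit directions, sphere image = the unit directions
identity_map <- function(unit_nodes, transform = function(u) u) {
  structure(list(original_nodes = transform(unit_nodes),
                 sphere_nodes = unit_nodes,
                 cycles_run = 0L, converged = TRUE,
                 cv_initial = NA_real_, cv_final = NA_real_,
                 cv_history = numeric(0)),
            class = "spherical_map")
}

# uniform random unit vectors (seeded)
random_unit_nodes <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(3 * n), n, 3)
    m / sqrt(rowSums(m^2))
  })
}

# small fast fusion configuration for contract tests (not the defaults)
tiny_fusion_config <- function(seed = 1L) {
  fusion_config(appearance_layers = c(60L, 25L, 10L),
                epochs_pretrain = 10L, epochs_finetune = 40L,
                step_mm = 2, sh_n_max_fit = 400L, seed = seed)
}

# small fast cohort for contract tests
tiny_cohort <- function(n = 8, seed = 7) {
  make_cohort(n, 0.5,
              nodule_params = nodule_sim_params(base_radius_mm = 6),
              seed = seed)
}

# a four-marker-group feature set with controllable class contrast
synth_features <- function(n = 14, seed = 2, contrast = TRUE) {
  withr::with_seed(seed, {
    y <- rep(c("benign", "malignant"), length.out = n)
    mal <- y == "malignant"
    shape <- matrix(runif(n * 70, 0, 0.05), n, 70)
    if (contrast) shape[mal, 1:10] <- shape[mal, 1:10] + 0.05
    app <- matrix(runif(n * 1000, 0, 0.01), n, 1000)
    if (contrast) app[mal, 1:100] <- app[mal, 1:100] + 0.01
    voc <- matrix(exp(rnorm(n * 27, log(10), 0.5)), n, 27)
    if (contrast) voc[mal, 1:10] <- voc[mal, 1:10] * 2
    size <- 10 + runif(n) + if (contrast) 2 * mal else 0
    list(shape = shape, app = app, voc = voc, size = size, y = y)
  })
}

# an all-foreground record of i.i.d. Gaussian HU noise
rand_record <- function(n = 6, seed = 4, sd = 1) {
  withr::with_seed(seed, {
    vox <- array(rnorm(n^3, sd = sd), rep(n, 3))
  })
  nodule_record("r", volume3d(vox),
                nodule_mask(array(1L, rep(n, 3))))
}

# two well-separated Gaussian clusters for classifier checks
two_cluster_data <- function(n = 100, d = 10, sep = 4, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("benign", "malignant"), each = n / 2)
    X <- matrix(rnorm(n * d), n, d)
    X[y == "malignant", 1:3] <- X[y == "malignant", 1:3] + sep
    list(X = X, y = y)
  })
}

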