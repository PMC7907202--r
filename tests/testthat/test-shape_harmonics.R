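rms <- function(m) sqrt(mean(m^2))

test_that("low-degree basis matches the classical closed forms", {
  u <- random_unit_nodes(40, seed = 2)
  th <- acos(u[, 3]); ph <- atan2(u[, 2], u[, 1])
  B <- real_sh_basis(th, ph, 2)
  expect_equal(B[, 1], rep(sqrt(1 / (4 * pi)), 40), tolerance = 1e-12)
  # degree 1 (orthonormal real basis, Condon-Shortley omitted): y, z, x
  expect_equal(B[, 2], sqrt(3 / (4 * pi)) * u[, 2], tolerance = 1e-12)
  expect_equal(B[, 3], sqrt(3 / (4 * pi)) * u[, 3], tolerance = 1e-12)
  expect_equal(B[, 4], sqrt(3 / (4 * pi)) * u[, 1], tolerance = 1e-12)
  # degree 2, m = 0: sqrt(5/16pi)(3z^2 - 1)
  expect_equal(B[, 7], sqrt(5 / (16 * pi)) * (3 * u[, 3]^2 - 1),
               tolerance = 1e-12)
  # m = +/-2 sectoral pair
  expect_equal(B[, 9], sqrt(15 / (16 * pi)) * (u[, 1]^2 - u[, 2]^2),
               tolerance = 1e-12)
  expect_equal(B[, 5], sqrt(15 / (4 * pi)) * u[, 1] * u[, 2],
               tolerance = 1e-12)
  # column count and numerical health at high degree
  B70 <- real_sh_basis(th, ph, 70)
  expect_identical(ncol(B70), 5041L)
  expect_true(all(is.finite(B70)))
})

test_that("degree-1 fits are exact for spheres and linearly mapped spheres", {
  u <- random_unit_nodes(300, seed = 3)
  sphere <- identity_map(u)
  m1 <- fit_sh(sphere, 1)
  expect_lt(rms(reconstruct(m1, sphere, 1) - u), 1e-6)

  # (2,1,1) ellipsoid with identity angular parameterization
  ell <- identity_map(u, transform = function(x) x %*% diag(c(2, 1, 1)))
  m2 <- fit_sh(ell, 1)
  expect_lt(rms(reconstruct(m2, ell, 1) - ell$original_nodes), 1e-6)
})

test_that("least-squares coefficients match a normal-equations oracle", {
  u <- random_unit_nodes(50, seed = 4)
  smap <- identity_map(u, transform = function(x)
    x * (1 + 0.3 * x[, 3]^2) + 0.05 * matrix(sin(1:150), 50, 3))
  L <- 3
  model <- fit_sh(smap, L)
  th <- acos(u[, 3]); ph <- atan2(u[, 2], u[, 1])
  B <- real_sh_basis(th, ph, L)
  brute <- solve(crossprod(B), crossprod(B, smap$original_nodes))
  expect_equal(unname(model$coefficients), unname(brute), tolerance = 1e-8)
})

test_that("reconstruct honors order bounds and nesting", {
  u <- random_unit_nodes(120, seed = 5)
  smap <- identity_map(u, transform = function(x) x * (1 + 0.2 * x[, 1]))
  model <- fit_sh(smap, 4)
  expect_equal(reconstruct(model, smap, 4),
               real_sh_basis(acos(u[, 3]), atan2(u[, 2], u[, 1]), 4) %*%
                 model$coefficients,
               tolerance = 1e-12)
  r0 <- reconstruct(model, smap, 0)
  expect_equal(apply(r0, 2, function(col) diff(range(col))), rep(0, 3),
               tolerance = 1e-12)
  expect_error(reconstruct(model, smap, 5), class = "nf_bounds_error")
  expect_error(fit_sh(identity_map(random_unit_nodes(8)), 3),
               class = "nf_rank_error")
})

test_that("shape feature is a monotone 70-vector, ~0 for a sphere", {
  u <- random_unit_nodes(500, seed = 6)
  sf <- shape_feature_vector(identity_map(u))
  expect_length(sf, 70)
  expect_true(all(sf < 1e-6))

  bump <- identity_map(u, transform = function(x) {
    th <- acos(x[, 3]); ph <- atan2(x[, 2], x[, 1])
    r <- 1 + 0.2 * real_sh_basis(th, ph, 6)[, 6^2 + 7]
    x * r
  })
  sfb <- shape_feature_vector(bump)
  expect_true(all(diff(sfb) <= 1e-12))
  expect_true(all(sfb >= 0))
  # x * (1 + 0.2 Y_6) spans degrees {1, 5, 7}: exact once order 7 enters
  expect_gt(sfb[6], 100 * sfb[7])
  expect_lt(sfb[7], 1e-8)
})

test_that("normalized errors are invariant to uniform scaling", {
  mesh <- extract_mesh(ball_mask(6), step_mm = 2)
  smap <- map_to_sphere(mesh, ar_config())
  sf1 <- shape_feature_vector(smap)
  scaled <- smap
  scaled$original_nodes <- smap$original_nodes * 3.7
  sf2 <- shape_feature_vector(scaled)
  expect_equal(unname(sf1), unname(sf2), tolerance = 1e-10)
})

test_that("feature curves are stable under 90-degree rotation of the mask", {
  rec <- make_nodule("malignant", seed = 3)
  rot <- function(a) aperm(a[, dim(a)[2]:1, ], c(2, 1, 3))  # 90 deg about z
  feat <- function(vox) {
    mesh <- extract_mesh(nodule_mask(vox), step_mm = 1.5)
    shape_feature_vector(map_to_sphere(mesh, ar_config()))
  }
  f0 <- feat(rec$mask$voxels)
  f1 <- feat(rot(rec$mask$voxels))
  rel <- abs(f1[1:10] - f0[1:10]) / f0[1:10]
  expect_true(all(rel < 0.05))
})

test_that("spiculated surfaces need higher orders than smooth ones (seed 1)", {
  feat <- function(label, seed) {
    rec <- make_nodule(label, seed = seed)
    mesh <- extract_mesh(rec$mask, step_mm = 1.5)
    smap <- map_to_sphere(mesh, ar_config())
    list(map = smap, sf = shape_feature_vector(smap))
  }
  ben <- feat("benign", 1)
  mal <- feat("malignant", 1)
  # reconstruction error at order 1 is strictly larger for the spiculated shape
  err1 <- function(f) {
    m <- fit_sh(f$map, 1)
    rms(reconstruct(m, f$map, 1) - f$map$original_nodes) /
      rms(f$map$original_nodes)
  }
  expect_gt(err1(mal), err1(ben))
  expect_gt(mean(mal$sf[1:10]), mean(ben$sf[1:10]))
})
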