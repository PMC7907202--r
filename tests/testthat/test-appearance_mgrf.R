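test_that("clique codes count strict exceedances over the 6 axial neighbors", {
  const <- nodule_record("c", volume3d(array(5, c(5, 5, 5))),
                         nodule_mask(array(1L, c(5, 5, 5))))
  for (r in seq(2, 4)) expect_identical(code_clique(const$volume, c(r, r, r)), 0L)

  vox <- array(100, c(3, 3, 3))
  vox[1, 2, 2] <- 90; vox[3, 2, 2] <- 110
  vox[2, 1, 2] <- 120; vox[2, 3, 2] <- 80
  vox[2, 2, 1] <- 100; vox[2, 2, 3] <- 130
  expect_identical(code_clique(volume3d(vox), c(2, 2, 2)), 3L)

  vox6 <- array(200, c(3, 3, 3)); vox6[2, 2, 2] <- -10
  expect_identical(code_clique(volume3d(vox6), c(2, 2, 2)), 6L)

  expect_error(code_clique(volume3d(vox), c(1, 2, 2)),
               class = "nf_bounds_error")
})

test_that("empirical marginals match the exhaustive oracle and normalize", {
  rec <- rand_record(6)
  for (rho in 1:2) {
    f <- empirical_marginals(rec, rho)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    cnt <- oracle_counts(rec$volume$voxels, rec$mask$voxels, rho)
    expect_equal(f, cnt / sum(cnt), tolerance = 1e-15)
  }
  # partial mask: oracle over the masked voxels only
  msk <- rec$mask$voxels; msk[1:3, , ] <- 0L
  rec2 <- nodule_record("m", rec$volume, nodule_mask(msk))
  f2 <- empirical_marginals(rec2, 1)
  cnt2 <- oracle_counts(rec2$volume$voxels, msk, 1)
  expect_equal(f2, cnt2 / sum(cnt2), tolerance = 1e-15)
})

test_that("on i.i.d. continuous noise every code is equally likely (1/7)", {
  rec <- rand_record(50, seed = 11)   # ~1.1e5 complete cliques at rho = 1
  f <- empirical_marginals(rec, 1)
  expect_true(all(abs(f - 1 / 7) < 0.01))
})

test_that("potential estimates follow the analytic MLE formula", {
  # null deviation: F_emp equal to the core law gives zero potentials
  expect_equal(nodulefuse:::.potentials_from_marginals(rep(1 / 7, 7)),
               rep(0, 7), tolerance = 1e-15)

  # constant training volume: all mass on beta = 0
  const <- nodule_record("c", volume3d(array(7, c(8, 8, 8))),
                         nodule_mask(array(1L, c(8, 8, 8))))
  model <- learn_potentials(const, clique_config(1L))
  expect_equal(unname(model$potentials[1, 1]), -7, tolerance = 1e-12)
  expect_equal(unname(model$potentials[2:7, 1]), rep(49 / 42, 6),
               tolerance = 1e-12)
  expect_true(all(is.finite(model$potentials)))

  # energies of a constant volume under that model: -7 everywhere eligible
  emap <- gibbs_energy_map(const, model)
  expect_equal(unname(emap[!is.na(emap)]), rep(-7, 6^3), tolerance = 1e-12)
})

test_that("energy maps equal a per-voxel brute-force sum", {
  rec <- rand_record(6, seed = 5)
  cfg <- clique_config(1:2)
  model <- learn_potentials(rec, cfg)
  emap <- gibbs_energy_map(rec, model)

  d <- dim(rec$volume$voxels)
  vox <- rec$volume$voxels
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    inb <- all(c(x, y, z) - 2 >= 1) && all(c(x, y, z) + 2 <= d)
    if (!inb) {
      expect_true(is.na(emap[x, y, z]))
    } else {
      e <- 0
      for (k in 1:2) {
        rho <- cfg$radii[k]
        beta <- sum(c(vox[x - rho, y, z], vox[x + rho, y, z],
                      vox[x, y - rho, z], vox[x, y + rho, z],
                      vox[x, y, z - rho], vox[x, y, z + rho]) > vox[x, y, z])
        e <- e + model$potentials[beta + 1, k]
      }
      expect_equal(emap[x, y, z], e, tolerance = 1e-12)
    }
  }

  # zero potentials give zero energy
  model0 <- model
  model0$potentials[] <- 0
  emap0 <- gibbs_energy_map(rec, model0)
  expect_equal(unname(emap0[!is.na(emap0)]),
               rep(0, sum(!is.na(emap0))))
})

test_that("appearance histograms are 1000 normalized bins", {
  rec <- rand_record(10, seed = 6)
  model <- learn_potentials(rec, clique_config(1:2))
  h <- appearance_feature_vector(rec, model)
  expect_length(h, 1000)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_true(all(h >= 0))

  # constant energy map: all mass in a single bin
  const <- nodule_record("c", volume3d(array(3, c(7, 7, 7))),
                         nodule_mask(array(1L, c(7, 7, 7))))
  mc <- learn_potentials(const, clique_config(1L))
  hc <- appearance_feature_vector(const, mc)
  expect_identical(sum(hc > 0), 1L)
  expect_equal(max(hc), 1)
})

test_that("features are invariant to affine HU changes (ordinal coding)", {
  rec <- rand_record(8, seed = 7)
  model <- learn_potentials(rec, clique_config(1:2))
  h0 <- appearance_feature_vector(rec, model)
  shift <- rec; shift$volume$voxels <- rec$volume$voxels + 100
  gain <- rec; gain$volume$voxels <- rec$volume$voxels * 2.5
  expect_identical(h0, appearance_feature_vector(shift, model))
  expect_identical(h0, appearance_feature_vector(gain, model))
  expect_identical(unname(learn_potentials(shift, clique_config(1:2))$potentials),
                   unname(model$potentials))
})

test_that("potentials vanish on large i.i.d. volumes (core-law consistency)", {
  rec <- rand_record(50, seed = 12)
  model <- learn_potentials(rec, clique_config(1L))
  expect_true(all(abs(model$potentials) < 0.1))
})

test_that("clumped texture shifts the mean Gibbs energy (3-seed, one-sided)", {
  gaps <- vapply(1:3, function(s) {
    ben <- extract_roi(make_nodule("benign", seed = s), 6)
    mal <- extract_roi(make_nodule("malignant", seed = s + 100), 6)
    model <- learn_potentials(list(ben, mal), clique_config(1:5))
    eb <- gibbs_energy_map(ben, model)
    em <- gibbs_energy_map(mal, model)
    mean(eb, na.rm = TRUE) - mean(em, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(gaps), 0)   # homogeneous benign sits at higher energy
})

test_that("degenerate inputs raise data errors", {
  tiny <- nodule_record("t", volume3d(array(1, c(3, 3, 3))),
                        nodule_mask(array(1L, c(3, 3, 3))))
  expect_error(empirical_marginals(tiny, 5), class = "nf_data_error")
  big_model <- structure(list(radii = 5L,
                              potentials = matrix(0, 7, 1),
                              energy_range = c(0, 1)),
                         class = "mgrf_model")
  expect_error(gibbs_energy_map(tiny, big_model), class = "nf_data_error")
})
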