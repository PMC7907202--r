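test_that("nodule simulation is deterministic and class-faithful", {
  a <- make_nodule("malignant", seed = 42)
  b <- make_nodule("malignant", seed = 42)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_false(identical(a$volume$voxels,
                         make_nodule("malignant", seed = 43)$volume$voxels))

  # noise and smooth field off: constant HU inside the mask
  quiet <- nodule_sim_params(noise_sd_hu = 0, lowfreq_amp_hu = 0)
  rec <- make_nodule("benign", quiet, seed = 1)
  inside <- rec$volume$voxels[rec$mask$voxels == 1L]
  expect_identical(diff(range(inside)), 0)
  expect_equal(inside[1], quiet$hu_mean)

  # benign masks ignore the spiculation amplitude
  ben1 <- make_nodule("benign", nodule_sim_params(spiculation_amplitude = 0.3),
                      seed = 5)
  ben2 <- make_nodule("benign", nodule_sim_params(spiculation_amplitude = 0),
                      seed = 5)
  expect_identical(ben1$mask$voxels, ben2$mask$voxels)

  # oversized request fails loudly
  expect_error(make_nodule("benign",
                           nodule_sim_params(base_radius_mm = 80,
                                             max_grid = 64L), seed = 1),
               class = "nf_sizing_error")
})

test_that("spiculation increases surface area at matched base radius (seed 1)", {
  ben <- make_nodule("benign", seed = 1)
  mal <- make_nodule("malignant", nodule_sim_params(spiculation_amplitude = 0.3),
                     seed = 1)
  area_b <- mesh_area(extract_mesh(ben$mask))
  area_m <- mesh_area(extract_mesh(mal$mask))
  expect_gt(area_m, area_b)
})

test_that("VOC simulation follows the stated log-normal law", {
  null_p <- voc_sim_params(malignant_shift = rep(0, 27))
  n <- 10000
  mb <- colMeans(t(vapply(seq_len(n), function(s)
    log(make_voc_panel("benign", null_p, seed = s)$concentrations),
    numeric(27))))
  mm <- colMeans(t(vapply(seq_len(n), function(s)
    log(make_voc_panel("malignant", null_p, seed = n + s)$concentrations),
    numeric(27))))
  se <- 0.5 * sqrt(2 / n)   # SE of a difference of means, log-sd 0.5
  expect_true(all(abs(mb - mm) < 3 * se))

  shift_p <- voc_sim_params(malignant_shift = rep(1, 27),
                            n_shifted_channels = 27L)
  mm2 <- colMeans(t(vapply(seq_len(n), function(s)
    log(make_voc_panel("malignant", shift_p, seed = 2 * n + s)$concentrations),
    numeric(27))))
  expect_true(all(abs((mm2 - mb) - 1) < 3 * se))

  expect_true(all(make_voc_panel("benign", seed = 1)$concentrations > 0))
  # only the first n_shifted_channels move
  part <- voc_sim_params(malignant_shift = rep(1, 27), n_shifted_channels = 5L)
  mm3 <- colMeans(t(vapply(seq_len(n), function(s)
    log(make_voc_panel("malignant", part, seed = 5 * n + s)$concentrations),
    numeric(27))))
  expect_true(all(abs((mm3 - mb)[1:5] - 1) < 3 * se))
  expect_true(all(abs((mm3 - mb)[6:27]) < 3 * se))
})

test_that("cohorts have the prescribed composition and per-subject seeds", {
  quick <- nodule_sim_params(base_radius_mm = 4)
  co <- make_cohort(47, 37 / 47, nodule_params = quick, seed = 9)
  expect_identical(sum(co$labels == "malignant"), 37L)
  expect_identical(sum(co$labels == "benign"), 10L)
  expect_identical(nrow(co$manifest$entries), 47L)

  co0 <- make_cohort(10, 0, nodule_params = quick, seed = 2)
  expect_true(all(co0$labels == "benign"))

  co_a <- make_cohort(6, 0.5, nodule_params = quick, seed = 3)
  co_b <- make_cohort(6, 0.5, nodule_params = quick, seed = 3)
  expect_identical(co_a$manifest$entries, co_b$manifest$entries)
  expect_identical(co_a$records[[2]]$volume$voxels,
                   co_b$records[[2]]$volume$voxels)
  expect_identical(co_a$panels[[5]]$concentrations,
                   co_b$panels[[5]]$concentrations)
})

test_that("a written cohort reads back identically", {
  td <- withr::local_tempdir()
  co <- make_cohort(4, 0.5, nodule_params = nodule_sim_params(base_radius_mm = 4),
                    seed = 5)
  write_cohort(co, td)
  back <- read_cohort(td)
  expect_identical(back$labels, co$labels)
  expect_identical(back$ids, co$ids)
  for (i in 1:4) {
    expect_equal(back$records[[i]]$volume$voxels, co$records[[i]]$volume$voxels,
                 tolerance = 1e-6)
    expect_identical(back$records[[i]]$mask$voxels, co$records[[i]]$mask$voxels)
    expect_equal(unname(back$panels[[i]]$concentrations),
                 unname(co$panels[[i]]$concentrations), tolerance = 1e-12)
  }
})

test_that("stronger spiculation raises low-order reconstruction error", {
  err_low <- function(amplitude, seed) {
    p <- nodule_sim_params(spiculation_amplitude = amplitude)
    rec <- make_nodule(if (amplitude > 0) "malignant" else "malignant",
                       p, seed = seed)
    mesh <- extract_mesh(rec$mask, step_mm = 1.5)
    sf <- shape_feature_vector(map_to_sphere(mesh, ar_config()))
    mean(sf[1:10])
  }
  amps <- c(0, 0.15, 0.3)
  curves <- vapply(1:3, function(s) vapply(amps, err_low, numeric(1), seed = s),
                   numeric(3))
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) > 0))
})
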