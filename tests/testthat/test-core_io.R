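test_that("NIfTI and raw round-trips preserve voxels and spacing exactly", {
  withr::with_seed(1, {
    vox <- array(sample(-1000:400, 20^3, replace = TRUE), c(20, 20, 20))
  })
  vol <- volume3d(vox, spacing = c(0.7, 0.7, 2.5))
  for (ext in c("nii.gz", "raw")) {
    path <- file.path(withr::local_tempdir(), paste0("vol.", ext))
    write_volume(vol, path)
    back <- read_volume(path)
    expect_identical(as.integer(back$voxels), as.integer(vox))
    expect_equal(back$spacing, c(0.7, 0.7, 2.5), tolerance = 1e-6)
  }
})

test_that("load_nodule validates alignment, mask content and connectivity", {
  td <- withr::local_tempdir()
  vox <- array(0L, c(20, 20, 20)); vox[8:12, 8:12, 8:12] <- 100L
  msk <- array(0L, c(20, 20, 20)); msk[8:12, 8:12, 8:12] <- 1L
  write_volume(volume3d(vox), file.path(td, "vol.nii.gz"))
  write_volume(volume3d(msk), file.path(td, "mask.nii.gz"))
  rec <- load_nodule(file.path(td, "vol.nii.gz"), file.path(td, "mask.nii.gz"))
  expect_s3_class(rec, "nodule_record")
  expect_identical(sum(rec$mask$voxels), 125L)

  # shape mismatch
  write_volume(volume3d(array(0L, c(21, 21, 21))), file.path(td, "big.nii.gz"))
  expect_error(load_nodule(file.path(td, "vol.nii.gz"),
                           file.path(td, "big.nii.gz")),
               class = "nf_alignment_error")

  # empty mask
  write_volume(volume3d(array(0L, c(20, 20, 20))), file.path(td, "empty.nii.gz"))
  expect_error(load_nodule(file.path(td, "vol.nii.gz"),
                           file.path(td, "empty.nii.gz")),
               class = "nf_empty_mask_error")

  # two disconnected components: rejected, unless auto-repair keeps largest
  two <- array(0L, c(20, 20, 20))
  two[2:4, 2:4, 2:4] <- 1L   # 27 voxels
  two[15, 15, 15] <- 1L      # satellite
  write_volume(volume3d(two), file.path(td, "two.nii.gz"))
  expect_error(load_nodule(file.path(td, "vol.nii.gz"),
                           file.path(td, "two.nii.gz")),
               class = "nf_value_error")
  rec2 <- load_nodule(file.path(td, "vol.nii.gz"), file.path(td, "two.nii.gz"),
                      largest_component = TRUE)
  expect_identical(sum(rec2$mask$voxels), 27L)

  # unreadable format
  writeLines("not a nifti", file.path(td, "junk.nii"))
  expect_error(read_volume(file.path(td, "junk.nii")), class = "nf_format_error")
})

test_that("extract_roi crops to the padded bounding box and preserves foreground", {
  vox <- array(0, c(21, 21, 21))
  msk <- array(0L, c(21, 21, 21)); msk[11, 11, 11] <- 1L
  rec <- nodule_record("r", volume3d(vox), nodule_mask(msk))
  roi <- extract_roi(rec, pad_voxels = 2)
  expect_identical(dim(roi$volume$voxels), c(5L, 5L, 5L))
  expect_identical(sum(roi$mask$voxels), 1L)

  blk <- array(0L, c(21, 21, 21)); blk[3:6, 5:10, 7:14] <- 1L
  rec2 <- nodule_record("b", volume3d(vox), nodule_mask(blk))
  roi0 <- extract_roi(rec2, 0)
  expect_identical(dim(roi0$mask$voxels), c(4L, 6L, 8L))
  expect_identical(sum(roi0$mask$voxels), sum(blk))

  roi_big <- extract_roi(rec2, 100)
  expect_identical(dim(roi_big$mask$voxels), c(21L, 21L, 21L))

  # spacing unchanged, origin shifted to the crop corner
  expect_identical(roi0$volume$spacing, rec2$volume$spacing)
  expect_equal(roi0$volume$origin, c(2, 4, 6))
})

test_that("VOC tables enforce the 27-channel schema and preserve order", {
  td <- withr::local_tempdir()
  withr::with_seed(2, {
    panels <- lapply(1:3, function(i)
      voc_panel(paste0("p", i), runif(27, 0.1, 50)))
  })
  path <- file.path(td, "voc.csv")
  write_voc_table(panels, path)
  back <- load_voc_table(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_length(back[[i]]$concentrations, 27)
    expect_equal(unname(back[[i]]$concentrations),
                 unname(panels[[i]]$concentrations), tolerance = 1e-12)
  }

  # 26 channels -> schema error
  df <- utils::read.csv(path, check.names = FALSE)
  utils::write.csv(df[, 1:27], file.path(td, "short.csv"), row.names = FALSE)
  expect_error(load_voc_table(file.path(td, "short.csv")),
               class = "nf_schema_error")

  # negative entry -> value error
  df2 <- df; df2[2, 5] <- -1
  utils::write.csv(df2, file.path(td, "neg.csv"), row.names = FALSE)
  expect_error(load_voc_table(file.path(td, "neg.csv")),
               class = "nf_value_error")

  # non-numeric entry -> value error
  df3 <- df; df3[1, 3] <- "oops"
  utils::write.csv(df3, file.path(td, "bad.csv"), row.names = FALSE)
  expect_error(load_voc_table(file.path(td, "bad.csv")),
               class = "nf_value_error")

  expect_error(voc_panel("p", runif(26)), class = "nf_schema_error")
})

test_that("manifests enforce unique ids and binary labels", {
  good <- data.frame(id = c("a", "b"), voc_id = c("a", "b"),
                     label = c("benign", "malignant"))
  m <- cohort_manifest(good)
  td <- withr::local_tempdir()
  write_manifest(m, file.path(td, "m.csv"))
  expect_identical(read_manifest(file.path(td, "m.csv"))$entries$label,
                   c("benign", "malignant"))
  expect_error(cohort_manifest(rbind(good, good[1, ])),
               class = "nf_schema_error")
  bad <- good; bad$label[1] <- "weird"
  expect_error(cohort_manifest(bad), class = "nf_value_error")
})
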