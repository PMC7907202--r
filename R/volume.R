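#' 3-D CT volume in Hounsfield units
#'
#' A `volume3d` wraps a 3-D numeric array of HU values together with its voxel
#' spacing and world origin. Arrays are indexed `[x, y, z]` (1-based); the
#' world coordinate of voxel `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param voxels 3-D numeric array of finite HU values.
#' @param spacing numeric length-3, voxel edge lengths (dx, dy, dz) in mm,
#'   all strictly positive.
#' @param origin numeric length-3, world position of voxel (1, 1, 1) in mm.
#' @return An object of class `volume3d` with fields `voxels`, `spacing`,
#'   `origin`.
#' @export
volume3d <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    nf_format_error("voxels must be a 3-D array")
  if (any(dim(voxels) < 1L))
    nf_format_error("all three volume dimensions must be positive")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    nf_value_error("spacing must be three strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    nf_value_error("origin must be three finite values")
  if (any(!is.finite(voxels)))
    nf_value_error("HU values must all be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' Binary nodule mask
#'
#' A `nodule_mask` is a binary grid aligned with its `volume3d`. A valid mask
#' has at least one foreground voxel forming a single 26-connected component;
#' multi-component masks are rejected unless `largest_component = TRUE`, which
#' keeps only the largest component (tie broken by first label encountered).
#'
#' @param voxels 3-D array with values in {0, 1} (logical accepted).
#' @param spacing voxel spacing in mm, as in [volume3d()].
#' @param largest_component keep the largest 26-connected component instead of
#'   rejecting multi-component masks.
#' @return An object of class `nodule_mask`.
#' @export
nodule_mask <- function(voxels, spacing = c(1, 1, 1), largest_component = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    nf_format_error("mask voxels must be a 3-D array")
  v <- voxels
  storage.mode(v) <- "integer"
  if (any(is.na(v)) || !all(v %in% c(0L, 1L)))
    nf_value_error("mask values must be 0 or 1")
  if (sum(v) == 0L)
    nf_empty_mask_error("mask has no foreground voxel")
  ncomp <- cpp_n_components_26(as.integer(v), dim(v))
  if (ncomp > 1L) {
    if (!largest_component)
      nf_value_error(paste0("mask has ", ncomp, " 26-connected components; ",
                            "expected exactly 1 (use largest_component = TRUE to repair)"))
    v <- .largest_component_26(v)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    nf_value_error("spacing must be three strictly positive values")
  structure(list(voxels = v, spacing = spacing), class = "nodule_mask")
}

.largest_component_26 <- function(v) {
  # label by repeated flood fill: peel components until none remain
  best <- NULL; best_n <- -1L
  rem <- v
  while (sum(rem) > 0L) {
    seed <- which(rem == 1L)[1L]
    comp <- .flood_26(rem, seed)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    rem[comp == 1L] <- 0L
  }
  best
}

.flood_26 <- function(v, seed) {
  d <- dim(v)
  out <- array(0L, d)
  stack <- seed
  out[seed] <- 1L
  idx <- arrayInd(seed, d)
  queue <- list(idx)
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (any(q < 1L) || any(q > d)) next
      if (v[q[1], q[2], q[3]] == 1L && out[q[1], q[2], q[3]] == 0L) {
        out[q[1], q[2], q[3]] <- 1L
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  out
}

#' One nodule: CT sub-volume, aligned mask, and label
#'
#' @param id character identifier.
#' @param volume a [volume3d()].
#' @param mask a [nodule_mask()] with the same grid shape as `volume`.
#' @param label one of `"benign"`, `"malignant"`, `"unknown"`.
#' @return An object of class `nodule_record`.
#' @export
nodule_record <- function(id, volume, mask, label = "unknown") {
  stopifnot(inherits(volume, "volume3d"), inherits(mask, "nodule_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    nf_alignment_error("volume and mask grid shapes differ (%s vs %s)",
                       paste(dim(volume$voxels), collapse = "x"),
                       paste(dim(mask$voxels), collapse = "x"))
  if (max(abs(volume$spacing - mask$spacing)) > 1e-6)
    nf_alignment_error("volume and mask voxel spacings differ")
  label <- match.arg(label, c("benign", "malignant", "unknown"))
  structure(list(id = as.character(id), volume = volume, mask = mask,
                 label = label),
            class = "nodule_record")
}

#' @export
print.nodule_record <- function(x, ...) {
  cat(sprintf("<nodule_record '%s'> %s voxels @ %s mm, %d foreground, label=%s\n",
              x$id, paste(dim(x$volume$voxels), collapse = "x"),
              paste(signif(x$volume$spacing, 3), collapse = "x"),
              sum(x$mask$voxels), x$label))
  invisible(x)
}

# ---- NIfTI / raw I/O --------------------------------------------------------

#' Read a volume from NIfTI or raw + JSON sidecar
#'
#' `.nii`/`.nii.gz` files are read with RNifti; any other path is treated as a
#' raw little-endian binary with a JSON sidecar `<path>.json` carrying
#' `{shape, spacing, dtype, origin}` (`dtype` one of `int16`, `int32`,
#' `float64`).
#'
#' @param path file path.
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) nf_format_error("file not found: %s", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e) nf_format_error("unreadable NIfTI %s: %s",
                                                        path, conditionMessage(e)))
    arr <- array(as.numeric(img), dim = dim(img))
    sp <- RNifti::pixdim(img)[seq_len(3)]
    volume3d(arr, spacing = sp)
  } else {
    side <- paste0(path, ".json")
    if (!file.exists(side)) nf_format_error("missing sidecar %s", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    need <- c("shape", "spacing", "dtype")
    if (!all(need %in% names(meta)))
      nf_format_error("sidecar %s lacks fields %s", side,
                      paste(setdiff(need, names(meta)), collapse = ", "))
    what <- switch(meta$dtype,
                   int16 = list(mode = "integer", size = 2L),
                   int32 = list(mode = "integer", size = 4L),
                   float64 = list(mode = "double", size = 8L),
                   nf_format_error("unsupported dtype '%s'", meta$dtype))
    n <- prod(meta$shape)
    raw <- readBin(path, what = what$mode, n = n, size = what$size,
                   endian = "little")
    if (length(raw) != n) nf_format_error("raw file %s truncated", path)
    origin <- if (!is.null(meta$origin)) meta$origin else c(0, 0, 0)
    volume3d(array(as.numeric(raw), dim = meta$shape),
             spacing = meta$spacing, origin = origin)
  }
}

#' Write a volume as NIfTI or raw + JSON sidecar
#'
#' Integer-valued grids are stored as integers so HU round-trips bit-exactly.
#'
#' @param vol a [volume3d()] or [nodule_mask()].
#' @param path destination; `.nii`/`.nii.gz` selects NIfTI.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  voxels <- vol$voxels
  spacing <- vol$spacing
  is_int <- all(voxels == round(voxels)) &&
    max(abs(voxels)) <= .Machine$integer.max
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- voxels
    if (is_int) storage.mode(arr) <- "integer"
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path, datatype = if (is_int) "int32" else "double")
  } else {
    dtype <- if (is_int) "int32" else "float64"
    con <- file(path, "wb")
    on.exit(close(con))
    if (is_int) writeBin(as.integer(voxels), con, size = 4L, endian = "little")
    else writeBin(as.numeric(voxels), con, size = 8L, endian = "little")
    origin <- if (is.null(vol$origin)) c(0, 0, 0) else vol$origin
    jsonlite::write_json(list(shape = dim(voxels), spacing = spacing,
                              dtype = dtype, origin = origin),
                         paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Load a nodule (volume + aligned mask) from disk
#'
#' @param volume_path,mask_path paths accepted by [read_volume()].
#' @param id record identifier (default: volume file stem).
#' @param label optional label.
#' @param largest_component passed to [nodule_mask()].
#' @return A validated [nodule_record()].
#' @export
load_nodule <- function(volume_path, mask_path, id = NULL, label = "unknown",
                        largest_component = FALSE) {
  vol <- read_volume(volume_path)
  mvol <- read_volume(mask_path)
  if (!identical(dim(vol$voxels), dim(mvol$voxels)))
    nf_alignment_error("mask grid %s does not match volume grid %s",
                       paste(dim(mvol$voxels), collapse = "x"),
                       paste(dim(vol$voxels), collapse = "x"))
  if (max(abs(vol$spacing - mvol$spacing)) > 1e-6)
    nf_alignment_error("mask spacing does not match volume spacing")
  msk <- nodule_mask(mvol$voxels, spacing = mvol$spacing,
                     largest_component = largest_component)
  if (is.null(id))
    id <- sub("\\.nii(\\.gz)?$", "", basename(volume_path))
  nodule_record(id, vol, msk, label = label)
}

#' Crop a nodule record to its mask bounding box
#'
#' The bounding box of the mask foreground is dilated by `pad_voxels` on every
#' side and clipped to the volume bounds; spacing is unchanged and the mask
#' foreground count is preserved.
#'
#' @param record a [nodule_record()].
#' @param pad_voxels non-negative integer padding.
#' @return A cropped [nodule_record()].
#' @export
extract_roi <- function(record, pad_voxels = 0L) {
  stopifnot(inherits(record, "nodule_record"), pad_voxels >= 0)
  pad <- as.integer(pad_voxels)
  m <- record$mask$voxels
  d <- dim(m)
  idx <- which(m == 1L)
  ai <- arrayInd(idx, d)
  lo <- pmax(apply(ai, 2, min) - pad, 1L)
  hi <- pmin(apply(ai, 2, max) + pad, d)
  sl <- lapply(1:3, function(k) lo[k]:hi[k])
  newvol <- volume3d(record$volume$voxels[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
                     spacing = record$volume$spacing,
                     origin = record$volume$origin +
                       (lo - 1) * record$volume$spacing)
  newmask <- nodule_mask(m[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
                         spacing = record$mask$spacing)
  nodule_record(record$id, newvol, newmask, label = record$label)
}
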