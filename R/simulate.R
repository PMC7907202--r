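#' Synthetic nodule simulation parameters
#'
#' Controls the geometry and texture of simulated nodules. Benign nodules
#' are spheres of radius `base_radius_mm` with homogeneous attenuation (a
#' constant plus an optional smooth low-frequency field plus Gaussian
#' noise). Malignant nodules have their radial surface modulated by random
#' spherical harmonics of degree `spiculation_degree` with relative
#' amplitude `spiculation_amplitude` (spiculation), and a two-level clumped
#' attenuation field of contrast `texture_contrast_hu` at spatial scale
#' `texture_clump_mm` (spatial non-homogeneity).
#'
#' Defaults place the nodule inside the 4-20 mm diameter range typical of
#' screening-detected nodules at CT-plausible soft-tissue attenuation.
#'
#' @param base_radius_mm nodule radius in mm.
#' @param spiculation_amplitude surface perturbation as a fraction of the
#'   radius, in `[0, 1)`.
#' @param spiculation_degree spherical-harmonic degree of the perturbation.
#' @param texture_contrast_hu HU contrast between the two texture levels.
#' @param texture_clump_mm spatial scale of the texture clumps.
#' @param noise_sd_hu additive Gaussian noise SD.
#' @param lowfreq_amp_hu amplitude of the benign smooth low-frequency field
#'   (0 disables).
#' @param lowfreq_scale_mm spatial scale of that field.
#' @param hu_mean mean attenuation inside the nodule.
#' @param background_hu attenuation outside the nodule.
#' @param spacing_mm voxel spacing triple.
#' @param max_grid refuse grids larger than this per axis.
#' @return A `nodule_sim_params` list.
#' @export
nodule_sim_params <- function(base_radius_mm = 8, spiculation_amplitude = 0.25,
                              spiculation_degree = 8L,
                              texture_contrast_hu = 120, texture_clump_mm = 3,
                              noise_sd_hu = 10, lowfreq_amp_hu = 10,
                              lowfreq_scale_mm = 5, hu_mean = -50,
                              background_hu = -800, spacing_mm = c(1, 1, 1),
                              max_grid = 192L) {
  stopifnot(base_radius_mm > 0, spiculation_amplitude >= 0,
            spiculation_amplitude < 1, spiculation_degree >= 2,
            texture_contrast_hu >= 0, texture_clump_mm > 0, noise_sd_hu >= 0,
            lowfreq_amp_hu >= 0, all(spacing_mm > 0))
  structure(list(base_radius_mm = base_radius_mm,
                 spiculation_amplitude = spiculation_amplitude,
                 spiculation_degree = as.integer(spiculation_degree),
                 texture_contrast_hu = texture_contrast_hu,
                 texture_clump_mm = texture_clump_mm,
                 noise_sd_hu = noise_sd_hu,
                 lowfreq_amp_hu = lowfreq_amp_hu,
                 lowfreq_scale_mm = lowfreq_scale_mm,
                 hu_mean = hu_mean, background_hu = background_hu,
                 spacing_mm = rep_len(as.numeric(spacing_mm), 3),
                 max_grid = as.integer(max_grid)),
            class = "nodule_sim_params")
}

#' Synthetic VOC panel parameters
#'
#' Concentrations are log-normal per channel; malignant panels receive an
#' additive shift on the log scale on the first `n_shifted_channels`
#' channels. Defaults emulate a panel where a subset of carbonyl compounds
#' is moderately elevated in malignancy, giving breath markers alone
#' discriminative power well short of the imaging markers.
#'
#' @param log_mean_benign length-27 benign log-mean (log nmol/L).
#' @param log_sd length-27 positive log-scale SD.
#' @param malignant_shift length-27 additive log-scale shift.
#' @param n_shifted_channels how many leading channels receive the shift.
#' @return A `voc_sim_params` list.
#' @export
voc_sim_params <- function(log_mean_benign = rep(log(10), 27),
                           log_sd = rep(0.5, 27),
                           malignant_shift = rep(0.4, 27),
                           n_shifted_channels = 10L) {
  stopifnot(length(log_mean_benign) == 27, length(log_sd) == 27,
            length(malignant_shift) == 27, all(log_sd > 0),
            n_shifted_channels >= 0, n_shifted_channels <= 27)
  structure(list(log_mean_benign = log_mean_benign, log_sd = log_sd,
                 malignant_shift = malignant_shift,
                 n_shifted_channels = as.integer(n_shifted_channels)),
            class = "voc_sim_params")
}

#' Null-control simulation parameters
#'
#' Parameter pair in which every benign/malignant contrast is switched off:
#' no spiculation, no texture contrast, no low-frequency field, no VOC
#' shift. Both classes then follow the identical generative law, so any
#' classifier evaluated on such a cohort can only perform at chance; useful
#' as a negative control for the pipeline.
#'
#' @return list with elements `nodule` and `voc`.
#' @export
zero_contrast_params <- function() {
  list(nodule = nodule_sim_params(spiculation_amplitude = 0,
                                  texture_contrast_hu = 0,
                                  lowfreq_amp_hu = 0),
       voc = voc_sim_params(malignant_shift = rep(0, 27)))
}

#' Simulate one nodule
#'
#' Deterministic given `(label, params, seed)`. The radial surface
#' \eqn{r(\theta,\phi)} is the base radius, modulated for malignant nodules
#' by a random spherical-harmonic combination of degree
#' `spiculation_degree` normalized to peak amplitude
#' `spiculation_amplitude`; the mask contains every voxel inside that
#' surface. Attenuation follows the class-specific law described in
#' [nodule_sim_params()].
#'
#' @param label `"benign"` or `"malignant"`.
#' @param params a [nodule_sim_params()].
#' @param seed integer seed.
#' @param id record id (default derived from label and seed).
#' @return A [nodule_record()].
#' @export
make_nodule <- function(label = c("benign", "malignant"),
                        params = nodule_sim_params(), seed = 1L,
                        id = NULL) {
  label <- match.arg(label)
  stopifnot(inherits(params, "nodule_sim_params"))
  p <- params
  amp <- if (label == "malignant") p$spiculation_amplitude else 0
  half_mm <- p$base_radius_mm * (1 + amp) + 3
  nvox <- 2L * as.integer(ceiling(half_mm / p$spacing_mm)) + 1L
  if (any(nvox > p$max_grid))
    nf_sizing_error("perturbed surface needs a %s grid, exceeding max_grid = %d",
                    paste(nvox, collapse = "x"), p$max_grid)
  ctr <- (nvox + 1) / 2
  ax <- lapply(1:3, function(k) (seq_len(nvox[k]) - ctr[k]) * p$spacing_mm[k])
  X <- array(rep(ax[[1]], times = nvox[2] * nvox[3]), nvox)
  Y <- array(rep(rep(ax[[2]], each = nvox[1]), times = nvox[3]), nvox)
  Z <- array(rep(ax[[3]], each = nvox[1] * nvox[2]), nvox)
  R <- sqrt(X^2 + Y^2 + Z^2)

  withr::with_seed(as.integer(seed), {
    if (label == "malignant" && amp > 0) {
      l <- p$spiculation_degree
      a <- rnorm(2 * l + 1)
      theta <- acos(pmin(pmax(ifelse(R > 0, Z / R, 1), -1), 1))
      phi <- atan2(Y, X)
      s <- .sh_degree_block(as.numeric(theta), as.numeric(phi), l) %*% a
      s <- s / max(abs(s))
      rad <- p$base_radius_mm * (1 + p$spiculation_amplitude * array(s, nvox))
    } else {
      rad <- array(p$base_radius_mm, nvox)
    }
    mask <- array(as.integer(R <= rad), nvox)

    hu <- array(p$background_hu, nvox)
    if (label == "malignant" && p$texture_contrast_hu > 0) {
      t <- gaussian_smooth_3d(array(rnorm(prod(nvox)), nvox),
                              p$texture_clump_mm / p$spacing_mm)
      thr <- stats::median(t[mask == 1L])
      lev <- ifelse(t > thr, p$texture_contrast_hu / 2,
                    -p$texture_contrast_hu / 2)
      hu[mask == 1L] <- p$hu_mean + lev[mask == 1L]
    } else {
      base <- array(p$hu_mean, nvox)
      if (p$lowfreq_amp_hu > 0) {
        f <- gaussian_smooth_3d(array(rnorm(prod(nvox)), nvox),
                                p$lowfreq_scale_mm / p$spacing_mm)
        f <- f / stats::sd(f)
        base <- base + p$lowfreq_amp_hu * f
      }
      hu[mask == 1L] <- base[mask == 1L]
    }
    if (p$noise_sd_hu > 0)
      hu <- hu + array(rnorm(prod(nvox), sd = p$noise_sd_hu), nvox)

    if (is.null(id)) id <- sprintf("sim_%s_%d", label, as.integer(seed))
    nodule_record(id,
                  volume3d(hu, spacing = p$spacing_mm),
                  nodule_mask(mask, spacing = p$spacing_mm,
                              largest_component = TRUE),
                  label = label)
  })
}

#' Simulate one VOC panel
#'
#' Concentrations are `exp(N(mu, log_sd))` with `mu = log_mean_benign`
#' plus, for malignant panels, `malignant_shift` on the first
#' `n_shifted_channels` channels. Deterministic given `(label, params,
#' seed)`.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param params a [voc_sim_params()].
#' @param seed integer seed.
#' @param patient_id id for the panel.
#' @return A [voc_panel()].
#' @export
make_voc_panel <- function(label = c("benign", "malignant"),
                           params = voc_sim_params(), seed = 1L,
                           patient_id = NULL) {
  label <- match.arg(label)
  stopifnot(inherits(params, "voc_sim_params"))
  mu <- params$log_mean_benign
  if (label == "malignant" && params$n_shifted_channels > 0) {
    sel <- seq_len(params$n_shifted_channels)
    mu[sel] <- mu[sel] + params$malignant_shift[sel]
  }
  if (is.null(patient_id)) patient_id <- sprintf("sim_%s_%d", label,
                                                 as.integer(seed))
  withr::with_seed(as.integer(seed),
                   voc_panel(patient_id, exp(rnorm(27, mu, params$log_sd))))
}

#' Simulate a cohort of nodules with matched VOC panels
#'
#' `round(prevalence * n)` subjects are malignant; class order is shuffled
#' and every subject gets its own sub-seed derived from `seed`, so the
#' cohort is reproducible as a whole and per subject.
#'
#' @param n number of subjects (>= 2).
#' @param prevalence malignant fraction in `[0, 1]`.
#' @param nodule_params a [nodule_sim_params()].
#' @param voc_params a [voc_sim_params()].
#' @param seed integer seed.
#' @return A `nodule_cohort`: list with `manifest` ([cohort_manifest()]),
#'   `records`, `panels`, `labels`, `ids`.
#' @export
make_cohort <- function(n, prevalence = 0.5,
                        nodule_params = nodule_sim_params(),
                        voc_params = voc_sim_params(), seed = 1L) {
  stopifnot(n >= 2, prevalence >= 0, prevalence <= 1)
  n <- as.integer(n)
  n_mal <- as.integer(round(prevalence * n))
  withr::with_seed(as.integer(seed), {
    labels <- sample(c(rep("malignant", n_mal), rep("benign", n - n_mal)))
    subseeds <- sample.int(2^28, 2L * n)
  })
  ids <- sprintf("subj_%03d", seq_len(n))
  records <- lapply(seq_len(n), function(i)
    make_nodule(labels[i], nodule_params, seed = subseeds[2L * i - 1L],
                id = ids[i]))
  panels <- lapply(seq_len(n), function(i)
    make_voc_panel(labels[i], voc_params, seed = subseeds[2L * i],
                   patient_id = ids[i]))
  manifest <- cohort_manifest(data.frame(id = ids, voc_id = ids,
                                         label = labels,
                                         stringsAsFactors = FALSE),
                              provenance = sprintf("simulated cohort, seed %d",
                                                   as.integer(seed)))
  structure(list(manifest = manifest, records = records, panels = panels,
                 labels = labels, ids = ids, seed = as.integer(seed)),
            class = "nodule_cohort")
}

#' @export
print.nodule_cohort <- function(x, ...) {
  cat(sprintf("<nodule_cohort> %d subjects (%d malignant / %d benign)\n",
              length(x$ids), sum(x$labels == "malignant"),
              sum(x$labels == "benign")))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one NIfTI volume and mask per subject under `dir/nodules/`, the
#' VOC table as `voc.csv`, and the manifest (with file paths) as
#' `manifest.csv`.
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  ndir <- file.path(dir, "nodules")
  dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
  vp <- file.path("nodules", paste0(cohort$ids, "_vol.nii.gz"))
  mp <- file.path("nodules", paste0(cohort$ids, "_mask.nii.gz"))
  for (i in seq_along(cohort$ids)) {
    write_volume(cohort$records[[i]]$volume, file.path(dir, vp[i]))
    write_volume(cohort$records[[i]]$mask, file.path(dir, mp[i]))
  }
  write_voc_table(cohort$panels, file.path(dir, "voc.csv"))
  ent <- cohort$manifest$entries
  ent$volume_path <- vp
  ent$mask_path <- mp
  write_manifest(cohort_manifest(ent, cohort$manifest$provenance),
                 file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv`, `voc.csv` and `nodules/`.
#' @return A `nodule_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  ent <- manifest$entries
  panels_all <- load_voc_table(file.path(dir, "voc.csv"))
  pid <- vapply(panels_all, `[[`, "", "patient_id")
  records <- lapply(seq_len(nrow(ent)), function(i)
    load_nodule(file.path(dir, ent$volume_path[i]),
                file.path(dir, ent$mask_path[i]),
                id = ent$id[i], label = ent$label[i]))
  panels <- panels_all[match(ent$voc_id, pid)]
  if (any(vapply(panels, is.null, TRUE)))
    nf_schema_error("manifest references VOC panels missing from voc.csv")
  structure(list(manifest = manifest, records = records, panels = panels,
                 labels = ent$label, ids = ent$id, seed = NA_integer_),
            class = "nodule_cohort")
}
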