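#' Clique family configuration for the 7th-order MGRF
#'
#' Each clique family couples a voxel with its 6 axial neighbors (+/-x,
#' +/-y, +/-z) at distance `rho` voxels — 7 voxels per clique. One family
#' per radius in `radii`.
#'
#' @param radii distinct positive integer radii (voxel units).
#' @return A `clique_config` list.
#' @export
clique_config <- function(radii = 1:5) {
  radii <- as.integer(radii)
  if (length(radii) == 0 || any(radii < 1) || anyDuplicated(radii))
    nf_value_error("radii must be distinct positive integers")
  structure(list(radii = radii), class = "clique_config")
}

# beta codes for every voxel of a volume at one radius: the number of the 6
# axial neighbors at distance rho whose HU strictly exceeds the center.
# Voxels whose clique leaves the grid get NA.
clique_codes <- function(voxels, rho) {
  d <- dim(voxels)
  if (any(d <= 2 * rho)) return(array(NA_integer_, d))
  cnt <- array(0L, d)
  for (axis in 1:3) for (sgn in c(-1L, 1L)) {
    nb <- .shift_axis(voxels, -sgn * rho, axis)  # value of neighbor at +sgn*rho
    cnt <- cnt + (nb > voxels)
  }
  core <- lapply(1:3, function(k) (rho + 1L):(d[k] - rho))
  out <- array(NA_integer_, d)
  out[core[[1]], core[[2]], core[[3]]] <-
    cnt[core[[1]], core[[2]], core[[3]]]
  out
}

#' Ordinal clique code at a single voxel
#'
#' beta = number of the 6 axial neighbors at distance `rho` with HU strictly
#' greater than the center voxel; ties count as "not greater". beta ranges
#' over `{0, ..., 6}` and is invariant to any monotone (offset/contrast)
#' transform of the HU scale.
#'
#' @param volume a [volume3d()].
#' @param r voxel index triple (1-based).
#' @param rho clique radius in voxels.
#' @return Integer in 0..6.
#' @export
code_clique <- function(volume, r, rho = 1L) {
  stopifnot(inherits(volume, "volume3d"), length(r) == 3)
  d <- dim(volume$voxels)
  r <- as.integer(r)
  if (any(r - rho < 1L) || any(r + rho > d))
    nf_bounds_error("clique at (%s) with rho = %d leaves the grid",
                    paste(r, collapse = ","), rho)
  ctr <- volume$voxels[r[1], r[2], r[3]]
  nb <- c(volume$voxels[r[1] - rho, r[2], r[3]],
          volume$voxels[r[1] + rho, r[2], r[3]],
          volume$voxels[r[1], r[2] - rho, r[3]],
          volume$voxels[r[1], r[2] + rho, r[3]],
          volume$voxels[r[1], r[2], r[3] - rho],
          volume$voxels[r[1], r[2], r[3] + rho])
  sum(nb > ctr)
}

#' Empirical marginal distribution of clique codes
#'
#' Pooled relative frequencies of beta over all in-mask voxels of the
#' training records whose full clique lies inside the grid, for one radius.
#'
#' @param records a [nodule_record()] or list of them.
#' @param rho clique radius.
#' @return Numeric length-7 probability vector (codes 0..6).
#' @export
empirical_marginals <- function(records, rho = 1L) {
  if (inherits(records, "nodule_record")) records <- list(records)
  counts <- rep(0, 7)
  for (rec in records) {
    codes <- clique_codes(rec$volume$voxels, rho)
    sel <- rec$mask$voxels == 1L & !is.na(codes)
    if (any(sel)) counts <- counts + tabulate(codes[sel] + 1L, 7L)
  }
  if (sum(counts) == 0)
    nf_data_error("no complete clique of radius %d inside any training mask",
                  rho)
  counts / sum(counts)
}

# uniform core law: the center's rank among 7 i.i.d. continuous signals
.f_core <- rep(1 / 7, 7)

#' Learn the MGRF potentials from training nodules
#'
#' Analytic maximum-likelihood approximation of the Gibbs potentials,
#' \deqn{\upsilon_{7:\rho}(\beta) = \frac{F_{core}(\beta) -
#'   F_{emp}(\beta)}{F_{core}(\beta)\,(1 - F_{core}(\beta))},}
#' with the uniform core distribution `F_core = 1/7` (the marginal law of
#' the code under independent continuous signals). The range of the training
#' Gibbs energies is recorded for histogram binning at inference.
#'
#' @param records list of training [nodule_record()]s.
#' @param config a [clique_config()].
#' @return An `mgrf_model`: `radii`, `potentials` (7 x n_radii matrix, rows
#'   beta = 0..6), `energy_range`.
#' @export
learn_potentials <- function(records, config = clique_config()) {
  if (inherits(records, "nodule_record")) records <- list(records)
  tables <- lapply(records, clique_code_table, radii = config$radii)
  .learn_from_tables(tables, config$radii)
}

.potentials_from_marginals <- function(f_emp) {
  (.f_core - f_emp) / (.f_core * (1 - .f_core))
}

.learn_from_tables <- function(tables, radii) {
  nr <- length(radii)
  pot <- matrix(0, 7, nr, dimnames = list(beta = 0:6, rho = radii))
  for (k in seq_len(nr)) {
    counts <- Reduce(`+`, lapply(tables, function(t) t$marginal_counts[, k]))
    if (sum(counts) == 0)
      nf_data_error("no complete clique of radius %d in the training set",
                    radii[k])
    pot[, k] <- .potentials_from_marginals(counts / sum(counts))
  }
  energies <- unlist(lapply(tables, function(t)
    .energies_from_codes(t$codes, pot)))
  if (length(energies) == 0)
    nf_data_error("no voxel with complete cliques at all radii in training set")
  structure(list(radii = radii, potentials = pot,
                 energy_range = range(energies)),
            class = "mgrf_model")
}

# Per-record cached code summaries so fold-wise relearning never rescans the
# volumes: per-radius marginal counts (over in-mask voxels with a complete
# clique at that radius) and the per-voxel code matrix over in-mask voxels
# with complete cliques at every radius (for energies).
clique_code_table <- function(record, radii) {
  stopifnot(inherits(record, "nodule_record"))
  d <- dim(record$volume$voxels)
  inmask <- record$mask$voxels == 1L
  nr <- length(radii)
  code_arrays <- lapply(radii, function(r) clique_codes(record$volume$voxels, r))
  marginal_counts <- matrix(0, 7, nr)
  for (k in seq_len(nr)) {
    sel <- inmask & !is.na(code_arrays[[k]])
    if (any(sel))
      marginal_counts[, k] <- tabulate(code_arrays[[k]][sel] + 1L, 7L)
  }
  all_ok <- inmask
  for (k in seq_len(nr)) all_ok <- all_ok & !is.na(code_arrays[[k]])
  codes <- vapply(seq_len(nr),
                  function(k) as.integer(code_arrays[[k]][all_ok]),
                  integer(sum(all_ok)))
  codes <- matrix(codes, ncol = nr)
  list(marginal_counts = marginal_counts, codes = codes,
       eligible_index = which(all_ok),
       n_inmask = sum(inmask), n_excluded = sum(inmask) - sum(all_ok))
}

.energies_from_codes <- function(codes, potentials) {
  if (nrow(codes) == 0) return(numeric(0))
  e <- numeric(nrow(codes))
  for (k in seq_len(ncol(codes))) e <- e + potentials[codes[, k] + 1L, k]
  e
}

#' Voxel-wise Gibbs energy of a nodule under an MGRF model
#'
#' \eqn{e(r) = \sum_\rho \upsilon_{7:\rho}(\beta_\rho(r))} for every in-mask
#' voxel whose cliques at all model radii are complete; other voxels are NA
#' and the in-mask exclusion count is recorded in attribute `n_excluded`.
#'
#' @param record a [nodule_record()].
#' @param model an [learn_potentials()] result.
#' @return Array of energies (NA outside the eligible set).
#' @export
gibbs_energy_map <- function(record, model) {
  stopifnot(inherits(record, "nodule_record"), inherits(model, "mgrf_model"))
  tab <- clique_code_table(record, model$radii)
  if (nrow(tab$codes) == 0)
    nf_data_error("no in-mask voxel with complete cliques at all radii %s",
                  paste(model$radii, collapse = ","))
  out <- array(NA_real_, dim(record$volume$voxels))
  out[tab$eligible_index] <- .energies_from_codes(tab$codes, model$potentials)
  attr(out, "n_excluded") <- tab$n_excluded
  out
}

#' Appearance feature: Gibbs-energy histogram
#'
#' 1000 equal-width bins spanning the model's training `energy_range`
#' (values clamped into range), normalized to sum 1.
#'
#' @param record a [nodule_record()].
#' @param model an `mgrf_model`.
#' @return Numeric length-1000 probability vector, class
#'   `appearance_feature`.
#' @export
appearance_feature_vector <- function(record, model) {
  emap <- gibbs_energy_map(record, model)
  .energy_histogram(emap[!is.na(emap)], model$energy_range)
}

.energy_histogram <- function(e, rng, nbins = 1000L) {
  if (length(e) == 0) nf_data_error("empty energy sample")
  width <- rng[2] - rng[1]
  if (width <= 0) {
    h <- c(length(e), rep(0, nbins - 1L))
  } else {
    idx <- pmin(pmax(floor((e - rng[1]) / width * nbins) + 1L, 1L), nbins)
    h <- tabulate(idx, nbins)
  }
  structure(setNames(h / sum(h), sprintf("mgrf_bin_%04d", seq_len(nbins))),
            class = "appearance_feature")
}
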