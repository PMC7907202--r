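#' Size feature of a nodule
#'
#' Volume is the foreground voxel count times the voxel volume; size is
#' summarized as the equivalent sphere diameter `d = (6V/pi)^(1/3)`, the
#' convention used to characterize nodules by diameter.
#'
#' @param record a [nodule_record()].
#' @return A `size_feature` with `volume_mm3` and `equivalent_diameter_mm`.
#' @export
size_feature <- function(record) {
  stopifnot(inherits(record, "nodule_record"))
  nfg <- sum(record$mask$voxels)
  if (nfg == 0) nf_empty_mask_error("empty mask")
  V <- nfg * prod(record$mask$spacing)
  structure(list(volume_mm3 = V,
                 equivalent_diameter_mm = (6 * V / pi)^(1 / 3)),
            class = "size_feature")
}

#' k-NN malignancy probability from nodule size
#'
#' The basic size classifier: the malignant fraction among the `k` training
#' nodules nearest in equivalent diameter (absolute difference). Distance
#' ties are broken by training-record order.
#'
#' @param query_d equivalent diameter (mm) of the query nodule, or a
#'   `size_feature`.
#' @param training_d numeric vector of training diameters.
#' @param training_labels matching labels (`"benign"`/`"malignant"`).
#' @param k neighborhood size, `<= length(training_d)`.
#' @return Malignancy probability in `{0, 1/k, ..., 1}`.
#' @export
knn_size_probability <- function(query_d, training_d, training_labels, k = 5L) {
  if (inherits(query_d, "size_feature")) query_d <- query_d$equivalent_diameter_mm
  n <- length(training_d)
  if (n == 0) nf_data_error("empty training set for the size k-NN")
  stopifnot(length(training_labels) == n, k >= 1, k <= n)
  ord <- order(abs(training_d - query_d), seq_len(n))  # stable tie-break
  mean(training_labels[ord[seq_len(k)]] == "malignant")
}

#' Breath-feature normalizer
#'
#' Per-channel affine standardization on the log scale:
#' `z = (log(c + eps) - location) / scale`, with location/scale the training
#' mean/SD and the scale floored at `scale_floor` so constant channels map
#' to finite zeros.
#'
#' @param panels list of training [voc_panel()]s (>= 2).
#' @param eps offset before the log (concentrations may be 0).
#' @param scale_floor lower bound on the per-channel SD.
#' @return A `breath_normalizer`.
#' @export
fit_breath_normalizer <- function(panels, eps = 1e-6, scale_floor = 1e-8) {
  if (inherits(panels, "voc_panel")) panels <- list(panels)
  if (length(panels) < 2) nf_data_error("need >= 2 panels to fit a normalizer")
  M <- t(vapply(panels, function(p) unname(p$concentrations), numeric(27)))
  L <- log(M + eps)
  structure(list(location = colMeans(L),
                 scale = pmax(apply(L, 2, stats::sd), scale_floor),
                 eps = eps, scale_floor = scale_floor),
            class = "breath_normalizer")
}

#' @rdname fit_breath_normalizer
#' @param normalizer a fitted `breath_normalizer`.
#' @param panel a [voc_panel()] or numeric length-27 concentration vector.
#' @return `apply_breath_normalizer()`: numeric length-27 z-score vector.
#' @export
apply_breath_normalizer <- function(normalizer, panel) {
  stopifnot(inherits(normalizer, "breath_normalizer"))
  x <- if (inherits(panel, "voc_panel")) unname(panel$concentrations)
       else as.numeric(panel)
  if (length(x) != 27) nf_schema_error("panel must have 27 channels, got %d",
                                       length(x))
  setNames((log(x + normalizer$eps) - normalizer$location) / normalizer$scale,
           sprintf("voc_z_%02d", 1:27))
}
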