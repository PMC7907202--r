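#' Fusion pipeline configuration
#'
#' Bundles every tunable of the four-marker pipeline: the mesh/mapping and
#' harmonic settings of the shape branch, the clique radii of the
#' appearance branch, the branch autoencoder stacks (three hidden layers
#' each, tapering to the bottlenecks 70 to 10, 1000 to 100, 27 to 10), the
#' size k-NN, and the second-stage fusion classifier over the 7-dimensional
#' concatenation of the three branch probability pairs and the k-NN
#' probability.
#'
#' @param shape_layers,appearance_layers,breath_layers hidden widths per
#'   branch.
#' @param fusion_layers hidden widths of the fusion stage
#'   (`fusion_mode = "ae_softmax"`); with `"softmax_only"` the fused
#'   decision is a plain softmax over the 7 inputs.
#' @param fusion_mode `"ae_softmax"` (default) or `"softmax_only"`.
#' @param epochs_pretrain,epochs_finetune epoch budgets for the small
#'   networks (shape, breath, fusion).
#' @param appearance_epochs_pretrain,appearance_epochs_finetune epoch
#'   budgets for the appearance stack, whose layers are two orders of
#'   magnitude larger and dominate the training cost.
#' @param learning_rate,momentum optimizer settings shared by all branches.
#' @param knn_k size k-NN neighborhood (odd avoids 50/50 ties).
#' @param radii MGRF clique radii (voxels).
#' @param roi_pad ROI padding in voxels (must cover `max(radii)`).
#' @param smooth_sigma_mm,step_mm mesh extraction settings, see
#'   [extract_mesh()].
#' @param ar an [ar_config()].
#' @param sh_max_order,sh_n_max_fit shape-feature settings, see
#'   [shape_feature_vector()].
#' @param seed base seed for all stochastic training stages.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(shape_layers = c(40L, 20L, 10L),
                          appearance_layers = c(500L, 250L, 100L),
                          breath_layers = c(20L, 15L, 10L),
                          fusion_layers = c(4L, 2L),
                          fusion_mode = c("ae_softmax", "softmax_only"),
                          epochs_pretrain = 60L, epochs_finetune = 200L,
                          appearance_epochs_pretrain = 20L,
                          appearance_epochs_finetune = 60L,
                          learning_rate = 0.5, momentum = 0.9,
                          knn_k = 5L, radii = 1:5, roi_pad = 6L,
                          smooth_sigma_mm = 1.2, step_mm = 1.75,
                          ar = ar_config(), sh_max_order = 70L,
                          sh_n_max_fit = 900L, seed = 1L) {
  fusion_mode <- match.arg(fusion_mode)
  if (roi_pad < max(radii))
    nf_value_error("roi_pad must cover the largest clique radius")
  structure(list(shape_layers = shape_layers,
                 appearance_layers = appearance_layers,
                 breath_layers = breath_layers,
                 fusion_layers = fusion_layers, fusion_mode = fusion_mode,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 appearance_epochs_pretrain =
                   as.integer(appearance_epochs_pretrain),
                 appearance_epochs_finetune =
                   as.integer(appearance_epochs_finetune),
                 learning_rate = learning_rate, momentum = momentum,
                 knn_k = as.integer(knn_k), radii = as.integer(radii),
                 roi_pad = as.integer(roi_pad),
                 smooth_sigma_mm = smooth_sigma_mm, step_mm = step_mm,
                 ar = ar, sh_max_order = as.integer(sh_max_order),
                 sh_n_max_fit = as.integer(sh_n_max_fit),
                 seed = as.integer(seed)),
            class = "fusion_config")
}

.rows_as_panels <- function(voc) {
  lapply(seq_len(nrow(voc)), function(i) voc_panel(paste0("row", i), voc[i, ]))
}

.branch_ae_config <- function(config, layers, seed_offset,
                              appearance = FALSE) {
  ae_config(layers,
            epochs_pretrain = if (appearance)
              config$appearance_epochs_pretrain else config$epochs_pretrain,
            epochs_finetune = if (appearance)
              config$appearance_epochs_finetune else config$epochs_finetune,
            learning_rate = config$learning_rate,
            momentum = config$momentum,
            seed = config$seed + seed_offset)
}

#' Raw and reduced feature-space dimensions
#'
#' The default configuration considers 1098 raw features (1000 appearance
#' histogram bins + 70 shape reconstruction errors + 1 size + 27 VOCs),
#' reduced by the branch bottlenecks to 121 (100 + 10 + 1 + 10).
#'
#' @param config a [fusion_config()].
#' @return List with `raw_dim`, `reduced_dim`, `per_group_raw`,
#'   `per_group_reduced`.
#' @export
describe_feature_space <- function(config = fusion_config()) {
  raw <- c(shape = config$sh_max_order, appearance = 1000L, size = 1L,
           breath = 27L)
  red <- c(shape = as.integer(tail(config$shape_layers, 1)),
           appearance = as.integer(tail(config$appearance_layers, 1)),
           size = 1L,
           breath = as.integer(tail(config$breath_layers, 1)))
  list(raw_dim = sum(raw), reduced_dim = sum(red),
       per_group_raw = raw, per_group_reduced = red)
}

#' Train the two-stage fusion model
#'
#' Trains the three branch classifiers (shape, appearance, breath — the
#' breath normalizer is fitted on the training panels inside), computes the
#' size k-NN probability for every training subject with that subject
#' excluded from its own neighbor pool, and trains the second-stage fusion
#' classifier on the 7-dimensional vector of the three branch probability
#' pairs plus the k-NN probability. Deterministic given `config$seed`.
#'
#' @param shape matrix `n x 70` of shape features.
#' @param appearance matrix `n x 1000` of appearance features.
#' @param voc matrix `n x 27` of raw VOC concentrations.
#' @param size_d length-`n` equivalent diameters (mm).
#' @param labels length-`n` labels.
#' @param config a [fusion_config()].
#' @return A `fusion_model`.
#' @export
train_fusion <- function(shape, appearance, voc, size_d, labels,
                         config = fusion_config()) {
  n <- length(labels)
  groups <- list(shape = shape, appearance = appearance, voc = voc)
  for (g in names(groups)) {
    m <- groups[[g]]
    if (is.null(m) || !nrow(as.matrix(m)) == n || any(!is.finite(as.matrix(m))))
      nf_data_error("marker group '%s' missing or incomplete for a subject", g)
  }
  shape <- as.matrix(shape); appearance <- as.matrix(appearance)
  voc <- as.matrix(voc)
  if (length(size_d) != n || any(!is.finite(size_d)))
    nf_data_error("marker group 'size' missing or incomplete for a subject")

  normalizer <- fit_breath_normalizer(.rows_as_panels(voc))
  Z <- t(apply(voc, 1, function(x) apply_breath_normalizer(normalizer, x)))

  clf_shape <- train_branch(shape, labels,
                            .branch_ae_config(config, config$shape_layers, 1L))
  clf_app <- train_branch(appearance, labels,
                          .branch_ae_config(config, config$appearance_layers,
                                            2L, appearance = TRUE))
  clf_breath <- train_branch(Z, labels,
                             .branch_ae_config(config, config$breath_layers, 3L))

  k <- min(config$knn_k, n - 1L)
  knn_p <- vapply(seq_len(n), function(i)
    knn_size_probability(size_d[i], size_d[-i], labels[-i], k = k),
    numeric(1))

  Fmat <- cbind(predict_branch(clf_shape, shape),
                predict_branch(clf_app, appearance),
                predict_branch(clf_breath, Z),
                knn = knn_p)
  fus_layers <- if (config$fusion_mode == "ae_softmax")
    config$fusion_layers else integer(0)
  clf_fusion <- train_branch(Fmat, labels,
                             .branch_ae_config(config, fus_layers, 4L))

  structure(list(shape = clf_shape, appearance = clf_app,
                 breath = clf_breath, fusion = clf_fusion,
                 normalizer = normalizer,
                 knn = list(training_d = size_d, training_labels = labels,
                            k = k),
                 threshold = 0.5, config = config),
            class = "fusion_model")
}

#' Predict malignancy with a trained fusion model
#'
#' @param model a [train_fusion()] result.
#' @param shape,appearance,voc,size_d features of the query subjects (one
#'   row / element each).
#' @return data.frame with the fused malignancy probability, the label at
#'   threshold 0.5, and the per-branch probabilities.
#' @export
predict_fusion <- function(model, shape, appearance, voc, size_d) {
  stopifnot(inherits(model, "fusion_model"))
  as_mat <- function(x, d) {
    if (is.null(dim(x))) x <- matrix(x, ncol = d)
    as.matrix(x)
  }
  shape <- as_mat(shape, model$shape$input_dim)
  appearance <- as_mat(appearance, model$appearance$input_dim)
  voc <- as_mat(voc, 27L)
  if (any(!is.finite(shape)) || any(!is.finite(appearance)) ||
      any(!is.finite(voc)) || any(!is.finite(size_d)))
    nf_schema_error("non-finite values in prediction features")
  Z <- t(apply(voc, 1, function(x)
    apply_breath_normalizer(model$normalizer, x)))
  p_shape <- predict_branch(model$shape, shape)
  p_app <- predict_branch(model$appearance, appearance)
  p_breath <- predict_branch(model$breath, Z)
  knn_p <- vapply(size_d, function(d)
    knn_size_probability(d, model$knn$training_d, model$knn$training_labels,
                         k = model$knn$k), numeric(1))
  Fmat <- cbind(p_shape, p_app, p_breath, knn = knn_p)
  p_fused <- predict_branch(model$fusion, Fmat)[, "malignant"]
  data.frame(prob_malignant = p_fused,
             label = ifelse(p_fused >= model$threshold, "malignant", "benign"),
             prob_shape = p_shape[, "malignant"],
             prob_appearance = p_app[, "malignant"],
             prob_breath = p_breath[, "malignant"],
             prob_knn = knn_p,
             stringsAsFactors = FALSE)
}

# ---- cohort-level feature extraction ---------------------------------------

#' Extract the per-nodule feature bundle of a cohort
#'
#' Computes, once per subject, everything the evaluation protocols need:
#' the shape error curve (mesh, spherical mapping, harmonics), the
#' equivalent diameter, the raw VOC concentrations, and the cached MGRF
#' clique-code tables from which fold-specific potentials, energy ranges
#' and appearance histograms are re-derived without rescanning the volumes.
#'
#' @param cohort a [make_cohort()]/[read_cohort()] cohort.
#' @param config a [fusion_config()].
#' @param progress print per-subject progress.
#' @return A `cohort_features` list.
#' @export
extract_cohort_features <- function(cohort, config = fusion_config(),
                                    progress = FALSE) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  n <- length(cohort$ids)
  shape <- matrix(NA_real_, n, config$sh_max_order)
  size_d <- numeric(n)
  tables <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- extract_roi(cohort$records[[i]], pad_voxels = config$roi_pad)
    mesh <- extract_mesh(rec$mask, smooth_sigma_mm = config$smooth_sigma_mm,
                         step_mm = config$step_mm)
    smap <- map_to_sphere(mesh, config$ar)
    shape[i, ] <- shape_feature_vector(smap, max_order = config$sh_max_order,
                                       n_max_fit = config$sh_n_max_fit)
    size_d[i] <- size_feature(rec)$equivalent_diameter_mm
    tables[[i]] <- clique_code_table(rec, config$radii)
    if (progress) message(sprintf("  features %d/%d (%s)", i, n,
                                  cohort$ids[i]))
  }
  voc <- t(vapply(cohort$panels, function(p) unname(p$concentrations),
                  numeric(27)))
  colnames(shape) <- sprintf("sh_err_%03d", seq_len(config$sh_max_order))
  colnames(voc) <- sprintf("voc_%02d", 1:27)
  structure(list(shape = shape, size_d = size_d, voc = voc,
                 mgrf_tables = tables, ids = cohort$ids,
                 labels = cohort$labels, config = config),
            class = "cohort_features")
}

# appearance histogram matrix for all subjects under an MGRF model learned
# from the subjects in train_idx only (leakage-safe fold re-learning)
.appearance_matrix <- function(feats, train_idx) {
  model <- .learn_from_tables(feats$mgrf_tables[train_idx],
                              feats$config$radii)
  A <- t(vapply(feats$mgrf_tables, function(tab)
    as.numeric(.energy_histogram(.energies_from_codes(tab$codes,
                                                      model$potentials),
                                 model$energy_range)),
    numeric(1000)))
  colnames(A) <- sprintf("mgrf_bin_%04d", 1:1000)
  list(model = model, matrix = A)
}

#' Full raw feature table (1098 columns) of a cohort
#'
#' Appearance histograms and the breath z-scores in this table are derived
#' from models learned on the *whole* cohort; the evaluation protocols
#' never use this table (they re-learn those models inside every fold) —
#' it is the persisted-feature interface of the pipeline.
#'
#' @param cohort a cohort.
#' @param config a [fusion_config()].
#' @param feats optionally, a precomputed [extract_cohort_features()].
#' @return data.frame: `id`, `label`, `size_d_mm`, `sh_err_001..070`,
#'   `mgrf_bin_0001..1000`, `voc_z_01..27`.
#' @export
features_table <- function(cohort, config = fusion_config(), feats = NULL) {
  if (is.null(feats)) feats <- extract_cohort_features(cohort, config)
  app <- .appearance_matrix(feats, seq_along(feats$ids))$matrix
  normalizer <- fit_breath_normalizer(.rows_as_panels(feats$voc))
  Z <- t(apply(feats$voc, 1, function(x)
    apply_breath_normalizer(normalizer, x)))
  colnames(Z) <- sprintf("voc_z_%02d", 1:27)
  data.frame(id = feats$ids, label = feats$labels,
             size_d_mm = feats$size_d, feats$shape, app, Z,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# ---- evaluation -------------------------------------------------------------

.metrics_from_predictions <- function(labels, prob, threshold = 0.5) {
  pred <- ifelse(prob >= threshold, "malignant", "benign")
  TP <- sum(pred == "malignant" & labels == "malignant")
  FP <- sum(pred == "malignant" & labels == "benign")
  TN <- sum(pred == "benign" & labels == "benign")
  FN <- sum(pred == "benign" & labels == "malignant")
  auc <- if (length(unique(labels)) == 2)
    as.numeric(pROC::auc(pROC::roc(response = labels, predictor = prob,
                                   levels = c("benign", "malignant"),
                                   direction = "<", quiet = TRUE)))
  else NA_real_
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = 100 * (TP + TN) / length(labels),
       sensitivity = 100 * TP / (TP + FN),
       specificity = 100 * TN / (TN + FP),
       auc = auc)
}

#' Evaluate the pipeline on a cohort
#'
#' `mode = "loso"`: one train/predict round per subject; within every fold
#' the MGRF potentials and energy range, the breath normalizer, all branch
#' classifiers, the k-NN neighbor pool and the fusion stage are learned
#' from the remaining subjects only, so nothing about the held-out subject
#' (its features or label) influences its own prediction.
#' `mode = "split"`: one stratified `split_fraction` / `1 - split_fraction`
#' train/test split (seeded), same leakage rules.
#'
#' @param cohort a cohort.
#' @param mode `"loso"` or `"split"`.
#' @param split_fraction training fraction for `mode = "split"`.
#' @param config a [fusion_config()].
#' @param seed seed for the split draw (training seeds come from
#'   `config$seed`).
#' @param feats optional precomputed [extract_cohort_features()].
#' @param progress print per-fold progress.
#' @return An `eval_report`: confusion counts, accuracy / sensitivity /
#'   specificity in percent, AUC, per-subject predictions, per-branch
#'   metrics, and the feature-space dimensions.
#' @export
evaluate_cohort <- function(cohort, mode = c("loso", "split"),
                            split_fraction = 0.75, config = fusion_config(),
                            seed = 1L, feats = NULL, progress = FALSE) {
  mode <- match.arg(mode)
  labels <- cohort$labels
  n <- length(labels)
  if (n < 4 || length(unique(labels)) < 2)
    nf_data_error("evaluation needs >= 4 subjects with both classes present")
  if (is.null(feats)) feats <- extract_cohort_features(cohort, config,
                                                       progress = progress)
  predict_fold <- function(train_idx, test_idx) {
    app <- .appearance_matrix(feats, train_idx)$matrix
    model <- train_fusion(feats$shape[train_idx, , drop = FALSE],
                          app[train_idx, , drop = FALSE],
                          feats$voc[train_idx, , drop = FALSE],
                          feats$size_d[train_idx], labels[train_idx], config)
    predict_fusion(model, feats$shape[test_idx, , drop = FALSE],
                   app[test_idx, , drop = FALSE],
                   feats$voc[test_idx, , drop = FALSE],
                   feats$size_d[test_idx])
  }

  if (mode == "loso") {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rows[[i]] <- predict_fold(setdiff(seq_len(n), i), i)
      if (progress) message(sprintf("  fold %d/%d", i, n))
    }
    pred <- do.call(rbind, rows)
    eval_idx <- seq_len(n)
  } else {
    if (min(table(labels)) < 2)
      nf_data_error("split evaluation needs >= 2 subjects per class")
    train_idx <- withr::with_seed(as.integer(seed), {
      unlist(lapply(split(seq_len(n), labels), function(ix)
        sample(ix, max(1L, round(split_fraction * length(ix))))))
    })
    eval_idx <- setdiff(seq_len(n), train_idx)
    if (length(eval_idx) == 0 || length(unique(labels[eval_idx])) < 2)
      nf_data_error("degenerate split: test set lacks a class")
    pred <- predict_fold(sort(train_idx), eval_idx)
  }

  truth <- labels[eval_idx]
  fused <- .metrics_from_predictions(truth, pred$prob_malignant)
  branch <- lapply(c(shape = "prob_shape", appearance = "prob_appearance",
                     breath = "prob_breath", size_knn = "prob_knn"),
                   function(col) .metrics_from_predictions(truth, pred[[col]]))
  per_subject <- data.frame(id = feats$ids[eval_idx], label = truth, pred,
                            stringsAsFactors = FALSE)
  structure(list(mode = mode, n = length(eval_idx),
                 confusion = fused[c("TP", "FP", "TN", "FN")],
                 accuracy = fused$accuracy, sensitivity = fused$sensitivity,
                 specificity = fused$specificity, auc = fused$auc,
                 branch_metrics = branch, per_subject = per_subject,
                 feature_dims = describe_feature_space(config),
                 seed = as.integer(seed), config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s over %d subjects\n", x$mode, x$n))
  cat(sprintf("  fused: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  cat(sprintf("  confusion: TP %d FP %d TN %d FN %d\n", x$confusion$TP,
              x$confusion$FP, x$confusion$TN, x$confusion$FN))
  for (b in names(x$branch_metrics))
    cat(sprintf("  %-10s accuracy %.2f%%\n", b, x$branch_metrics[[b]]$accuracy))
  cat(sprintf("  features: %d raw -> %d reduced\n", x$feature_dims$raw_dim,
              x$feature_dims$reduced_dim))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Deterministic content (no timestamps), so identical runs produce
#' byte-identical files.
#'
#' @param report an `eval_report`.
#' @param path destination.
#' @export
write_eval_report <- function(report, path) {
  out <- report[c("mode", "n", "confusion", "accuracy", "sensitivity",
                  "specificity", "auc", "seed")]
  out$branch_accuracy <- lapply(report$branch_metrics, `[[`, "accuracy")
  out$feature_dims <- report$feature_dims[c("raw_dim", "reduced_dim")]
  out$per_subject <- report$per_subject
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns")
  invisible(path)
}
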