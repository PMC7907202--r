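# ---- config file handling ---------------------------------------------------

.check_keys <- function(lst, allowed, where) {
  bad <- setdiff(names(lst), allowed)
  if (length(bad))
    nf_schema_error("unknown config key(s) in %s: %s", where,
                    paste(bad, collapse = ", "))
  lst
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a single JSON object with optional sections
#' `cohort` (`n`, `prevalence`, `nodule`, `voc` — arguments of
#' [make_cohort()] and the two simulator parameter constructors),
#' `fusion` (arguments of [fusion_config()]) and `evaluation` (`mode`,
#' `split_fraction`). Unknown keys are rejected rather than ignored.
#'
#' @param config path to a JSON file, a list, or `NULL` for all defaults.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = NULL) {
  cfg <- if (is.null(config)) list()
         else if (is.character(config)) jsonlite::read_json(config,
                                                            simplifyVector = TRUE)
         else config
  .check_keys(cfg, c("cohort", "fusion", "evaluation"), "top level")
  ch <- .check_keys(cfg$cohort %||% list(),
                    c("n", "prevalence", "nodule", "voc", "seed"), "cohort")
  .check_keys(ch$nodule %||% list(), names(formals(nodule_sim_params)),
              "cohort.nodule")
  .check_keys(ch$voc %||% list(), names(formals(voc_sim_params)),
              "cohort.voc")
  fu <- .check_keys(cfg$fusion %||% list(),
                    setdiff(names(formals(fusion_config)), "ar"), "fusion")
  ev <- .check_keys(cfg$evaluation %||% list(), c("mode", "split_fraction"),
                    "evaluation")
  structure(list(cohort = ch, fusion = fu, evaluation = ev),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 31-bit polynomial hash of the serialized config
.config_hash <- function(cfg) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(unclass(cfg),
                                                   auto_unbox = TRUE,
                                                   digits = 10)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.resolve_fusion_config <- function(pcfg, seed) {
  args <- pcfg$fusion
  args$seed <- seed
  do.call(fusion_config, args)
}

.resolve_cohort <- function(pcfg, seed) {
  ch <- pcfg$cohort
  np <- do.call(nodule_sim_params, as.list(ch$nodule %||% list()))
  vp <- do.call(voc_sim_params, as.list(ch$voc %||% list()))
  make_cohort(n = ch$n %||% 60L, prevalence = ch$prevalence %||% 0.5,
              nodule_params = np, voc_params = vp,
              seed = ch$seed %||% seed)
}

# ---- model container --------------------------------------------------------

.mat2j <- function(m) list(dim = dim(m), data = as.numeric(m))
.j2mat <- function(j) matrix(j$data, j$dim[1], j$dim[2])

.branch2j <- function(clf) {
  list(layers = lapply(clf$layers, function(l)
         list(W = .mat2j(l$W), b = as.numeric(l$b))),
       Wo = .mat2j(clf$Wo), bo = as.numeric(clf$bo),
       scale_lo = as.numeric(clf$scale_lo),
       scale_width = as.numeric(clf$scale_width),
       input_dim = clf$input_dim, bottleneck_dim = clf$bottleneck_dim)
}

.j2branch <- function(j) {
  structure(list(layers = lapply(j$layers, function(l)
                   list(W = .j2mat(l$W), b = l$b)),
                 Wo = .j2mat(j$Wo), bo = j$bo,
                 scale_lo = j$scale_lo, scale_width = j$scale_width,
                 input_dim = j$input_dim, bottleneck_dim = j$bottleneck_dim,
                 config = NULL),
            class = "branch_classifier")
}

#' Serialize / restore a trained fusion model
#'
#' JSON container (schema version 1) holding the MGRF model, the breath
#' normalizer, the size k-NN memory, and all network weights at full
#' precision.
#'
#' @param model a [train_fusion()] result.
#' @param mgrf_model the [learn_potentials()] model the appearance features
#'   were computed with.
#' @param path destination JSON.
#' @param meta optional named list merged into the container (seed, hash).
#' @export
write_fusion_model <- function(model, mgrf_model, path, meta = list()) {
  stopifnot(inherits(model, "fusion_model"), inherits(mgrf_model, "mgrf_model"))
  obj <- c(meta, list(
    schema_version = 1L,
    mgrf = list(radii = mgrf_model$radii,
                potentials = .mat2j(mgrf_model$potentials),
                energy_range = mgrf_model$energy_range),
    normalizer = unclass(model$normalizer),
    knn = model$knn,
    threshold = model$threshold,
    branches = list(shape = .branch2j(model$shape),
                    appearance = .branch2j(model$appearance),
                    breath = .branch2j(model$breath),
                    fusion = .branch2j(model$fusion))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fusion_model
#' @return `read_fusion_model()`: list with `model` (a `fusion_model`) and
#'   `mgrf` (an `mgrf_model`).
#' @export
read_fusion_model <- function(path) {
  if (!file.exists(path))
    nf_format_error("model container not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(j$schema_version) || j$schema_version != 1L)
    nf_format_error("unsupported model schema in %s", path)
  tomat <- function(x) .j2mat(list(dim = unlist(x$dim), data = unlist(x$data)))
  fix_branch <- function(b) {
    structure(list(layers = lapply(b$layers, function(l)
                     list(W = tomat(l$W), b = unlist(l$b))),
                   Wo = tomat(b$Wo), bo = unlist(b$bo),
                   scale_lo = unlist(b$scale_lo),
                   scale_width = unlist(b$scale_width),
                   input_dim = b$input_dim,
                   bottleneck_dim = b$bottleneck_dim, config = NULL),
              class = "branch_classifier")
  }
  mgrf <- structure(list(radii = unlist(j$mgrf$radii),
                         potentials = tomat(j$mgrf$potentials),
                         energy_range = unlist(j$mgrf$energy_range)),
                    class = "mgrf_model")
  normalizer <- structure(lapply(j$normalizer, unlist),
                          class = "breath_normalizer")
  model <- structure(list(shape = fix_branch(j$branches$shape),
                          appearance = fix_branch(j$branches$appearance),
                          breath = fix_branch(j$branches$breath),
                          fusion = fix_branch(j$branches$fusion),
                          normalizer = normalizer,
                          knn = list(training_d = unlist(j$knn$training_d),
                                     training_labels = unlist(j$knn$training_labels),
                                     k = j$knn$k),
                          threshold = j$threshold, config = NULL),
                     class = "fusion_model")
  list(model = model, mgrf = mgrf)
}

# ---- pipeline driver --------------------------------------------------------

#' Run one stage of the end-to-end pipeline
#'
#' Commands: `simulate` writes a synthetic cohort (NIfTI volumes/masks,
#' `voc.csv`, `manifest.csv`) under `out/cohort`; `extract-features` writes
#' `features.csv` (id, label, size, then the 1098 raw feature columns);
#' `train` fits the full fusion model on the cohort and writes
#' `model.json`; `evaluate` requires a trained `model.json` (the
#' configuration being evaluated must have been fitted first) and runs the
#' fold-wise evaluation protocol, writing `eval_report.json` and
#' `predictions.csv`; `predict` applies `model.json` to the cohort and
#' writes `predictions.csv`. Every JSON artifact embeds the seed and a
#' hash of the resolved configuration; outputs of a failing command are
#' removed.
#'
#' @param command one of `simulate`, `extract-features`, `train`,
#'   `evaluate`, `predict`.
#' @param config a [pipeline_config()] input (path, list or `NULL`).
#' @param out output/working directory.
#' @param seed integer seed.
#' @param dry_run print the execution plan without reading or writing.
#' @param progress verbose progress.
#' @return Invisibly, a list of artifact paths (or the plan if `dry_run`).
#' @export
run_pipeline <- function(command = c("simulate", "extract-features", "train",
                                     "evaluate", "predict"),
                         config = NULL, out = ".", seed = 1L,
                         dry_run = FALSE, progress = FALSE) {
  command <- match.arg(command)
  pcfg <- pipeline_config(config)
  seed <- as.integer(seed)
  hash <- .config_hash(pcfg)
  cohort_dir <- file.path(out, "cohort")
  paths <- list(cohort = cohort_dir,
                features = file.path(out, "features.csv"),
                model = file.path(out, "model.json"),
                report = file.path(out, "eval_report.json"),
                predictions = file.path(out, "predictions.csv"),
                run_meta = file.path(out, "run.json"))
  plan <- switch(command,
    "simulate" = sprintf("simulate cohort (n=%s) -> %s",
                         pcfg$cohort$n %||% 60L, cohort_dir),
    "extract-features" = sprintf("read %s -> %s", cohort_dir, paths$features),
    "train" = sprintf("read %s -> %s", cohort_dir, paths$model),
    "evaluate" = sprintf("read %s + %s -> %s", cohort_dir, paths$model,
                         paths$report),
    "predict" = sprintf("read %s + %s -> %s", cohort_dir, paths$model,
                        paths$predictions))
  if (dry_run) {
    message("dry-run [", command, "] ", plan)
    return(invisible(list(plan = plan)))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  need <- function(path, hint) {
    if (!file.exists(path))
      nf_format_error("missing prerequisite '%s' (%s)", path, hint)
  }
  created <- character(0)
  on_fail_cleanup <- function() {
    for (p in created) if (file.exists(p)) unlink(p, recursive = TRUE)
  }
  write_meta <- function(extra = list()) {
    jsonlite::write_json(c(list(command = command, seed = seed,
                                config_hash = hash), extra),
                         paths$run_meta, auto_unbox = TRUE)
  }

  result <- tryCatch({
    fcfg <- .resolve_fusion_config(pcfg, seed)
    if (command == "simulate") {
      created <- cohort_dir
      cohort <- .resolve_cohort(pcfg, seed)
      write_cohort(cohort, cohort_dir)
      write_meta(list(n = length(cohort$ids)))
      list(cohort = cohort_dir)
    } else if (command == "extract-features") {
      need(file.path(cohort_dir, "manifest.csv"), "run 'simulate' first")
      created <- paths$features
      cohort <- read_cohort(cohort_dir)
      tab <- features_table(cohort, fcfg)
      utils::write.csv(tab, paths$features, row.names = FALSE)
      write_meta(list(n = nrow(tab), feature_columns = ncol(tab) - 2L))
      list(features = paths$features)
    } else if (command == "train") {
      need(file.path(cohort_dir, "manifest.csv"), "run 'simulate' first")
      created <- paths$model
      cohort <- read_cohort(cohort_dir)
      feats <- extract_cohort_features(cohort, fcfg, progress = progress)
      app <- .appearance_matrix(feats, seq_along(feats$ids))
      model <- train_fusion(feats$shape, app$matrix, feats$voc,
                            feats$size_d, cohort$labels, fcfg)
      write_fusion_model(model, app$model, paths$model,
                         meta = list(seed = seed, config_hash = hash))
      write_meta()
      list(model = paths$model)
    } else if (command == "evaluate") {
      need(file.path(cohort_dir, "manifest.csv"), "run 'simulate' first")
      need(paths$model, "run 'train' first to produce model.json")
      created <- c(paths$report, paths$predictions)
      cohort <- read_cohort(cohort_dir)
      mode <- pcfg$evaluation$mode %||% "loso"
      report <- evaluate_cohort(cohort, mode = mode,
                                split_fraction =
                                  pcfg$evaluation$split_fraction %||% 0.75,
                                config = fcfg, seed = seed,
                                progress = progress)
      write_eval_report(report, paths$report)
      utils::write.csv(report$per_subject, paths$predictions,
                       row.names = FALSE)
      write_meta()
      list(report = paths$report, predictions = paths$predictions,
           eval_report = report)
    } else { # predict
      need(file.path(cohort_dir, "manifest.csv"), "run 'simulate' first")
      need(paths$model, "run 'train' first to produce model.json")
      created <- paths$predictions
      cohort <- read_cohort(cohort_dir)
      mm <- read_fusion_model(paths$model)
      feats <- extract_cohort_features(cohort, fcfg, progress = progress)
      app <- t(vapply(feats$mgrf_tables, function(tab)
        as.numeric(.energy_histogram(
          .energies_from_codes(tab$codes, mm$mgrf$potentials),
          mm$mgrf$energy_range)), numeric(1000)))
      pred <- predict_fusion(mm$model, feats$shape, app, feats$voc,
                             feats$size_d)
      pred <- cbind(id = feats$ids, pred)
      utils::write.csv(pred, paths$predictions, row.names = FALSE)
      write_meta()
      list(predictions = paths$predictions)
    }
  }, nf_error = function(e) { on_fail_cleanup(); stop(e) },
     error = function(e) { on_fail_cleanup(); stop(e) })
  invisible(result)
}
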