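#' Exhaled-breath VOC panel
#'
#' One patient's panel of 27 carbonyl volatile-organic-compound
#' concentrations. Channel identities are treated as opaque ordered columns;
#' only the order is contractual.
#'
#' @param patient_id character identifier.
#' @param concentrations numeric vector of exactly 27 finite, non-negative
#'   concentrations (nmol/L).
#' @param channels optional channel names (length 27).
#' @return An object of class `voc_panel`.
#' @export
voc_panel <- function(patient_id, concentrations, channels = NULL) {
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != 27L)
    nf_schema_error("VOC panel must have exactly 27 channels, got %d",
                    length(concentrations))
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    nf_value_error("VOC concentrations must be finite and non-negative")
  if (is.null(channels)) channels <- sprintf("voc_%02d", 1:27)
  structure(list(patient_id = as.character(patient_id),
                 concentrations = setNames(concentrations, channels)),
            class = "voc_panel")
}

#' Read a VOC concentration table
#'
#' Expects a UTF-8 CSV with a header row: a `patient_id` column followed by
#' exactly 27 named concentration channels. Column order defines channel
#' order.
#'
#' @param path CSV path.
#' @return A list of [voc_panel()] objects, one per row.
#' @export
load_voc_table <- function(path) {
  if (!file.exists(path)) nf_format_error("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    nf_schema_error("VOC table must have a 'patient_id' column")
  chan <- setdiff(names(df), "patient_id")
  if (length(chan) != 27L)
    nf_schema_error("VOC table must have 27 concentration channels, got %d",
                    length(chan))
  vals <- df[, chan, drop = FALSE]
  num <- vapply(vals, function(x) suppressWarnings(as.numeric(x)),
                numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df))
  if (any(is.na(num)))
    nf_value_error("non-numeric VOC concentration entries")
  if (any(num < 0))
    nf_value_error("negative VOC concentration entries")
  lapply(seq_len(nrow(df)), function(i)
    voc_panel(df$patient_id[i], num[i, ], channels = chan))
}

#' Write VOC panels to CSV
#'
#' @param panels list of [voc_panel()] objects.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_voc_table <- function(panels, path) {
  stopifnot(length(panels) > 0)
  mat <- t(vapply(panels, function(p) unname(p$concentrations), numeric(27)))
  df <- data.frame(patient_id = vapply(panels, `[[`, "", "patient_id"),
                   mat, check.names = FALSE)
  names(df) <- c("patient_id", names(panels[[1]]$concentrations))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cohort manifest
#'
#' Links nodule records to VOC panels and labels. `entries` must have unique
#' ids and labels in {benign, malignant}.
#'
#' @param entries data.frame with columns `id`, `voc_id`, `label` and
#'   optionally `volume_path`, `mask_path`.
#' @param provenance free-text provenance note.
#' @return An object of class `cohort_manifest`.
#' @export
cohort_manifest <- function(entries, provenance = "") {
  need <- c("id", "voc_id", "label")
  if (!all(need %in% names(entries)))
    nf_schema_error("manifest needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(entries$id))
    nf_schema_error("manifest ids must be unique")
  if (!all(entries$label %in% c("benign", "malignant")))
    nf_value_error("manifest labels must be 'benign' or 'malignant'")
  structure(list(entries = entries, provenance = provenance),
            class = "cohort_manifest")
}

#' @rdname cohort_manifest
#' @param path CSV path.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) nf_format_error("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  prov <- attr(df, "provenance")
  cohort_manifest(df, provenance = if (is.null(prov)) "" else prov)
}

#' @rdname cohort_manifest
#' @param manifest a `cohort_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest$entries, path, row.names = FALSE)
  invisible(path)
}
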