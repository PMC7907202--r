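# Classed conditions so callers (and tests) can distinguish failure modes.

nf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "nf_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

nf_alignment_error <- function(msg, ...) nf_stop("nf_alignment_error", msg, ...)
nf_empty_mask_error <- function(msg, ...) nf_stop("nf_empty_mask_error", msg, ...)
nf_format_error <- function(msg, ...) nf_stop("nf_format_error", msg, ...)
nf_schema_error <- function(msg, ...) nf_stop("nf_schema_error", msg, ...)
nf_value_error <- function(msg, ...) nf_stop("nf_value_error", msg, ...)
nf_mesh_error <- function(msg, ...) nf_stop("nf_mesh_error", msg, ...)
nf_rank_error <- function(msg, ...) nf_stop("nf_rank_error", msg, ...)
nf_bounds_error <- function(msg, ...) nf_stop("nf_bounds_error", msg, ...)
nf_data_error <- function(msg, ...) nf_stop("nf_data_error", msg, ...)
nf_training_error <- function(msg, ...) nf_stop("nf_training_error", msg, ...)
nf_sizing_error <- function(msg, ...) nf_stop("nf_sizing_error", msg, ...)
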