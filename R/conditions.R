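#' @keywords internal
#' @noRd
abort_sensmap <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "sensmap_error"), call = call))
}

alignment_error <- function(msg) abort_sensmap(msg, "sensmap_alignment_error")
format_error <- function(msg) abort_sensmap(msg, "sensmap_format_error")
validation_error <- function(msg) abort_sensmap(msg, "sensmap_validation_error")
degenerate_error <- function(msg) abort_sensmap(msg, "sensmap_degenerate_error")
applicability_error <- function(msg) abort_sensmap(msg, "sensmap_applicability_error")
optimization_error <- function(msg) abort_sensmap(msg, "sensmap_optimization_error")
insufficient_data_error <- function(msg) abort_sensmap(msg, "sensmap_insufficient_data_error")
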