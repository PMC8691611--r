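# Classed conditions so callers (and the CLI) can react to failure modes
# individually rather than parsing messages.

abort_actimetr <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "actimetr_error"),
                      call = call))
}

#' @noRd
format_error <- function(msg) abort_actimetr(msg, "actimetr_format_error")
sampling_error <- function(msg) abort_actimetr(msg, "actimetr_sampling_error")
range_error <- function(msg) abort_actimetr(msg, "actimetr_range_error")
shape_error <- function(msg) abort_actimetr(msg, "actimetr_shape_error")
size_error <- function(msg) abort_actimetr(msg, "actimetr_size_error")
parameter_error <- function(msg) abort_actimetr(msg, "actimetr_parameter_error")
applicability_error <- function(msg) abort_actimetr(msg, "actimetr_applicability_error")
alignment_error <- function(msg) abort_actimetr(msg, "actimetr_alignment_error")
coverage_error <- function(msg) abort_actimetr(msg, "actimetr_coverage_error")
io_error <- function(msg) abort_actimetr(msg, "actimetr_io_error")
correlation_error <- function(msg) abort_actimetr(msg, "actimetr_correlation_error")
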