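# Classed conditions so callers (and the CLI) can react to failure modes
# without string-matching messages.

ll_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "lengthlaw_error"), call = call))
}

stop_domain <- function(msg) ll_stop(msg, "lengthlaw_domain_error")
stop_insufficient <- function(msg) ll_stop(msg, "lengthlaw_insufficient_data_error")
stop_degenerate <- function(msg) ll_stop(msg, "lengthlaw_degenerate_design_error")
stop_unusable <- function(msg) ll_stop(msg, "lengthlaw_unusable_input_error")
stop_malformed <- function(msg) ll_stop(msg, "lengthlaw_malformed_input_error")
stop_unit_mismatch <- function(msg) ll_stop(msg, "lengthlaw_unit_mismatch_error")

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number", name))
  }
}
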