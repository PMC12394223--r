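# Classed conditions so callers (and the CLI) can tell user/validation
# errors (exit 2) from internal failures (exit 1).

ke_abort <- function(message, class) {
  stop(structure(
    class = c(class, "ke_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

ke_parameter_error  <- function(msg) ke_abort(msg, "ke_parameter_error")
ke_input_error      <- function(msg) ke_abort(msg, "ke_input_error")
ke_degenerate_error <- function(msg) ke_abort(msg, "ke_degenerate_error")
ke_protocol_error   <- function(msg) ke_abort(msg, "ke_protocol_error")
ke_config_error     <- function(msg) ke_abort(msg, "ke_config_error")
ke_data_error       <- function(msg) ke_abort(msg, "ke_data_error")
ke_alignment_error  <- function(msg) ke_abort(msg, "ke_alignment_error")
ke_parse_error      <- function(msg) ke_abort(msg, "ke_parse_error")
ke_generation_error <- function(msg) ke_abort(msg, "ke_generation_error")
ke_usage_error      <- function(msg) ke_abort(msg, "ke_usage_error")
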