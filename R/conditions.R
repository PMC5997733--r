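# Typed conditions so callers (and the command-line wrapper) can map failures
# to exit codes: config -> 2, data -> 3, inference -> 4.

stop_config <- function(msg, field = NULL, call. = FALSE) {
  if (!is.null(field)) msg <- sprintf("%s [field: %s]", msg, field)
  stop(errorCondition(msg, field = field,
                      class = c("cs_config_error", "cs_error", "error", "condition")))
}

stop_data <- function(msg, class = character(), ...) {
  stop(errorCondition(msg, ...,
                      class = c(class, "cs_data_error", "cs_error", "error", "condition")))
}

stop_inference <- function(msg, ...) {
  stop(errorCondition(msg, ...,
                      class = c("cs_inference_error", "cs_error", "error", "condition")))
}

# structure errors: containment/laminarity violations in clone-set systems
stop_structure <- function(msg, ...) {
  stop(errorCondition(msg, ...,
                      class = c("cs_structure_error", "cs_data_error", "cs_error",
                                "error", "condition")))
}

exit_code_for <- function(cond) {
  if (inherits(cond, "cs_config_error")) return(2L)
  if (inherits(cond, "cs_inference_error")) return(4L)
  if (inherits(cond, "cs_data_error")) return(3L)
  3L
}
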