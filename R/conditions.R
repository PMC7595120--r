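# Classed conditions so callers can distinguish failure modes programmatically.
# Every error raised by the package carries class "ctdsnet_error" plus a
# specific subclass such as "ctdsnet_error_non_finite_data".

stop_ctds <- function(subclass, message, ...) {
  rlang::abort(
    message,
    class = c(paste0("ctdsnet_error_", subclass), "ctdsnet_error"),
    ...
  )
}

warn_ctds <- function(subclass, message, ...) {
  rlang::warn(
    message,
    class = c(paste0("ctdsnet_warning_", subclass), "ctdsnet_warning"),
    ...
  )
}
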