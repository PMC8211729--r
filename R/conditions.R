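#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can branch on failure mode with
# tryCatch(..., braintraits_validation = ...). All inherit from "braintraits_error".
bt_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg,
    class = c(paste0("braintraits_", class), "braintraits_error", "error", "condition"),
    call = call
  ))
}

bt_warn <- function(msg, class) {
  warning(warningCondition(msg,
    class = c(paste0("braintraits_", class), "braintraits_warning", "warning", "condition")
  ))
}

#' @noRd
stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < 0)
    bt_stop(sprintf("'%s' must be a single non-negative integer", name), "validation")
  as.integer(x)
}
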