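#' @keywords internal
#' Signal a classed error so callers can dispatch on the failure mode.
hawkfs_abort <- function(message, class) {
  stop(structure(
    class = c(class, "hawkfs_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
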