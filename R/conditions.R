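# Classed conditions so callers (and the renderer's per-panel error handling)
# can distinguish an absent input from a malformed one.

stop_mriscreen <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mriscreen_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_absent_input <- function(msg, ...) stop_mriscreen("mriscreen_absent_input", msg, ...)
stop_format       <- function(msg, ...) stop_mriscreen("mriscreen_format_error", msg, ...)
stop_orientation  <- function(msg, ...) stop_mriscreen("mriscreen_orientation_error", msg, ...)
stop_geometry     <- function(msg, ...) stop_mriscreen("mriscreen_geometry_error", msg, ...)
stop_schema       <- function(msg, ...) stop_mriscreen("mriscreen_schema_error", msg, ...)
stop_parameter    <- function(msg, ...) stop_mriscreen("mriscreen_parameter_error", msg, ...)
stop_empty_log    <- function(msg, ...) stop_mriscreen("mriscreen_empty_log", msg, ...)

# Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
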