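# Internal helpers shared across modules.

# Set the RNG locally for the calling frame when a seed is supplied.
# All stochastic entry points route through this, so a given seed fully
# determines their output and the caller's RNG state is left untouched.
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort("`seed` must be a single integer.", class = "flywasp_validation_error")
    }
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

abort_validation <- function(msg) {
  abort(msg, class = "flywasp_validation_error")
}

abort_degenerate <- function(msg) {
  abort(msg, class = "flywasp_degenerate_error")
}

abort_config <- function(msg) {
  abort(msg, class = "flywasp_config_error")
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

# Collapse a character vector into "a, b, c" for messages.
comma <- function(x) paste(x, collapse = ", ")
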