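# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed error, so callers can catch specific failure modes.
mcp_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "mcpaste_error", "error"), ...))
}

mcp_warn <- function(msg, class = "mcpaste_warning") {
  warning(warningCondition(msg, class = c(class, "mcpaste_warning", "warning")))
}

# sample() treats a length-1 numeric x as 1:x; this does not.
resample <- function(x, size, replace = FALSE) {
  if (length(x) == 1L) {
    if (size == 1L) return(x)
    if (!replace) mcp_stop("cannot sample more than one item from a singleton",
                           "sampling_error")
  }
  x[sample.int(length(x), size, replace = replace)]
}

# Deterministic 31-bit seed derived from a base seed and a string key.
# Keeps per-image RNG streams independent of dataset iteration order.
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(as.character(key))) h <- (h * 31 + code) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h + 1) %% m)
}

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

assert_rgb_image <- function(x, what = "image") {
  if (!is_rgb_image(x) || dim(x)[1] < 1L || dim(x)[2] < 1L)
    mcp_stop(sprintf("%s must be a nonempty height x width x 3 numeric array", what),
             "empty_input_error")
  invisible(x)
}

# Cheap stable checksum of a configuration list (hex string); used for run
# manifests so artifacts can be tied to the exact configuration.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  m <- 2147483647
  h <- 7
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% m
  sprintf("%08x", as.integer(h))
}
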