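# Internal helpers shared across modules.

# Signal a classed condition so callers/tests can distinguish user error
# kinds. All inherit from "psofusion_error".
psf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "psofusion_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

err_invalid_input  <- function(msg, ...) psf_stop("psofusion_invalid_input", msg, ...)
err_invalid_config <- function(msg, ...) psf_stop("psofusion_invalid_config", msg, ...)
err_format         <- function(msg, ...) psf_stop("psofusion_format_error", msg, ...)
err_dependency     <- function(msg, ...) psf_stop("psofusion_dependency_error", msg, ...)
err_numerical      <- function(msg, ...) psf_stop("psofusion_numerical_failure", msg, ...)

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream. Every seeded entry point in the package routes through this, so
# nested seeded calls (e.g. re-training inside a swarm iteration) do not
# perturb the enclosing random draws.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and small stream offsets, kept well
# inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + o) %% 2147483647
  as.integer(s)
}

is_binary_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m == 0 | m == 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
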