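# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

tf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tabfuse_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

tf_schema_error <- function(msg, ...) tf_stop("tabfuse_schema_error", msg, ...)
tf_parse_error <- function(msg, ...) tf_stop("tabfuse_parse_error", msg, ...)
tf_io_error <- function(msg, ...) tf_stop("tabfuse_io_error", msg, ...)
tf_capability_error <- function(msg, ...) tf_stop("tabfuse_capability_error", msg, ...)

# Deterministic derivation of stage seeds from one global seed; keeps every
# derived value a valid 32-bit integer.
derive_seed <- function(global_seed, stage) {
  offsets <- c(
    generate_fit = 11L, generate_sample = 12L, quality = 13L,
    split = 21L, train = 31L, backbone = 32L, explain = 41L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(global_seed) * 97 + off) %% .Machine$integer.max)
}
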