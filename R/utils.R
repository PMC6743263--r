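#' @importFrom rlang %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows filter mutate select group_by summarise ungroup left_join n
#' @keywords internal
"_PACKAGE"

# Condition constructor: all package errors carry class "ctimr_error" plus a
# specific subclass so callers (and the CLI) can map them to exit codes.
ctimr_abort <- function(message, class = "ctimr_generic_error", ...) {
  cond <- structure(
    class = c(class, "ctimr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# UTC ISO-8601 timestamp with seconds precision; `clock` interfaces allow
# deterministic tests.
utc_now <- function() {
  format(as.POSIXct(Sys.time(), tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
}

sha256_hex <- function(x) digest::digest(x, algo = "sha256", serialize = FALSE)
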