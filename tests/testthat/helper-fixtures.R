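# Shared test helpers: small fixture specs, deterministic clocks, and
# attribute comparison utilities.

# A small-matrix spec keeps unit tests fast; acceptance checks use the
# generator defaults.
small_spec <- function(..., matrix = c(32L, 32L), seed = 1L) {
  args <- list(...)
  args$matrix <- args$matrix %||% matrix
  args$seed <- args$seed %||% seed
  if (is.null(args$burned_in)) {
    args$burned_in <- list(list(rows = c(1L, 5L), cols = c(1L, 12L), slices = NULL))
  }
  do.call(fixture_spec, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic, strictly increasing clock for audit/QC timestamps.
make_clock <- function() {
  i <- 0L
  function() {
    i <<- i + 1L
    sprintf("2026-01-01T%02d:%02d:%02dZ", i %/% 3600L, (i %/% 60L) %% 60L, i %% 60L)
  }
}

# Strip class/ordering noise: tag -> (vr, value) map for value comparison.
attr_values <- function(ds) {
  lapply(ds$attributes, function(a) list(vr = a$vr, value = a$value))
}

study_attr_values <- function(study) {
  lapply(study_datasets(study), attr_values)
}

# All character-rendered values of a study (attributes + file meta).
all_values <- function(study) {
  unlist(lapply(study_datasets(study), function(ds) {
    vapply(c(ds$attributes, ds$meta), function(a) ctimr:::render_value(a$value), "")
  }), use.names = FALSE)
}

reviewer_a <- function() account("revA", "central_reviewer")
reviewer_b <- function() account("revB", "central_reviewer")
qc_account <- function() account("qc1", "qc_staff")
pm_account <- function() account("pm1", "project_manager")
admin_account <- function() account("root", "admin")
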