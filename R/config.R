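# Plain-text (YAML) configuration for deidentification profiles, QC
# protocol specs and fixture specs. Round-trips are lossless.

#' Write / read a deidentification profile as YAML
#'
#' @param profile A [deid_profile()].
#' @param path YAML file path.
#' @name profile-io
#' @export
write_profile <- function(profile, path) {
  yaml::write_yaml(list(
    org_root = profile$org_root,
    default_private_action = profile$default_private_action,
    date_blank = profile$date_blank,
    scan_keywords = as.list(profile$scan_keywords),
    number_patterns = as.list(profile$number_patterns),
    rules = lapply(profile$rules, function(r) {
      x <- list(tag = r$tag, action = r$action)
      if (!is.null(r$n_source)) x$n_source <- r$n_source
      x
    })
  ), path)
  invisible(path)
}

#' @rdname profile-io
#' @export
read_profile <- function(path) {
  x <- tryCatch(yaml::read_yaml(path), error = function(e) {
    ctimr_abort(sprintf("cannot parse profile %s: %s", path, conditionMessage(e)),
                "ctimr_config_error")
  })
  deid_profile(
    rules = lapply(x$rules, function(r) deid_rule(r$tag, r$action, r$n_source)),
    scan_keywords = unlist(x$scan_keywords),
    number_patterns = unlist(x$number_patterns),
    default_private_action = x$default_private_action %||% "E",
    org_root = x$org_root %||% "1.2.410.200001",
    date_blank = isTRUE(x$date_blank)
  )
}

#' Write / read a QC protocol spec as YAML
#'
#' @param spec A [protocol_spec()].
#' @param path YAML file path.
#' @name protocol-io
#' @export
write_protocol <- function(spec, path) {
  yaml::write_yaml(list(
    modality = spec$modality,
    required_orientations = spec$required_orientations,
    rules = lapply(spec$rules, function(r) list(
      parameter = r$parameter, comparator = r$comparator,
      threshold = r$threshold, units = r$units, optional = r$optional,
      tolerance = r$tolerance))
  ), path)
  invisible(path)
}

#' @rdname protocol-io
#' @export
read_protocol <- function(path) {
  x <- tryCatch(yaml::read_yaml(path), error = function(e) {
    ctimr_abort(sprintf("cannot parse protocol %s: %s", path, conditionMessage(e)),
                "ctimr_config_error")
  })
  if (is.null(x$rules) || length(x$rules) == 0L) {
    ctimr_abort(sprintf("protocol %s defines no rules", path), "ctimr_config_error")
  }
  protocol_spec(
    modality = x$modality %||% "CT",
    rules = lapply(x$rules, function(r) {
      thr <- r$threshold
      if (is.list(thr)) thr <- unlist(thr)
      qc_rule(r$parameter, r$comparator, thr,
              units = r$units %||% NA_character_,
              optional = isTRUE(r$optional), tolerance = r$tolerance)
    }),
    required_orientations = x$required_orientations
  )
}

#' Write / read a fixture spec as YAML
#'
#' @param spec A [fixture_spec()].
#' @param path YAML file path.
#' @name fixture-io
#' @export
write_fixture_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname fixture-io
#' @export
read_fixture_spec <- function(path) {
  x <- tryCatch(yaml::read_yaml(path), error = function(e) {
    ctimr_abort(sprintf("cannot parse fixture spec %s: %s", path, conditionMessage(e)),
                "ctimr_config_error")
  })
  args <- x[intersect(names(x), names(formals(fixture_spec)))]
  if (!is.null(args$matrix)) args$matrix <- unlist(args$matrix)
  if (!is.null(args$pixel_spacing)) args$pixel_spacing <- unlist(args$pixel_spacing)
  if (!is.null(args$phi)) args$phi <- unlist(args$phi)
  do.call(fixture_spec, args)
}
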