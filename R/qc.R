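# Protocol-conformance image quality control.
#
# Automatic quantitative QC extracts acquisition parameters from the DICOM
# elements of a series (matrix, slice thickness, interslice gap, modality,
# manufacturer, sequence, pixel spacing, field of view) and checks them
# against declarative per-trial rules. Manual qualitative QC captures the
# four reviewer checks (artifacts, scan coverage, reconstruction, contrast
# enhancement). Both compile into a quality assessment report.

QC_COMPARATORS <- c("eq", "le", "ge", "in_set")
QC_QUALITATIVE_ITEMS <- c("artifact", "coverage", "reconstruction", "contrast")

#' Quantitative QC rule
#'
#' @param parameter Acquisition parameter name: one of `rows`, `columns`,
#'   `matrix`, `slice_thickness`, `interslice_gap`, `modality`,
#'   `manufacturer`, `sequence`, `pixel_spacing`, `field_of_view`,
#'   `n_slices`.
#' @param comparator `"eq"`, `"le"`, `"ge"`, or `"in_set"`.
#' @param threshold Numeric value/vector (eq/le/ge) or a set of allowed
#'   values (in_set).
#' @param units Unit label for reporting (e.g. `"mm"`).
#' @param optional If `TRUE`, a missing parameter does not fail the overall
#'   verdict.
#' @param tolerance Absolute tolerance for numeric `eq`; defaults to 1e-3 mm
#'   for the interslice gap and 1e-6 otherwise.
#' @return A `qc_rule`.
#' @export
qc_rule <- function(parameter, comparator, threshold, units = NA_character_,
                    optional = FALSE, tolerance = NULL) {
  if (!(comparator %in% QC_COMPARATORS)) {
    ctimr_abort(sprintf("unknown comparator: '%s'", comparator), "ctimr_config_error")
  }
  if (comparator %in% c("le", "ge") && !is.numeric(threshold)) {
    ctimr_abort("le/ge comparators need a numeric threshold", "ctimr_config_error")
  }
  tolerance <- tolerance %||% if (identical(parameter, "interslice_gap")) 1e-3 else 1e-6
  structure(list(parameter = parameter, comparator = comparator,
                 threshold = threshold, units = units,
                 optional = isTRUE(optional), tolerance = tolerance),
            class = "qc_rule")
}

#' Per-trial imaging protocol specification
#'
#' @param modality Expected modality code.
#' @param rules List of [qc_rule()]; at least one.
#' @param required_orientations Optional character vector (informational).
#' @return A `protocol_spec`.
#' @export
protocol_spec <- function(modality = "CT", rules, required_orientations = NULL) {
  if (missing(rules) || length(rules) == 0L) {
    ctimr_abort("a protocol needs at least one rule", "ctimr_config_error")
  }
  structure(list(modality = modality, rules = rules,
                 required_orientations = required_orientations),
            class = "protocol_spec")
}

#' Example CT protocol
#'
#' The worked trial requirement this package's QC module demonstrates:
#' axial CT at 512 x 512 with slice thickness <= 5 mm and 0 mm interslice
#' gap.
#'
#' @return A `protocol_spec`.
#' @export
default_ct_protocol <- function() {
  protocol_spec("CT", list(
    qc_rule("rows", "eq", 512),
    qc_rule("columns", "eq", 512),
    qc_rule("slice_thickness", "le", 5, units = "mm"),
    qc_rule("interslice_gap", "eq", 0, units = "mm"),
    qc_rule("modality", "in_set", "CT")
  ))
}

#' Extract acquisition parameters from a series
#'
#' The interslice gap is the mean spacing between consecutive slice centers
#' (projection of Image Position (Patient) on the slice normal) minus the
#' slice thickness; when positions are absent it falls back to Spacing
#' Between Slices (0018,0088) minus thickness. Absent elements are recorded
#' as missing (`NA`), never silently defaulted.
#'
#' @param series A `dcm_series` with at least one slice.
#' @return An `acq_params` list: `rows`, `columns`, `matrix`,
#'   `slice_thickness`, `interslice_gap`, `modality`, `manufacturer`,
#'   `sequence`, `pixel_spacing`, `field_of_view`, `n_slices`.
#' @export
derive_acquisition_params <- function(series) {
  ds_list <- series$datasets
  if (length(ds_list) == 0L) {
    ctimr_abort("series has no datasets", "ctimr_integrity_error")
  }
  rows <- unique(vapply(ds_list, function(d) as.numeric(ds_num(d, TAG_ROWS) %||% NA_real_)[1], 0))
  cols <- unique(vapply(ds_list, function(d) as.numeric(ds_num(d, TAG_COLS) %||% NA_real_)[1], 0))
  if (length(rows) > 1L || length(cols) > 1L) {
    ctimr_abort("inconsistent Rows/Columns within series", "ctimr_integrity_error")
  }
  first <- ds_list[[1]]
  thickness <- (ds_num(first, "(0018,0050)") %||% NA_real_)[1]
  gap <- NA_real_
  if (length(ds_list) >= 2L) {
    pos <- vapply(ds_list, slice_position, 0)
    if (!anyNA(pos)) {
      gap <- mean(diff(sort(pos))) - thickness
    }
  }
  if (is.na(gap)) {
    sbs <- (ds_num(first, "(0018,0088)") %||% NA_real_)[1]
    if (!is.na(sbs) && !is.na(thickness)) gap <- sbs - thickness
  }
  spacing <- ds_num(first, "(0028,0030)")
  fov <- if (!is.null(spacing) && length(spacing) == 2L && !anyNA(spacing) && !is.na(cols)) {
    cols * spacing[2]
  } else NA_real_
  structure(list(
    rows = rows, columns = cols,
    matrix = if (!is.na(rows) && !is.na(cols)) c(rows, cols) else NA,
    slice_thickness = thickness, interslice_gap = gap,
    modality = ds_value(first, "(0008,0060)"),
    manufacturer = ds_value(first, "(0008,0070)"),
    sequence = {
      s <- ds_value(first, "(0018,1030)")
      if (is.na(s)) ds_value(first, "(0008,103E)") else s
    },
    pixel_spacing = if (is.null(spacing)) NA else spacing,
    field_of_view = fov,
    n_slices = length(ds_list)
  ), class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm, paste(format(x[[nm]]), collapse = " x ")))
  }
  invisible(x)
}

check_rule <- function(rule, observed) {
  missing <- is.null(observed) || all(is.na(observed))
  if (missing) {
    return(list(verdict = "missing",
                message = sprintf("%s absent from series", rule$parameter)))
  }
  thr <- rule$threshold
  ok <- switch(rule$comparator,
    eq = if (is.numeric(thr) && is.numeric(observed)) {
      length(observed) == length(thr) && all(abs(observed - thr) <= rule$tolerance)
    } else identical(as.character(observed), as.character(thr)),
    le = all(as.numeric(observed) <= as.numeric(thr) + rule$tolerance),
    ge = all(as.numeric(observed) >= as.numeric(thr) - rule$tolerance),
    in_set = all(as.character(observed) %in% as.character(thr))
  )
  list(verdict = if (ok) "pass" else "fail",
       message = if (ok) "" else
         sprintf("%s = %s violates %s %s", rule$parameter,
                 paste(format(observed), collapse = "x"), rule$comparator,
                 paste(format(thr), collapse = "x")))
}

#' Run automatic quantitative QC
#'
#' Produces one finding per protocol rule. A rule whose parameter is absent
#' from the series yields verdict `"missing"` (treated as a failure for the
#' overall verdict unless the rule is marked optional).
#'
#' @param series A `dcm_series` or an `acq_params` object.
#' @param spec A [protocol_spec()].
#' @return A tibble of findings: `parameter`, `comparator`, `threshold`,
#'   `units`, `observed`, `verdict`, `optional`, `message`.
#' @export
run_auto_qc <- function(series, spec) {
  params <- if (inherits(series, "acq_params")) series
            else derive_acquisition_params(series)
  rows <- lapply(spec$rules, function(rule) {
    observed <- params[[rule$parameter]]
    res <- check_rule(rule, observed)
    tibble(parameter = rule$parameter, comparator = rule$comparator,
           threshold = paste(format(rule$threshold), collapse = "x"),
           units = rule$units,
           observed = if (is.null(observed) || all(is.na(observed))) NA_character_
                      else paste(format(observed), collapse = "x"),
           verdict = res$verdict, optional = rule$optional,
           message = res$message)
  })
  bind_rows(rows)
}

qualitative_template <- function() {
  tibble(item = character(), verdict = character(), comment = character(),
         assessor = character(), timestamp = character())
}

compute_overall <- function(findings, qualitative, missing_fails = TRUE) {
  quant_bad <- any(findings$verdict == "fail") ||
    (missing_fails && any(findings$verdict == "missing" & !findings$optional))
  qual_bad <- nrow(qualitative) > 0L && any(qualitative$verdict == "fail")
  if (quant_bad || qual_bad) "fail" else "pass"
}

#' Compile the quality assessment report
#'
#' Combines quantitative findings and qualitative items into the report the
#' QC workflow signs off on: overall pass/fail, the list of protocol
#' deviations, and (if configured) one open corrective-action query per
#' failing rule.
#'
#' @param findings Tibble from [run_auto_qc()].
#' @param qualitative Optional tibble of qualitative items (columns `item`,
#'   `verdict`, `comment`, `assessor`, `timestamp`).
#' @param missing_fails Treat missing required parameters as failures
#'   (default, conservative).
#' @param raise_queries Open one query per failing rule.
#' @param modality,series_uid Report header fields.
#' @param clock Timestamp source, a zero-argument function.
#' @return A `qc_report`.
#' @export
compile_report <- function(findings, qualitative = NULL, missing_fails = TRUE,
                           raise_queries = TRUE, modality = NA_character_,
                           series_uid = NA_character_, clock = utc_now) {
  qualitative <- qualitative %||% qualitative_template()
  deviations <- filter(findings, .data$verdict %in% c("fail", "missing"),
                       !.data$optional)
  queries <- list()
  if (raise_queries && nrow(deviations) > 0L) {
    queries <- lapply(seq_len(nrow(deviations)), function(i) {
      new_query(id = sprintf("QC-%s-%02d", substr(sha256_hex(series_uid %||% ""), 1, 6), i),
                category = "clinical", addressee = "site",
                text = sprintf("protocol deviation: %s",
                               deviations$message[i] %||% deviations$parameter[i]),
                opened_by = "qc-module", clock = clock)
    })
  }
  structure(list(modality = modality, series_uid = series_uid,
                 findings = findings, qualitative = qualitative,
                 overall = compute_overall(findings, qualitative, missing_fails),
                 missing_fails = missing_fails,
                 deviations = deviations, queries = queries,
                 generated = clock()),
            class = "qc_report")
}

#' Record a manual qualitative QC item
#'
#' Appends one of the four reviewer checks (`artifact`, `coverage`,
#' `reconstruction`, `contrast`) to a report in progress and recomputes the
#' overall verdict. The assessor must hold a QC-capable role.
#'
#' @param report A `qc_report`.
#' @param item One of the four qualitative items.
#' @param verdict `"pass"` or `"fail"`.
#' @param comment Free-text comment.
#' @param assessor An [account()] holding the `record_manual_qc` permission.
#' @param log Optional [audit_log()].
#' @param clock Timestamp source.
#' @return The updated `qc_report`.
#' @export
record_manual_qc <- function(report, item, verdict, comment = "",
                             assessor, log = NULL, clock = utc_now) {
  if (!(item %in% QC_QUALITATIVE_ITEMS)) {
    ctimr_abort(sprintf("unknown qualitative item: '%s'", item), "ctimr_config_error")
  }
  if (!(verdict %in% c("pass", "fail"))) {
    ctimr_abort("verdict must be 'pass' or 'fail'", "ctimr_config_error")
  }
  if (authorize(assessor, "record_manual_qc") != "allow") {
    ctimr_abort(sprintf("account '%s' (%s) may not record manual QC",
                        assessor$id, assessor$role), "ctimr_access_error")
  }
  report$qualitative <- bind_rows(report$qualitative,
    tibble(item = item, verdict = verdict, comment = comment,
           assessor = assessor$id, timestamp = clock()))
  report$overall <- compute_overall(report$findings, report$qualitative,
                                    report$missing_fails)
  if (!is.null(log)) {
    append_event(log, editor = assessor$id,
                 entity = paste0("qc:", report$series_uid), action = "create",
                 new = sprintf("%s=%s", item, verdict),
                 reason = NA_character_)
  }
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.qc_report <- function(x, ...) {
  lines <- c(
    "Quality assessment report",
    sprintf("  modality: %s   series: %s   generated: %s",
            x$modality, x$series_uid, x$generated),
    sprintf("  OVERALL: %s", toupper(x$overall)),
    "  quantitative findings:")
  for (i in seq_len(nrow(x$findings))) {
    f <- x$findings[i, ]
    lines <- c(lines, sprintf("    [%s] %s %s %s (observed %s)",
                              f$verdict, f$parameter, f$comparator,
                              f$threshold, f$observed %||% "NA"))
  }
  if (nrow(x$qualitative) > 0L) {
    lines <- c(lines, "  qualitative items:")
    for (i in seq_len(nrow(x$qualitative))) {
      q <- x$qualitative[i, ]
      lines <- c(lines, sprintf("    [%s] %s — %s (%s)", q$verdict, q$item,
                                q$comment, q$assessor))
    }
  }
  if (nrow(x$deviations) > 0L) {
    lines <- c(lines, sprintf("  protocol deviations: %d", nrow(x$deviations)),
               paste0("    - ", x$deviations$message))
  }
  if (length(x$queries) > 0L) {
    lines <- c(lines, sprintf("  queries raised: %d", length(x$queries)),
               vapply(x$queries, function(q)
                 sprintf("    - %s [%s] %s", q$id, q$state, q$messages$text[1]), ""))
  }
  lines
}

#' Serialize / parse a QC report as JSON
#'
#' The JSON form round-trips: `parse_qc_report_json(qc_report_json(x))`
#' reproduces the report.
#'
#' @param report A `qc_report`.
#' @param json A JSON string produced by `qc_report_json()`.
#' @name qc-report-json
#' @export
qc_report_json <- function(report) {
  jsonlite::toJSON(list(
    modality = report$modality, series_uid = report$series_uid,
    findings = report$findings, qualitative = report$qualitative,
    overall = report$overall, missing_fails = report$missing_fails,
    deviations = report$deviations,
    queries = lapply(report$queries, query_to_list),
    generated = report$generated
  ), dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

#' @rdname qc-report-json
#' @export
parse_qc_report_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  fix_tbl <- function(rows, template) {
    if (is.null(rows) || length(rows) == 0L) return(template)
    out <- bind_rows(lapply(rows, function(r) {
      as_tibble(r[!vapply(r, is.null, TRUE)])
    }))
    for (nm in names(template)) {
      if (!nm %in% names(out)) out[[nm]] <- template[[nm]][NA_integer_]
    }
    out[names(template)]
  }
  findings_tpl <- tibble(parameter = character(), comparator = character(),
                         threshold = character(), units = character(),
                         observed = character(), verdict = character(),
                         optional = logical(), message = character())
  structure(list(
    modality = x$modality %||% NA_character_,
    series_uid = x$series_uid %||% NA_character_,
    findings = fix_tbl(x$findings, findings_tpl),
    qualitative = fix_tbl(x$qualitative, qualitative_template()),
    overall = x$overall, missing_fails = isTRUE(x$missing_fails),
    deviations = fix_tbl(x$deviations, findings_tpl),
    queries = lapply(x$queries, function(q) {
      q$messages <- fix_tbl(q$messages,
                            tibble(timestamp = character(), actor = character(),
                                   event = character(), text = character()))
      query_from_list(q)
    }),
    generated = x$generated
  ), class = "qc_report")
}
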