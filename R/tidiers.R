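# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile labs
#' @export
ggplot2::autoplot

#' Tidy a QC report into its findings
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return The findings tibble.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$findings

#' One-row summary of a QC report
#' @param x A `qc_report`.
#' @param ... Unused.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble(overall = x$overall,
         n_findings = nrow(x$findings),
         n_fail = sum(x$findings$verdict == "fail"),
         n_missing = sum(x$findings$verdict == "missing"),
         n_qualitative = nrow(x$qualitative),
         n_deviations = nrow(x$deviations),
         n_queries = length(x$queries))
}

#' Tidy an audit log into its records
#' @param x An `audit_log`.
#' @param ... Unused.
#' @method tidy audit_log
#' @export
tidy.audit_log <- function(x, ...) audit_records(x)

#' One-row summary of an audit log
#' @param x An `audit_log`.
#' @param ... Unused.
#' @method glance audit_log
#' @export
glance.audit_log <- function(x, ...) {
  v <- verify_chain(x)
  tibble(n_records = nrow(audit_records(x)), valid = v$valid,
         first_broken = v$first_broken)
}

#' Tidy a deidentification result into its report
#' @param x A `deid_result`.
#' @param ... Unused.
#' @method tidy deid_result
#' @export
tidy.deid_result <- function(x, ...) x$report

#' One-row summary of a deidentification result
#' @param x A `deid_result`.
#' @param ... Unused.
#' @method glance deid_result
#' @export
glance.deid_result <- function(x, ...) {
  tibble(n_datasets = length(study_datasets(x$study)),
         n_applications = nrow(x$report),
         n_removed = sum(x$report$action == "E"),
         n_remapped_uids = sum(x$report$action == "C"))
}

#' Tidy a PHI manifest into its token table
#' @param x A `phi_manifest`.
#' @param ... Unused.
#' @method tidy phi_manifest
#' @export
tidy.phi_manifest <- function(x, ...) x$tokens

#' Tidy a cleanliness verdict into its findings
#' @param x A `clean_verdict`.
#' @param ... Unused.
#' @method tidy clean_verdict
#' @export
tidy.clean_verdict <- function(x, ...) x$findings

#' One-row summary of a cleanliness verdict
#' @param x A `clean_verdict`.
#' @param ... Unused.
#' @method glance clean_verdict
#' @export
glance.clean_verdict <- function(x, ...) {
  tibble(clean = x$clean, n_findings = nrow(x$findings))
}

#' Stack an SDTM export into one long tibble
#' @param x An `sdtm_export`.
#' @param ... Unused.
#' @method tidy sdtm_export
#' @export
tidy.sdtm_export <- function(x, ...) {
  bind_rows(
    mutate(x$tu, VISIT = NA_character_, ORRES = as.character(.data$ORRES)),
    mutate(x$tr, ORRES = as.character(.data$ORRES)),
    mutate(x$rs, LNKID = NA_character_)
  )
}

#' Plot QC findings as a pass/fail bar chart
#' @param object A `qc_report`.
#' @param ... Unused.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  ggplot(object$findings,
         aes(x = .data$parameter, fill = .data$verdict)) +
    geom_col(aes(y = 1), width = 0.8) +
    labs(title = sprintf("Quality assessment: %s", toupper(object$overall)),
         x = NULL, y = NULL, fill = "verdict")
}

#' Plot a slice of a DICOM dataset as a raster
#' @param object A `dcm_dataset` with pixel data.
#' @param ... Unused.
#' @method autoplot dcm_dataset
#' @export
autoplot.dcm_dataset <- function(object, ...) {
  if (is.null(object$pixel)) {
    ctimr_abort("dataset has no pixel data", "ctimr_geometry_error")
  }
  df <- expand.grid(row = seq_len(nrow(object$pixel)),
                    col = seq_len(ncol(object$pixel)))
  df$value <- as.vector(object$pixel)
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_tile() +
    labs(x = "column", y = "row", fill = "intensity")
}

#' @importFrom rlang .data
NULL
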