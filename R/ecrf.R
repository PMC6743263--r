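# Imaging eCRF layer: viewer-style measurement math, RECIST 1.1 response
# derivation, CDISC-controlled terminology mapping, and SDTM-style
# tabulation export (tumor domains TU / TR / RS).

RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD", "NE")
UNCODED <- "UNCODED"

#' Distance between two pixel points in mm
#'
#' Euclidean length under anisotropic pixel spacing: coordinates are
#' (row, col) pixel indices, spacing is (row mm, col mm).
#'
#' @param p1,p2 Numeric length-2 vectors `(row, col)`.
#' @param pixel_spacing Numeric `(row mm, col mm)`, both positive.
#' @return Length in mm.
#' @examples
#' compute_distance(c(0, 0), c(3, 4), c(1, 1)) # 5
#' @export
compute_distance <- function(p1, p2, pixel_spacing) {
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0)) {
    ctimr_abort("pixel spacing must be positive", "ctimr_geometry_error")
  }
  d <- (as.numeric(p1) - as.numeric(p2)) * as.numeric(pixel_spacing)
  sqrt(sum(d^2))
}

#' Polygon area in mm^2
#'
#' Shoelace formula on physically scaled vertices; orientation-independent.
#'
#' @param polygon Numeric matrix with >= 3 rows of `(row, col)` pixel
#'   vertices.
#' @param pixel_spacing Numeric `(row mm, col mm)`, both positive.
#' @return Area in mm^2.
#' @export
compute_area <- function(polygon, pixel_spacing) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) {
    ctimr_abort("a polygon needs at least 3 vertices", "ctimr_geometry_error")
  }
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0)) {
    ctimr_abort("pixel spacing must be positive", "ctimr_geometry_error")
  }
  y <- polygon[, 1] * pixel_spacing[1]
  x <- polygon[, 2] * pixel_spacing[2]
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Sum of target-lesion diameters at one timepoint
#'
#' @param measurements Numeric vector of longest diameters (mm), or a tibble
#'   with columns `diameter_mm` and `classification` (all must be
#'   `"target"`).
#' @return The arithmetic sum in mm (0 for an empty set).
#' @export
sum_of_diameters <- function(measurements) {
  if (is.data.frame(measurements)) {
    if (nrow(measurements) > 0L &&
        any(tolower(measurements$classification) != "target")) {
      ctimr_abort("sum of diameters includes only target lesions",
                  "ctimr_classification_error")
    }
    measurements <- measurements$diameter_mm
  }
  if (length(measurements) == 0L) return(0)
  if (any(measurements < 0)) {
    ctimr_abort("diameters must be non-negative", "ctimr_validation_error")
  }
  sum(as.numeric(measurements))
}

#' Derive the RECIST 1.1 timepoint response
#'
#' Thresholds follow the published RECIST 1.1 criteria, applied in order:
#'
#' * **PD** — a new lesion, or growth from nadir of at least 20% *and* at
#'   least 5 mm absolute;
#' * **CR** — all target lesions resolved and the current sum is 0;
#' * **PR** — decrease from baseline of at least 30%;
#' * **SD** — otherwise (baseline > 0);
#' * **NE** — no evaluable baseline.
#'
#' Both percentage boundaries are inclusive ("at least"). Growth from a
#' nadir of 0 (reappearance after complete disappearance) satisfies the
#' percentage term whenever the current sum exceeds 0, so PD then turns on
#' the 5 mm absolute gain. Vectorized over all arguments.
#'
#' @param baseline_sum Baseline sum of target diameters (mm).
#' @param nadir_sum Smallest sum on study up to this timepoint (mm).
#' @param current_sum Current sum (mm).
#' @param new_lesion Any unequivocal new lesion?
#' @param all_targets_resolved Have all target lesions disappeared
#'   (including nodal lesions regressing below the short-axis threshold)?
#' @return Character vector of `"CR"`, `"PR"`, `"SD"`, `"PD"`, `"NE"`.
#' @examples
#' derive_response(100, 100, 70) # "PR": exactly 30% decrease qualifies
#' derive_response(50, 50, 61)   # "PD": +22% and +11 mm
#' derive_response(100, 80, 90)  # "SD"
#' @export
derive_response <- function(baseline_sum, nadir_sum, current_sum,
                            new_lesion = FALSE, all_targets_resolved = FALSE) {
  n <- max(length(baseline_sum), length(nadir_sum), length(current_sum),
           length(new_lesion), length(all_targets_resolved))
  b <- rep_len(as.numeric(baseline_sum), n)
  nd <- rep_len(as.numeric(nadir_sum), n)
  cur <- rep_len(as.numeric(current_sum), n)
  nl <- rep_len(as.logical(new_lesion), n)
  res <- rep_len(as.logical(all_targets_resolved), n)
  if (any(b < 0 | nd < 0 | cur < 0, na.rm = TRUE)) {
    ctimr_abort("diameter sums must be non-negative", "ctimr_validation_error")
  }
  growth_pct <- ifelse(nd > 0, (cur - nd) / nd >= 0.2, cur > nd)
  pd <- nl | (growth_pct & (cur - nd) >= 5)
  cr <- res & cur == 0
  pr <- b > 0 & (b - cur) / b >= 0.3
  out <- rep("SD", n)
  out[b <= 0] <- "NE"
  out[pr] <- "PR"
  out[cr] <- "CR"
  out[pd] <- "PD"
  out
}

#' Map free text to controlled terminology
#'
#' Exact lookup after case folding and whitespace normalization; unmapped
#' terms yield the explicit `"UNCODED"` marker, never a silent
#' pass-through.
#'
#' @param value Character vector of free-text terms.
#' @param codelist A tibble with columns `term`, `code`, or a named
#'   character vector `c(term = code)`.
#' @return Character vector of controlled codes (or `"UNCODED"`).
#' @export
map_terminology <- function(value, codelist) {
  if (is.data.frame(codelist)) {
    codes <- stats::setNames(as.character(codelist$code),
                             normalize_term(codelist$term))
  } else {
    codes <- stats::setNames(as.character(codelist), normalize_term(names(codelist)))
  }
  out <- unname(codes[normalize_term(value)])
  out[is.na(out)] <- UNCODED
  out
}

normalize_term <- function(x) gsub("\\s+", " ", trimws(tolower(x)))

#' A small anatomical-location codelist
#'
#' Illustrative controlled terms for common RECIST target locations; real
#' trials load their therapeutic-area codelist from CSV.
#'
#' @return A tibble with columns `term`, `code`.
#' @export
anatomy_codelist <- function() {
  tibble(term = c("liver", "lung", "lymph node", "brain", "kidney",
                  "bone", "adrenal gland", "pleura"),
        code = c("LIVER", "LUNG", "LYMPH NODE", "BRAIN", "KIDNEY",
                 "BONE", "ADRENAL GLAND", "PLEURA"))
}

# ---- SDTM-style tabulation export -------------------------------------------

sdtm_templates <- function() {
  list(
    tu = tibble(DOMAIN = character(), USUBJID = character(),
                LNKID = character(), TESTCD = character(),
                ORRES = character(), ORRESU = character()),
    tr = tibble(DOMAIN = character(), USUBJID = character(),
                VISIT = character(), LNKID = character(),
                TESTCD = character(), ORRES = numeric(),
                ORRESU = character()),
    rs = tibble(DOMAIN = character(), USUBJID = character(),
                VISIT = character(), TESTCD = character(),
                ORRES = character(), ORRESU = character())
  )
}

#' Export imaging review results as SDTM-style tumor domains
#'
#' Emits one TU row per identified lesion, one TR row per measurement per
#' visit, and one RS row per timepoint response, in deterministic
#' (subject, visit, lesion) order. Export is blocked while any response is
#' unsigned (configurable), signalling an incomplete review.
#'
#' @param lesions Tibble: `subject`, `lesion_id`, `classification`,
#'   `location`.
#' @param measurements Tibble: `subject`, `visit`, `lesion_id`,
#'   `diameter_mm`.
#' @param responses Tibble: `subject`, `visit`, `response`, and (if
#'   `require_signed`) logical `signed`.
#' @param out_dir Optional directory: writes `tu.csv`, `tr.csv`, `rs.csv`.
#' @param require_signed Block export when any response is unsigned.
#' @param codelist Codelist applied to `location` for TU rows.
#' @return An `sdtm_export`: list of tibbles `tu`, `tr`, `rs` and `files`.
#' @export
export_tabulation <- function(lesions, measurements, responses,
                              out_dir = NULL, require_signed = TRUE,
                              codelist = anatomy_codelist()) {
  tpl <- sdtm_templates()
  if (require_signed && nrow(responses) > 0L) {
    if (!("signed" %in% names(responses)) || any(!responses$signed)) {
      ctimr_abort("export blocked: unsigned timepoint assessments present",
                  "ctimr_unsigned_error")
    }
  }
  tu <- if (nrow(lesions)) {
    arrange(tibble(DOMAIN = "TU", USUBJID = as.character(lesions$subject),
                   LNKID = as.character(lesions$lesion_id),
                   TESTCD = "TUMIDENT",
                   ORRES = toupper(as.character(lesions$classification)),
                   ORRESU = map_terminology(lesions$location, codelist)),
            .data$USUBJID, .data$LNKID)
  } else tpl$tu
  tr <- if (nrow(measurements)) {
    arrange(tibble(DOMAIN = "TR", USUBJID = as.character(measurements$subject),
                   VISIT = as.character(measurements$visit),
                   LNKID = as.character(measurements$lesion_id),
                   TESTCD = "LDIAM",
                   ORRES = as.numeric(measurements$diameter_mm),
                   ORRESU = "mm"),
            .data$USUBJID, .data$VISIT, .data$LNKID)
  } else tpl$tr
  rs <- if (nrow(responses)) {
    arrange(tibble(DOMAIN = "RS", USUBJID = as.character(responses$subject),
                   VISIT = as.character(responses$visit),
                   TESTCD = "OVRLRESP",
                   ORRES = as.character(responses$response),
                   ORRESU = ""),
            .data$USUBJID, .data$VISIT)
  } else tpl$rs
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(out_dir, c("tu.csv", "tr.csv", "rs.csv"))
    utils::write.csv(as.data.frame(tu), files[1], row.names = FALSE)
    utils::write.csv(as.data.frame(tr), files[2], row.names = FALSE)
    utils::write.csv(as.data.frame(rs), files[3], row.names = FALSE)
  }
  structure(list(tu = tu, tr = tr, rs = rs, files = files),
            class = "sdtm_export")
}

#' Re-import an SDTM-style tabulation export
#'
#' @param dir Directory holding `tu.csv`, `tr.csv`, `rs.csv`.
#' @return An `sdtm_export` with the three tibbles.
#' @export
import_tabulation <- function(dir) {
  rd <- function(f) as_tibble(utils::read.csv(file.path(dir, f),
                                              stringsAsFactors = FALSE,
                                              colClasses = "character"))
  tu <- rd("tu.csv"); tr <- rd("tr.csv"); rs <- rd("rs.csv")
  tr$ORRES <- as.numeric(tr$ORRES)
  structure(list(tu = tu, tr = tr, rs = rs, files = character(0)),
            class = "sdtm_export")
}

#' @export
print.sdtm_export <- function(x, ...) {
  cat(sprintf("<sdtm_export> TU: %d, TR: %d, RS: %d row(s)\n",
              nrow(x$tu), nrow(x$tr), nrow(x$rs)))
  invisible(x)
}
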