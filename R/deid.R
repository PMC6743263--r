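# Rule-driven DICOM deidentification.
#
# Five per-tag action codes drive the engine:
#   D  replace the value with the literal "DE-IDENTI"
#   R  reduce a date to YYYY0101 (keep year, normalize month/day)
#   E  remove the element
#   C  replace a UID with a new UID under the configured org root,
#      consistently across the whole study
#   N  substitute a named replacement-context value (subject number,
#      project id, or patient alias)
# After the rules run, a keyword / number-format scan sweeps the remaining
# elements (including private ones) for residual PHI, and a pixel blackout
# removes burned-in annotations.

ACTION_CODES <- c("D", "R", "E", "C", "N")
DEID_LITERAL <- "DE-IDENTI"
N_SOURCES <- c("initial", "subject_no", "project_id")

#' Deidentification rule
#'
#' @param tag A `dcm_tag` or tag string.
#' @param action One of `"D"`, `"R"`, `"E"`, `"C"`, `"N"`.
#' @param n_source For action N only: which replacement-context field
#'   supplies the value (`"initial"` maps to the patient alias,
#'   `"subject_no"`, `"project_id"`).
#' @return A `deid_rule`.
#' @export
deid_rule <- function(tag, action, n_source = NULL) {
  if (!is_string(action) || !(action %in% ACTION_CODES)) {
    ctimr_abort(sprintf("unknown action code: '%s'", action), "ctimr_config_error")
  }
  if (action == "N") {
    if (is.null(n_source) || !(n_source %in% N_SOURCES)) {
      ctimr_abort("action N requires n_source in {initial, subject_no, project_id}",
                  "ctimr_config_error")
    }
  } else if (!is.null(n_source)) {
    ctimr_abort("n_source is only meaningful for action N", "ctimr_config_error")
  }
  structure(list(tag = tag_key(tag), action = action, n_source = n_source),
            class = "deid_rule")
}

default_deid_rules <- function() {
  list(
    deid_rule("(0010,0010)", "N", "initial"),      # Patient name
    deid_rule("(0002,0003)", "C"),                 # Media storage SOP instance UID
    deid_rule("(0008,0018)", "C"),                 # SOP instance UID
    deid_rule("(0008,0050)", "E"),                 # Accession number
    deid_rule("(0008,0080)", "D"),                 # Institution name
    deid_rule("(0008,0081)", "E"),                 # Institution address
    deid_rule("(0008,0090)", "E"),                 # Referring physician name
    deid_rule("(0008,1050)", "E"),                 # Performing physician name
    deid_rule("(0010,0020)", "N", "subject_no"),   # Patient ID
    deid_rule("(0010,0030)", "R"),                 # Patient's birth date
    deid_rule("(0010,1001)", "E"),                 # Other patient names
    deid_rule("(0010,1002)", "E"),                 # Other patient IDs
    deid_rule("(0010,1040)", "E"),                 # Patient address
    deid_rule("(0020,0010)", "N", "project_id"),   # Study ID
    deid_rule("(0020,000D)", "C"),                 # Study instance UID
    deid_rule("(0020,000E)", "C")                  # Series instance UID
  )
}

default_scan_keywords <- function() {
  c("name", "birth", "patient", "hosp", "phone", "tel", "addr",
    "physician", "id", tolower(FIXTURE_INSTITUTIONS))
}

default_number_patterns <- function() {
  c(phone = "\\d{3}-\\d{4}-\\d{4}",
    national_id = "(?<!\\d)\\d{6,7}(?!\\d)",
    date_like = "(?<!\\d)(19|20)\\d{6}(?!\\d)")
}

#' Deidentification profile
#'
#' The default profile ships the sixteen standard per-tag rules (patient
#' name/ID/birth date, institution name/address, physicians, accession
#' number, study ID, other patient names/IDs, patient address, and the four
#' instance-hierarchy UIDs), the default keyword and number-format scan
#' lists, and a conservative remove policy for unmatched private elements.
#'
#' @param rules List of [deid_rule()] (at most one per tag).
#' @param scan_keywords Lowercase substrings flagged by [scan_for_phi()].
#' @param number_patterns Named character vector of PCRE digit patterns.
#' @param default_private_action Action applied to private elements with no
#'   explicit rule: `"E"` (remove, default), `"D"`, or `"N"` is not allowed
#'   here; use `"keep"` to leave them untouched.
#' @param org_root Dotted-decimal prefix for newly minted UIDs.
#' @param date_blank If `TRUE`, action R blanks the whole date instead of
#'   keeping the year.
#' @return A `deid_profile`.
#' @export
deid_profile <- function(rules = default_deid_rules(),
                         scan_keywords = default_scan_keywords(),
                         number_patterns = default_number_patterns(),
                         default_private_action = "E",
                         org_root = "1.2.410.200001",
                         date_blank = FALSE) {
  tags <- vapply(rules, function(r) r$tag, "")
  if (anyDuplicated(tags)) {
    ctimr_abort("at most one rule per tag", "ctimr_config_error")
  }
  if (!(default_private_action %in% c("E", "D", "keep"))) {
    ctimr_abort("default_private_action must be 'E', 'D' or 'keep'",
                "ctimr_config_error")
  }
  validate_uid(org_root)
  structure(list(rules = rules, scan_keywords = tolower(scan_keywords),
                 number_patterns = number_patterns,
                 default_private_action = default_private_action,
                 org_root = org_root, date_blank = isTRUE(date_blank)),
            class = "deid_profile")
}

#' @export
print.deid_profile <- function(x, ...) {
  cat(sprintf("<deid_profile> %d rule(s), %d keyword(s), %d pattern(s), private: %s, org root %s\n",
              length(x$rules), length(x$scan_keywords), length(x$number_patterns),
              x$default_private_action, x$org_root))
  invisible(x)
}

#' Replacement context
#'
#' The trial-assigned values substituted by action N: the subject screening
#' number, the project identifier, and the patient alias used for names.
#'
#' @param subject_no,project_id,patient_alias Non-empty strings.
#' @return A `replacement_context`.
#' @export
replacement_context <- function(subject_no = "Subject01",
                                project_id = "Project01",
                                patient_alias = "patient01") {
  for (v in c(subject_no, project_id, patient_alias)) {
    if (!is_string(v) || !nzchar(v)) {
      ctimr_abort("replacement context values must be non-empty strings",
                  "ctimr_context_error")
    }
  }
  structure(list(subject_no = subject_no, project_id = project_id,
                 patient_alias = patient_alias),
            class = "replacement_context")
}

ctx_value <- function(ctx, n_source) {
  switch(n_source,
         initial = ctx$patient_alias,
         subject_no = ctx$subject_no,
         project_id = ctx$project_id,
         ctimr_abort(sprintf("unknown n_source: %s", n_source), "ctimr_context_error"))
}

# ---- UID map ----------------------------------------------------------------

#' Study-wide UID map
#'
#' Maps original UIDs to new UIDs under `org_root`. The map is injective and
#' stable within a study: the same original UID always maps to the same new
#' UID, so Study/Series/SOP cross-references (including file-meta
#' (0002,0003)) stay consistent. New UIDs are a deterministic keyed hash of
#' (org_root, original UID), so re-running a deidentification with the same
#' root reproduces the map.
#'
#' @param org_root Dotted-decimal UID prefix for new UIDs.
#' @return A `uid_map` (environment-backed, mutated in place by lookups).
#' @export
uid_map <- function(org_root = "1.2.410.200001") {
  validate_uid(org_root)
  env <- new.env(parent = emptyenv())
  env$entries <- character(0)
  structure(list(env = env, org_root = org_root), class = "uid_map")
}

hash_uid <- function(org_root, key) {
  h <- sha256_hex(paste(org_root, key, sep = "|"))
  c1 <- format(strtoi(substr(h, 1L, 7L), 16L), scientific = FALSE)
  c2 <- format(strtoi(substr(h, 8L, 14L), 16L), scientific = FALSE)
  c3 <- format(strtoi(substr(h, 15L, 21L), 16L), scientific = FALSE)
  paste(org_root, c1, c2, c3, sep = ".")
}

#' Remap a UID through the study map
#'
#' Allocates a new UID under the org root on first sight and reuses it
#' thereafter. A UID already under the org root is returned unchanged, so
#' deidentification is idempotent.
#'
#' @param map A [uid_map()].
#' @param original The original UID string.
#' @param salt Optional extra key component: a non-`NULL` salt forces a
#'   fresh allocation distinct from the plain mapping (used when an
#'   instance's pixel content changes and it must become a new object).
#' @return The new UID string.
#' @export
uid_remap <- function(map, original, salt = NULL) {
  if (!is_string(original) || !nzchar(original)) {
    ctimr_abort("cannot remap an empty UID", "ctimr_profile_error")
  }
  key <- if (is.null(salt)) original else paste0(original, "#", salt)
  if (is.null(salt) && startsWith(original, paste0(map$org_root, "."))) {
    return(original)
  }
  hit <- map$env$entries[key]
  if (!is.na(hit)) return(unname(hit))
  new <- hash_uid(map$org_root, key)
  while (new %in% map$env$entries) {
    new <- hash_uid(map$org_root, paste0(key, "+"))
    key2 <- paste0(key, "+")
    key <- key2
  }
  map$env$entries[key] <- new
  unname(new)
}

#' Entries of a UID map
#'
#' @param map A [uid_map()].
#' @return A tibble with columns `original`, `new`.
#' @export
uid_map_entries <- function(map) {
  tibble(original = sub("#.*$", "", names(map$env$entries)),
         new = unname(map$env$entries))
}

# ---- Rule application -------------------------------------------------------

deid_removed <- function() structure(list(), class = "dcm_removed")

#' Is a value the REMOVED sentinel?
#' @param x Object returned by [apply_rule()].
#' @export
is_removed <- function(x) inherits(x, "dcm_removed")

#' Apply one deidentification rule to one attribute
#'
#' @param attr A `dcm_attr` whose tag matches `rule$tag`.
#' @param rule A [deid_rule()].
#' @param ctx A [replacement_context()] (required for action N).
#' @param uids A [uid_map()] (required for action C).
#' @param date_blank Action R blanks the date entirely instead of keeping
#'   the year.
#' @return The replacement `dcm_attr`, or the REMOVED sentinel for action E.
#' @export
apply_rule <- function(attr, rule, ctx = replacement_context(),
                       uids = uid_map(), date_blank = FALSE) {
  if (!identical(attr$tag, rule$tag)) {
    ctimr_abort(sprintf("rule tag %s does not match attribute tag %s",
                        rule$tag, attr$tag), "ctimr_profile_error")
  }
  switch(rule$action,
    D = dcm_attr(attr$tag, attr$vr, DEID_LITERAL),
    R = {
      v <- as.character(attr$value)
      digits <- gsub("[^0-9]", "", v)
      newv <- if (isTRUE(date_blank) || nchar(digits) < 4L) ""
              else paste0(substr(digits, 1L, 4L), "0101")
      dcm_attr(attr$tag, attr$vr, newv)
    },
    E = deid_removed(),
    C = {
      if (!identical(attr$vr, "UI")) {
        ctimr_abort(sprintf("action C requires VR UI, got %s at %s", attr$vr, attr$tag),
                    "ctimr_profile_error")
      }
      dcm_attr(attr$tag, "UI", uid_remap(uids, attr$value))
    },
    N = {
      if (is.null(ctx)) {
        ctimr_abort("action N requires a replacement context", "ctimr_context_error")
      }
      dcm_attr(attr$tag, attr$vr, ctx_value(ctx, rule$n_source))
    }
  )
}

# ---- Study deidentification -------------------------------------------------

report_row <- function(series, instance, tag, action, vr, value) {
  tibble(series = series, instance = instance, tag = tag, action = action,
         before_kind = vr,
         before_hash = sha256_hex(render_value(value)),
         after_kind = switch(action, D = "literal", R = "reduced-date",
                             E = "removed", C = "remapped-uid", N = "context"))
}

#' Deidentify a whole study
#'
#' Applies every profile rule to every dataset in which the tag occurs, using
#' one shared UID map for the study so that Study/Series/SOP cross-references
#' (and file-meta (0002,0003)) remain consistent. Private elements without an
#' explicit rule receive the profile's `default_private_action`. Re-running
#' on already-deidentified data is a no-op.
#'
#' @param study A `dcm_study`.
#' @param profile A [deid_profile()].
#' @param ctx A [replacement_context()].
#' @param uids Optional existing [uid_map()]; defaults to a fresh map rooted
#'   at `profile$org_root`.
#' @param log Optional [audit_log()]: one event is appended per dataset.
#' @param editor Account id recorded in audit events.
#' @return A `deid_result`: list with `study`, `uid_map`, and `report` (a
#'   tibble of rule applications that stores a hash of each original value,
#'   never the value itself).
#' @export
deidentify_study <- function(study, profile = deid_profile(),
                             ctx = replacement_context(),
                             uids = NULL, log = NULL, editor = "system") {
  uids <- uids %||% uid_map(profile$org_root)
  rules_by_tag <- stats::setNames(profile$rules,
                                  vapply(profile$rules, function(r) r$tag, ""))
  rows <- list()
  si_counter <- new.env(parent = emptyenv())
  si_counter$si <- 0L
  si_counter$ii <- 0L

  study2 <- study_map(study, function(ds) {
    si_counter$ii <- si_counter$ii + 1L
    idx <- si_counter$ii
    for (key in names(ds$attributes)) {
      a <- ds$attributes[[key]]
      rule <- rules_by_tag[[key]]
      if (!is.null(rule)) {
        res <- tryCatch(
          apply_rule(a, rule, ctx, uids, date_blank = profile$date_blank),
          ctimr_error = function(e) {
            ctimr_abort(sprintf("dataset %d, tag %s: %s", idx, key, conditionMessage(e)),
                        class(e)[1])
          })
        rows[[length(rows) + 1L]] <<- report_row(NA_integer_, idx, key,
                                                 rule$action, a$vr, a$value)
        if (is_removed(res)) ds$attributes[[key]] <- NULL
        else ds$attributes[[key]] <- res
      } else if (tag_is_private(key) && profile$default_private_action != "keep") {
        rows[[length(rows) + 1L]] <<- report_row(NA_integer_, idx, key,
                                                 profile$default_private_action,
                                                 a$vr, a$value)
        if (profile$default_private_action == "E") ds$attributes[[key]] <- NULL
        else ds$attributes[[key]] <- dcm_attr(key, a$vr, DEID_LITERAL)
      }
    }
    # file-meta media storage SOP instance UID follows the same map
    meta_rule <- rules_by_tag[[TAG_MEDIA_SOP_INSTANCE]]
    ma <- ds$meta[[TAG_MEDIA_SOP_INSTANCE]]
    if (!is.null(meta_rule) && !is.null(ma)) {
      res <- apply_rule(ma, meta_rule, ctx, uids, date_blank = profile$date_blank)
      rows[[length(rows) + 1L]] <<- report_row(NA_integer_, idx, TAG_MEDIA_SOP_INSTANCE,
                                               meta_rule$action, ma$vr, ma$value)
      if (!is_removed(res)) ds$meta[[TAG_MEDIA_SOP_INSTANCE]] <- res
    }
    ds
  })

  report <- if (length(rows)) bind_rows(rows) else
    tibble(series = integer(), instance = integer(), tag = character(),
           action = character(), before_kind = character(),
           before_hash = character(), after_kind = character())
  if (!is.null(log)) {
    append_event(log, editor = editor, entity = paste0("study:", study2$uid),
                 action = "modify", old = "identified-study",
                 new = "deidentified-study", reason = "deidentification")
  }
  structure(list(study = study2, uid_map = uids, report = report),
            class = "deid_result")
}

#' @export
print.deid_result <- function(x, ...) {
  cat(sprintf("<deid_result> %d rule application(s) across %d dataset(s)\n",
              nrow(x$report), length(study_datasets(x$study))))
  invisible(x)
}

# ---- Residual PHI scan ------------------------------------------------------

scan_one_value <- function(tag, vr, value, keywords, patterns, whitelist) {
  if (!is.character(value) || is.na(value) || !nzchar(value)) return(NULL)
  if (trimws(value) %in% whitelist) return(NULL)
  out <- list()
  low <- tolower(value)
  for (kw in keywords) {
    if (grepl(kw, low, fixed = TRUE)) {
      out[[length(out) + 1L]] <- tibble(tag = tag, vr = vr, reason = "keyword",
                                        matched = kw, snippet = substr(value, 1L, 40L))
    }
  }
  # digit-format scan: structural numeric/date/time/UID VRs are governed by
  # per-tag rules, not the free-text sweep
  if (!(vr %in% c("UI", "DA", "TM", "DT", "AS", "DS", "IS", "US", "UL"))) {
    for (pi in seq_along(patterns)) {
      m <- regmatches(value, regexpr(patterns[[pi]], value, perl = TRUE))
      if (length(m)) {
        out[[length(out) + 1L]] <- tibble(tag = tag, vr = vr, reason = "number-format",
                                          matched = names(patterns)[pi] %||% patterns[[pi]],
                                          snippet = m[1])
      }
    }
  }
  if (length(out)) bind_rows(out) else NULL
}

#' Scan a study for residual PHI
#'
#' Sweeps every text-valued element (standard and private) for profile
#' keywords (case-insensitive substrings) and digit patterns (phone-style
#' 3-4-4, national-id-style 6-7 digit, 8-digit date-like). Legitimate
#' replacement values — the `"DE-IDENTI"` literal and the replacement-context
#' values — are whitelisted. Findings are reported, never raised as errors.
#'
#' @param study A `dcm_study`.
#' @param profile A [deid_profile()].
#' @param ctx The [replacement_context()] whose values are whitelisted.
#' @return A tibble with columns `instance`, `tag`, `vr`, `reason`
#'   (`"keyword"` or `"number-format"`), `matched`, `snippet`.
#' @export
scan_for_phi <- function(study, profile = deid_profile(),
                         ctx = replacement_context()) {
  whitelist <- c(DEID_LITERAL,
                 if (!is.null(ctx)) unlist(ctx, use.names = FALSE))
  rows <- list()
  datasets <- study_datasets(study)
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    for (a in c(ds$attributes, ds$meta)) {
      f <- scan_one_value(a$tag, a$vr, a$value, profile$scan_keywords,
                          profile$number_patterns, whitelist)
      if (!is.null(f)) rows[[length(rows) + 1L]] <- mutate(f, instance = i, .before = 1L)
    }
  }
  if (length(rows)) bind_rows(rows) else
    tibble(instance = integer(), tag = character(), vr = character(),
           reason = character(), matched = character(), snippet = character())
}

# ---- Pixel blackout ---------------------------------------------------------

normalize_regions <- function(regions) {
  if (inherits(regions, "data.frame")) {
    lapply(seq_len(nrow(regions)), function(i) {
      list(rows = c(regions$r0[i], regions$r1[i]),
           cols = c(regions$c0[i], regions$c1[i]),
           slices = if ("slice" %in% names(regions) && !is.na(regions$slice[i]))
             regions$slice[i] else NULL)
    })
  } else regions
}

#' Black out pixel regions across a series
#'
#' Fills each rectangular region with the minimum pixel value (0 for the
#' unsigned data this package writes) on every addressed slice; all other
#' pixels are bit-identical. Each modified dataset becomes a new DICOM
#' object: it receives a fresh SOP Instance UID from the study UID map, and
#' file-meta (0002,0003) follows.
#'
#' @param series A `dcm_series`.
#' @param regions Either a list of `list(rows = c(r0, r1), cols = c(c0, c1),
#'   slices = NULL)` (1-based inclusive; `slices = NULL` addresses every
#'   slice) or a tibble with columns `slice` (NA = all), `r0`, `r1`, `c0`,
#'   `c1` (e.g. a manifest's `regions`).
#' @param uids The study [uid_map()].
#' @param log Optional [audit_log()].
#' @param editor Account id for audit events.
#' @return The modified `dcm_series`.
#' @export
blackout <- function(series, regions, uids = uid_map(), log = NULL,
                     editor = "system") {
  regions <- normalize_regions(regions)
  n <- length(series$datasets)
  for (ri in seq_along(regions)) {
    b <- regions[[ri]]
    slices <- b$slices %||% seq_len(n)
    for (zi in slices) {
      if (zi < 1L || zi > n) {
        ctimr_abort(sprintf("blackout slice %d outside series of %d slice(s)", zi, n),
                    "ctimr_geometry_error")
      }
      ds <- series$datasets[[zi]]
      if (is.null(ds$pixel)) {
        ctimr_abort(sprintf("slice %d has no pixel data", zi), "ctimr_geometry_error")
      }
      if (b$rows[1] < 1L || b$rows[2] > nrow(ds$pixel) ||
          b$cols[1] < 1L || b$cols[2] > ncol(ds$pixel) ||
          b$rows[1] > b$rows[2] || b$cols[1] > b$cols[2]) {
        ctimr_abort(sprintf("blackout region [%d:%d, %d:%d] outside %dx%d matrix on slice %d",
                            b$rows[1], b$rows[2], b$cols[1], b$cols[2],
                            nrow(ds$pixel), ncol(ds$pixel), zi),
                    "ctimr_geometry_error")
      }
      ds$pixel[b$rows[1]:b$rows[2], b$cols[1]:b$cols[2]] <- 0L
      series$datasets[[zi]] <- ds
      attr(series$datasets[[zi]], "ctimr_modified") <- TRUE
    }
  }
  for (zi in seq_len(n)) {
    if (isTRUE(attr(series$datasets[[zi]], "ctimr_modified"))) {
      ds <- series$datasets[[zi]]
      old <- ds_value(ds, TAG_SOP_INSTANCE)
      new <- uid_remap(uids, old, salt = "pixel-edit")
      ds <- ds_set(ds, TAG_SOP_INSTANCE, "UI", new)
      ds$meta[[TAG_MEDIA_SOP_INSTANCE]] <- dcm_attr(TAG_MEDIA_SOP_INSTANCE, "UI", new)
      attr(ds, "ctimr_modified") <- NULL
      series$datasets[[zi]] <- ds
      if (!is.null(log)) {
        append_event(log, editor = editor, entity = paste0("instance:", old),
                     action = "modify", old = "pixels", new = "blacked-out",
                     reason = "burned-in text blackout")
      }
    }
  }
  series
}

#' Black out all manifest regions of a study
#'
#' Convenience wrapper applying every burned-in region recorded in a PHI
#' manifest to the matching series.
#'
#' @param study A `dcm_study`.
#' @param manifest A `phi_manifest`.
#' @param uids The study [uid_map()].
#' @param log,editor Audit trail hookup, see [blackout()].
#' @return The modified `dcm_study`.
#' @export
blackout_study <- function(study, manifest, uids = uid_map(), log = NULL,
                           editor = "system") {
  regs <- manifest$regions
  if (nrow(regs) == 0L) return(study)
  for (si in unique(regs$series)) {
    study$series[[si]] <- blackout(study$series[[si]],
                                   filter(regs, .data$series == si),
                                   uids, log = log, editor = editor)
  }
  study
}

# ---- Verification oracle ----------------------------------------------------

#' Verify that a study is clean of manifest PHI
#'
#' The verdict is CLEAN iff no manifest metadata token (nor any original UID)
#' occurs in any attribute or file-meta value, and every manifest burned-in
#' region has been fully blacked out.
#'
#' @param study A `dcm_study` (typically re-read from disk).
#' @param manifest The `phi_manifest` from the fixture that produced the
#'   study.
#' @return A `clean_verdict`: list with `clean` (logical) and `findings`
#'   (tibble `type`, `detail`).
#' @export
verify_clean <- function(study, manifest) {
  findings <- list()
  datasets <- study_datasets(study)
  values <- unlist(lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    vals <- vapply(c(ds$attributes, ds$meta), function(a) render_value(a$value), "")
    stats::setNames(vals, paste0("ds", i, ":", names(vals)))
  }))
  tokens <- manifest$tokens
  for (i in seq_len(nrow(tokens))) {
    hit <- grepl(tokens$text[i], values, fixed = TRUE)
    if (any(hit)) {
      findings[[length(findings) + 1L]] <- tibble(
        type = "metadata-token",
        detail = sprintf("token '%s' (%s) found at %s", tokens$text[i],
                         tokens$kind[i], paste(names(values)[hit], collapse = ", ")))
    }
  }
  for (u in manifest$uids$uid) {
    hit <- grepl(u, values, fixed = TRUE)
    if (any(hit)) {
      findings[[length(findings) + 1L]] <- tibble(
        type = "original-uid",
        detail = sprintf("original UID %s found at %s", u,
                         paste(names(values)[hit], collapse = ", ")))
    }
  }
  regs <- manifest$regions
  for (i in seq_len(nrow(regs))) {
    si <- regs$series[i]; zi <- regs$slice[i]
    if (si <= length(study$series) && zi <= length(study$series[[si]]$datasets)) {
      px <- study$series[[si]]$datasets[[zi]]$pixel
      if (is.null(px) ||
          any(px[regs$r0[i]:regs$r1[i], regs$c0[i]:regs$c1[i]] != 0L)) {
        findings[[length(findings) + 1L]] <- tibble(
          type = "burned-in",
          detail = sprintf("region [%d:%d, %d:%d] on series %d slice %d not blacked out",
                           regs$r0[i], regs$r1[i], regs$c0[i], regs$c1[i], si, zi))
      }
    } else {
      findings[[length(findings) + 1L]] <- tibble(
        type = "burned-in",
        detail = sprintf("series %d slice %d missing from study", si, zi))
    }
  }
  findings <- if (length(findings)) bind_rows(findings) else
    tibble(type = character(), detail = character())
  structure(list(clean = nrow(findings) == 0L, findings = findings),
            class = "clean_verdict")
}

#' @export
print.clean_verdict <- function(x, ...) {
  cat(if (x$clean) "CLEAN: no residual PHI found\n"
      else sprintf("NOT CLEAN: %d residual finding(s)\n", nrow(x$findings)))
  if (!x$clean) print(x$findings)
  invisible(x)
}
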