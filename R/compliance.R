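# 21 CFR Part 11 style record keeping: append-only hash-chained audit
# trails, electronic signatures bound to record hashes, a CAPA query
# lifecycle, and role-based access control with central-reviewer blinding.

GENESIS_HASH <- strrep("0", 64L)
AUDIT_ACTIONS <- c("create", "modify", "delete")
ROLES <- c("site_crc", "uploader", "qc_staff", "central_reviewer",
           "adjudicator", "project_manager", "admin")
QUERY_CATEGORIES <- c("system", "clinical")

# ---- Audit trail ------------------------------------------------------------

#' Create an append-only audit log
#'
#' Records are chained with SHA-256: each record's hash covers all of its
#' fields plus the previous record's hash (genesis: 64 zeros), so any
#' post-hoc alteration is detectable. The log is environment-backed; the
#' public surface only ever appends.
#'
#' @param clock A zero-argument function returning a UTC ISO-8601 timestamp;
#'   injectable for deterministic tests.
#' @return An `audit_log`.
#' @export
audit_log <- function(clock = utc_now) {
  env <- new.env(parent = emptyenv())
  env$records <- audit_template()
  structure(list(env = env, clock = clock), class = "audit_log")
}

audit_template <- function() {
  tibble(seq = integer(), timestamp = character(), editor = character(),
         entity = character(), action = character(), old_value = character(),
         new_value = character(), reason = character(),
         prev_hash = character(), this_hash = character())
}

record_hash <- function(seq, timestamp, editor, entity, action,
                        old_value, new_value, reason, prev_hash) {
  nul <- function(x) if (is.na(x)) "" else as.character(x)
  sha256_hex(paste(seq, timestamp, nul(editor), nul(entity), nul(action),
                   nul(old_value), nul(new_value), nul(reason), prev_hash,
                   sep = "\x1f"))
}

#' Append an event to the audit trail
#'
#' Modifications and deletions must carry a non-empty reason and always
#' retain the old value: previous data is never obscured.
#'
#' @param log An [audit_log()].
#' @param editor Account id of the actor.
#' @param entity Identifier of the record acted on.
#' @param action `"create"`, `"modify"`, or `"delete"`.
#' @param old,new Serialized values (or value hashes); `old` is required for
#'   modify/delete.
#' @param reason Free-text reason; required for modify/delete.
#' @return The appended record (one-row tibble), invisibly.
#' @export
append_event <- function(log, editor, entity, action, old = NA_character_,
                         new = NA_character_, reason = NA_character_) {
  if (!(action %in% AUDIT_ACTIONS)) {
    ctimr_abort(sprintf("unknown audit action: '%s'", action), "ctimr_config_error")
  }
  if (action %in% c("modify", "delete") &&
      (is.na(reason) || !nzchar(trimws(reason)))) {
    ctimr_abort(sprintf("a reason is required for %s events", action),
                "ctimr_validation_error")
  }
  recs <- log$env$records
  seq <- nrow(recs) + 1L
  prev <- if (seq == 1L) GENESIS_HASH else recs$this_hash[seq - 1L]
  ts <- log$clock()
  rec <- tibble(seq = seq, timestamp = ts, editor = editor, entity = entity,
                action = action, old_value = as.character(old),
                new_value = as.character(new), reason = as.character(reason),
                prev_hash = prev,
                this_hash = record_hash(seq, ts, editor, entity, action,
                                        as.character(old), as.character(new),
                                        as.character(reason), prev))
  log$env$records <- bind_rows(recs, rec)
  invisible(rec)
}

#' Records of an audit log
#'
#' @param log An [audit_log()].
#' @return The records tibble (a copy; the log itself is append-only).
#' @export
audit_records <- function(log) {
  if (inherits(log, "audit_log")) log$env$records else as_tibble(log)
}

#' @export
print.audit_log <- function(x, ...) {
  recs <- audit_records(x)
  cat(sprintf("<audit_log> %d record(s)\n", nrow(recs)))
  invisible(x)
}

#' Verify the integrity of an audit trail
#'
#' Recomputes every hash and checks sequence contiguity and chain linkage.
#'
#' @param log An [audit_log()] or a records tibble.
#' @return A list: `valid` (logical) and `first_broken` (sequence number of
#'   the first broken record, `NA` if valid).
#' @export
verify_chain <- function(log) {
  recs <- audit_records(log)
  if (nrow(recs) == 0L) return(list(valid = TRUE, first_broken = NA_integer_))
  prev <- GENESIS_HASH
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    expected <- record_hash(r$seq, r$timestamp, r$editor, r$entity, r$action,
                            r$old_value, r$new_value, r$reason, r$prev_hash)
    if (r$seq != i || !identical(r$prev_hash, prev) ||
        !identical(r$this_hash, expected)) {
      return(list(valid = FALSE, first_broken = i))
    }
    prev <- r$this_hash
  }
  list(valid = TRUE, first_broken = NA_integer_)
}

#' Persist / load an audit log as JSON lines
#'
#' One JSON object per line; loading reconstructs the log so appending
#' continues the chain.
#'
#' @param log An [audit_log()].
#' @param path File path.
#' @param clock Clock for the reconstructed log.
#' @name audit-io
#' @export
write_audit_log <- function(log, path) {
  recs <- audit_records(log)
  lines <- vapply(seq_len(nrow(recs)), function(i) {
    jsonlite::toJSON(as.list(recs[i, ]), auto_unbox = TRUE, na = "null", digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname audit-io
#' @export
read_audit_log <- function(path, clock = utc_now) {
  log <- audit_log(clock = clock)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      x <- lapply(x, function(v) if (is.null(v)) NA_character_ else v)
      as_tibble(x)
    })
    recs <- bind_rows(rows)
    recs$seq <- as.integer(recs$seq)
    log$env$records <- recs[names(audit_template())]
  }
  log
}

# ---- Electronic signatures --------------------------------------------------

#' Sign an audit record
#'
#' Binds the signer's account, printed name, the meaning of the signature,
#' and a timestamp to the current hash of the addressed record; any later
#' change to the record invalidates the signature.
#'
#' @param log An [audit_log()].
#' @param seq Sequence number of the record to sign.
#' @param account The signing [account()].
#' @param meaning The signing meaning, e.g. `"review approved"`.
#' @param printed_name Signer's printed name (defaults to the account's
#'   display name).
#' @param clock Timestamp source.
#' @return An `e_signature`.
#' @export
sign_record <- function(log, seq, account, meaning,
                        printed_name = account$display_name, clock = NULL) {
  recs <- audit_records(log)
  if (!(seq %in% recs$seq)) {
    ctimr_abort(sprintf("no audit record with seq %s", seq), "ctimr_reference_error")
  }
  rec <- recs[recs$seq == seq, ]
  structure(list(signer = account$id, printed_name = printed_name,
                 meaning = meaning,
                 timestamp = if (is.null(clock)) log$clock() else clock(),
                 seq = as.integer(seq), entity = rec$entity,
                 bound_hash = rec$this_hash),
            class = "e_signature")
}

#' Verify an electronic signature
#'
#' @param sig An `e_signature`.
#' @param log The [audit_log()] holding the signed record.
#' @return `TRUE` iff the bound record still hashes to the signed value.
#' @export
verify_signature <- function(sig, log) {
  recs <- audit_records(log)
  if (!(sig$seq %in% recs$seq)) return(FALSE)
  r <- recs[recs$seq == sig$seq, ]
  current <- record_hash(r$seq, r$timestamp, r$editor, r$entity, r$action,
                         r$old_value, r$new_value, r$reason, r$prev_hash)
  identical(current, sig$bound_hash) && identical(r$this_hash, sig$bound_hash)
}

#' @export
print.e_signature <- function(x, ...) {
  cat(sprintf("<e_signature> %s (%s): \"%s\" on record %d at %s\n",
              x$printed_name, x$signer, x$meaning, x$seq, x$timestamp))
  invisible(x)
}

# ---- CAPA query lifecycle ---------------------------------------------------

#' Open a CAPA query
#'
#' Queries fall into two categories: system problems (e.g. image upload
#' issues) and clinical-trial problems (e.g. missing data). States move
#' along open -> answered -> closed, with an escalation side state; closed
#' queries are immutable.
#'
#' @param id Query identifier.
#' @param category `"system"` or `"clinical"`.
#' @param addressee Account id responsible for answering.
#' @param text Initial message.
#' @param opened_by Account id of the opener.
#' @param clock Timestamp source.
#' @return A `capa_query`.
#' @export
new_query <- function(id, category, addressee, text, opened_by = "system",
                      clock = utc_now) {
  if (!(category %in% QUERY_CATEGORIES)) {
    ctimr_abort(sprintf("unknown query category: '%s'", category), "ctimr_config_error")
  }
  structure(list(id = id, category = category, state = "open",
                 addressee = addressee,
                 messages = tibble(timestamp = clock(), actor = opened_by,
                                   event = "open", text = text),
                 resolution = NA_character_),
            class = "capa_query")
}

QUERY_TRANSITIONS <- list(
  answer = c("open", "escalated"),
  close = "answered",
  escalate = c("open", "answered")
)

#' Transition a query through its lifecycle
#'
#' Closed queries reject every event. Closing requires a project manager or
#' admin; authorization is checked before the state transition, so an
#' unauthorized close attempt reports an access error even from an
#' ineligible state.
#'
#' @param q A `capa_query`.
#' @param event `"answer"`, `"close"`, or `"escalate"`.
#' @param actor The acting [account()].
#' @param text Message or resolution text.
#' @param log Optional [audit_log()].
#' @param clock Timestamp source.
#' @return The updated `capa_query`.
#' @export
transition_query <- function(q, event, actor, text = "", log = NULL,
                             clock = utc_now) {
  if (!(event %in% names(QUERY_TRANSITIONS))) {
    ctimr_abort(sprintf("unknown query event: '%s'", event), "ctimr_config_error")
  }
  if (q$state == "closed") {
    ctimr_abort(sprintf("query %s is closed and immutable", q$id), "ctimr_state_error")
  }
  action_name <- paste0(event, "_query")
  if (authorize(actor, action_name) != "allow") {
    ctimr_abort(sprintf("account '%s' (%s) may not %s queries",
                        actor$id, actor$role, event), "ctimr_access_error")
  }
  allowed_from <- QUERY_TRANSITIONS[[event]]
  if (!(q$state %in% allowed_from)) {
    ctimr_abort(sprintf("cannot %s a query in state '%s'", event, q$state),
                "ctimr_state_error")
  }
  q$state <- switch(event, answer = "answered", close = "closed",
                    escalate = "escalated")
  q$messages <- bind_rows(q$messages,
    tibble(timestamp = clock(), actor = actor$id, event = event, text = text))
  if (event == "close") q$resolution <- text
  if (!is.null(log)) {
    append_event(log, editor = actor$id, entity = paste0("query:", q$id),
                 action = "modify", old = allowed_from[1], new = q$state,
                 reason = paste0("query ", event))
  }
  q
}

#' @export
print.capa_query <- function(x, ...) {
  cat(sprintf("<capa_query> %s [%s/%s] addressee: %s\n", x$id, x$category,
              x$state, x$addressee))
  invisible(x)
}

query_to_list <- function(q) {
  list(id = q$id, category = q$category, state = q$state,
       addressee = q$addressee, messages = q$messages,
       resolution = q$resolution)
}

query_from_list <- function(x) {
  msgs <- x$messages
  msgs <- if (is.null(msgs) || length(msgs) == 0L) {
    tibble(timestamp = character(), actor = character(), event = character(),
           text = character())
  } else as_tibble(msgs)
  structure(list(id = x$id, category = x$category, state = x$state,
                 addressee = x$addressee, messages = msgs,
                 resolution = x$resolution %||% NA_character_),
            class = "capa_query")
}

# ---- Accounts, roles, blinding ----------------------------------------------

#' Create an account
#'
#' @param id Account id.
#' @param role One of the system roles: site CRC, uploader, QC staff,
#'   central reviewer, adjudicator, project manager, admin.
#' @param site Site identifier (site-bound roles).
#' @param display_name Printed name for signatures.
#' @return An `account`.
#' @export
account <- function(id, role, site = NA_character_, display_name = id) {
  if (!(role %in% ROLES)) {
    ctimr_abort(sprintf("unknown role: '%s'", role), "ctimr_config_error")
  }
  structure(list(id = id, role = role, site = site,
                 display_name = display_name),
            class = "account")
}

#' The default role-by-action permission matrix
#'
#' @return A tibble with columns `role`, `action`; listed pairs are allowed,
#'   everything else is denied (admin is always allowed).
#' @export
default_permission_matrix <- function() {
  allow <- list(
    site_crc = c("upload_images", "run_deid", "raise_query", "answer_query",
                 "read_images"),
    uploader = c("upload_images", "run_deid", "answer_query"),
    qc_staff = c("run_qc", "record_manual_qc", "raise_query", "answer_query",
                 "read_images"),
    central_reviewer = c("read_images", "read_measurement", "write_measurement",
                         "read_form", "write_form", "sign_record",
                         "answer_query"),
    adjudicator = c("read_images", "read_measurement", "read_form",
                    "write_form", "sign_record", "answer_query"),
    project_manager = c("read_images", "read_measurement", "read_form",
                        "read_audit", "raise_query", "close_query",
                        "escalate_query", "export_data", "sign_record")
  )
  bind_rows(lapply(names(allow), function(r)
    tibble(role = r, action = allow[[r]])))
}

#' Authorize an action
#'
#' Pure function of (role, action, resource). Admin is allowed everything.
#' Central reviewers are blinded: they never read (or write) another
#' reviewer's measurements or forms, while always retaining access to their
#' own. Site CRCs are limited to their own site's resources.
#'
#' @param acct An [account()].
#' @param action Action name, e.g. `"read_measurement"`.
#' @param resource Optional resource descriptor:
#'   `list(owner =, owner_role =, site =)`.
#' @param matrix Permission matrix (role/action tibble); defaults to
#'   [default_permission_matrix()].
#' @return `"allow"` or `"deny"`.
#' @export
authorize <- function(acct, action, resource = NULL,
                      matrix = default_permission_matrix()) {
  if (!inherits(acct, "account")) {
    ctimr_abort("authorize() needs an account object", "ctimr_config_error")
  }
  if (!(acct$role %in% ROLES)) {
    ctimr_abort(sprintf("unknown role: '%s'", acct$role), "ctimr_config_error")
  }
  if (acct$role == "admin") return("allow")
  # reviewer blinding: a central reviewer never touches a peer reviewer's
  # measurements or forms, own records always pass through to the matrix
  if (acct$role == "central_reviewer" &&
      action %in% c("read_measurement", "write_measurement", "read_form",
                    "write_form") &&
      !is.null(resource$owner) &&
      identical(resource$owner_role %||% "central_reviewer", "central_reviewer") &&
      !identical(resource$owner, acct$id)) {
    return("deny")
  }
  if (acct$role == "site_crc" && !is.null(resource$site) &&
      !is.na(acct$site) && !identical(resource$site, acct$site)) {
    return("deny")
  }
  hit <- matrix$role == acct$role & matrix$action == action
  if (any(hit)) "allow" else "deny"
}

#' Read / write a permission matrix as CSV
#'
#' @param matrix A role/action tibble.
#' @param path CSV path with columns `role`, `action`.
#' @name permission-io
#' @export
write_permission_matrix <- function(matrix, path) {
  utils::write.csv(matrix, path, row.names = FALSE)
  invisible(path)
}

#' @rdname permission-io
#' @export
read_permission_matrix <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

# ---- Master tracking report -------------------------------------------------

#' Build the master tracking report
#'
#' Merges the project's audit events, query histories, electronic
#' signatures, and QC outcomes into one chronological table, retaining the
#' recorded reason for every modification. A pure function of its inputs:
#' regeneration is byte-identical.
#'
#' @param project A list with any of: `id`, `audit` (an [audit_log()] or
#'   records tibble), `queries` (list of `capa_query`), `signatures` (list
#'   of `e_signature`), `qc_reports` (list of `qc_report`).
#' @return A `tracking_report` tibble: `timestamp`, `type`, `actor`,
#'   `entity`, `action`, `detail`, `reason`.
#' @export
build_tracking_report <- function(project) {
  rows <- list(tibble(timestamp = character(), type = character(),
                      actor = character(), entity = character(),
                      action = character(), detail = character(),
                      reason = character()))
  if (!is.null(project$audit)) {
    recs <- audit_records(project$audit)
    if (nrow(recs)) {
      rows[[length(rows) + 1L]] <- tibble(
        timestamp = recs$timestamp, type = "audit", actor = recs$editor,
        entity = recs$entity, action = recs$action,
        detail = ifelse(is.na(recs$new_value), "", recs$new_value),
        reason = ifelse(is.na(recs$reason), "", recs$reason))
    }
  }
  for (q in project$queries %||% list()) {
    rows[[length(rows) + 1L]] <- tibble(
      timestamp = q$messages$timestamp, type = "query",
      actor = q$messages$actor, entity = paste0("query:", q$id),
      action = q$messages$event, detail = q$messages$text, reason = "")
  }
  for (s in project$signatures %||% list()) {
    rows[[length(rows) + 1L]] <- tibble(
      timestamp = s$timestamp, type = "signature", actor = s$signer,
      entity = s$entity, action = "sign", detail = s$meaning, reason = "")
  }
  for (r in project$qc_reports %||% list()) {
    rows[[length(rows) + 1L]] <- tibble(
      timestamp = r$generated, type = "qc", actor = "qc-module",
      entity = paste0("series:", r$series_uid), action = r$overall,
      detail = sprintf("%d finding(s), %d deviation(s)", nrow(r$findings),
                       nrow(r$deviations)),
      reason = "")
  }
  out <- bind_rows(rows)
  out <- out[order(out$timestamp, out$type, out$entity, out$action,
                   method = "radix"), ]
  structure(as_tibble(out), class = c("tracking_report", class(as_tibble(out))))
}

#' Export a tracking report
#'
#' @param report A `tracking_report`.
#' @param csv,json Optional output paths.
#' @return The report, invisibly.
#' @export
write_tracking_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(as.data.frame(report), json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
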