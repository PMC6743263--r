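# Part-11 record keeping: hash-chained audit trail, signatures, CAPA query
# lifecycle, role-based blinding, and the master tracking report.

test_that("audit events chain, retain old values, and demand reasons", {
  log <- audit_log(clock = make_clock())
  append_event(log, "revA", "form:1", "create", new = "sum=62")
  append_event(log, "revA", "form:1", "modify", old = "sum=62", new = "sum=58",
               reason = "re-measured lesion 2")
  recs <- audit_records(log)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$old_value[2], "sum=62")
  expect_equal(recs$prev_hash[1], strrep("0", 64))
  expect_equal(recs$prev_hash[2], recs$this_hash[1])
  expect_error(append_event(log, "revA", "form:1", "modify", old = "x", new = "y",
                            reason = "  "),
               class = "ctimr_validation_error")
  expect_error(append_event(log, "revA", "form:1", "delete", old = "x"),
               class = "ctimr_validation_error")
  expect_error(append_event(log, "revA", "form:1", "rename"),
               class = "ctimr_config_error")
})

test_that("sequence numbers are strictly increasing over many events", {
  log <- audit_log(clock = make_clock())
  for (i in 1:100) append_event(log, "sys", paste0("e", i), "create", new = "v")
  recs <- audit_records(log)
  expect_identical(recs$seq, 1:100)
  expect_true(verify_chain(log)$valid)
})

test_that("appending never rewrites earlier records", {
  log <- audit_log(clock = make_clock())
  snapshots <- list()
  set.seed(42)
  for (i in 1:30) {
    act <- sample(c("create", "modify", "delete"), 1)
    append_event(log, sample(c("a", "b"), 1), paste0("e", sample(5, 1)), act,
                 old = "o", new = "n",
                 reason = if (act == "create") NA_character_ else "routine correction")
    recs <- audit_records(log)
    if (length(snapshots)) {
      expect_identical(recs[seq_len(nrow(recs) - 1L), ], snapshots[[length(snapshots)]])
    }
    snapshots[[i]] <- recs
  }
  expect_true(verify_chain(log)$valid)
})

test_that("any single-field tamper is detected at or before the altered record", {
  log <- audit_log(clock = make_clock())
  for (i in 1:6) {
    append_event(log, paste0("user", i), paste0("entity", i), "modify",
                 old = paste0("old", i), new = paste0("new", i),
                 reason = paste0("reason ", i))
  }
  recs <- audit_records(log)
  expect_true(verify_chain(recs)$valid)
  fields <- c("seq", "timestamp", "editor", "entity", "action", "old_value",
              "new_value", "reason", "prev_hash", "this_hash")
  for (i in seq_len(nrow(recs))) {
    for (f in fields) {
      tampered <- recs
      tampered[[f]][i] <- if (f == "seq") 99L else paste0(tampered[[f]][i], "x")
      v <- verify_chain(tampered)
      expect_false(v$valid, info = sprintf("record %d field %s", i, f))
      expect_lte(v$first_broken, i)
    }
  }
  expect_true(verify_chain(audit_log())$valid)
})

test_that("electronic signatures bind to the record hash", {
  log <- audit_log(clock = make_clock())
  append_event(log, "revA", "assessment:V2", "create", new = "response=PR")
  sig <- sign_record(log, 1L, reviewer_a(), "review approved")
  expect_true(verify_signature(sig, log))
  sig2 <- sign_record(log, 1L, account("adj1", "adjudicator"), "adjudication approved")
  expect_true(verify_signature(sig2, log))
  expect_error(sign_record(log, 7L, reviewer_a(), "x"),
               class = "ctimr_reference_error")
  # simulate external tampering with the stored record
  log$env$records$new_value[1] <- "response=CR"
  expect_false(verify_signature(sig, log))
  expect_false(verify_signature(sig2, log))
})

test_that("the query lifecycle enforces its state graph and permissions", {
  clock <- make_clock()
  q <- new_query("Q1", "clinical", addressee = "site1", text = "missing slice 3",
                 opened_by = "qc1", clock = clock)
  expect_equal(q$state, "open")
  expect_error(transition_query(q, "close", reviewer_a(), "done", clock = clock),
               class = "ctimr_access_error")
  q <- transition_query(q, "answer", account("crc1", "site_crc"),
                        "slice re-uploaded", clock = clock)
  expect_equal(q$state, "answered")
  q2 <- transition_query(q, "close", pm_account(), "resolved: re-upload verified",
                         clock = clock)
  expect_equal(q2$state, "closed")
  expect_equal(q2$resolution, "resolved: re-upload verified")
  for (ev in c("answer", "close", "escalate")) {
    expect_error(transition_query(q2, ev, admin_account(), "x", clock = clock),
                 class = "ctimr_state_error")
  }
  # escalation path: answered -> escalated -> answered
  q3 <- transition_query(q, "escalate", pm_account(), "needs radiologist input",
                         clock = clock)
  expect_equal(q3$state, "escalated")
  q3 <- transition_query(q3, "answer", reviewer_a(), "confirmed artifact",
                         clock = clock)
  expect_equal(q3$state, "answered")
  expect_error(transition_query(q, "answer", admin_account(), "x", clock = clock),
               class = "ctimr_state_error")
  expect_error(new_query("Q2", "billing", "a", "t"), class = "ctimr_config_error")
})

test_that("blinding denies peer-reviewer reads while own and admin reads pass", {
  own <- list(type = "measurement", owner = "revA", owner_role = "central_reviewer")
  peer <- list(type = "measurement", owner = "revB", owner_role = "central_reviewer")
  expect_equal(authorize(reviewer_a(), "read_measurement", peer), "deny")
  expect_equal(authorize(reviewer_b(), "read_measurement", own), "deny")
  expect_equal(authorize(reviewer_a(), "read_measurement", own), "allow")
  expect_equal(authorize(reviewer_b(), "read_measurement", peer), "allow")
  expect_equal(authorize(admin_account(), "read_measurement", peer), "allow")
  # blinding is symmetric over every reviewer pair and exempts self-reads
  for (a in c("revA", "revB", "revC")) {
    for (b in c("revA", "revB", "revC")) {
      verdict <- authorize(account(a, "central_reviewer"), "read_form",
                           list(type = "form", owner = b,
                                owner_role = "central_reviewer"))
      expect_equal(verdict, if (a == b) "allow" else "deny")
    }
  }
})

test_that("the permission matrix gives each role exactly its actions", {
  matrix <- default_permission_matrix()
  expected <- list(
    qc_staff = c(record_manual_qc = "allow", run_qc = "allow",
                 read_form = "deny", write_measurement = "deny",
                 close_query = "deny"),
    uploader = c(upload_images = "allow", run_deid = "allow",
                 record_manual_qc = "deny", read_measurement = "deny"),
    site_crc = c(upload_images = "allow", read_measurement = "deny"),
    central_reviewer = c(write_measurement = "allow", sign_record = "allow",
                         close_query = "deny", export_data = "deny"),
    adjudicator = c(read_measurement = "allow", write_form = "allow",
                    record_manual_qc = "deny"),
    project_manager = c(close_query = "allow", export_data = "allow",
                        read_audit = "allow", write_measurement = "deny")
  )
  for (role in names(expected)) {
    for (action in names(expected[[role]])) {
      expect_equal(authorize(account(paste0(role, "-acct"), role), action,
                             matrix = matrix),
                   unname(expected[[role]][action]),
                   info = paste(role, action))
    }
  }
  # site CRCs are confined to their own site
  crc <- account("crc1", "site_crc", site = "site01")
  expect_equal(authorize(crc, "upload_images", list(site = "site01")), "allow")
  expect_equal(authorize(crc, "upload_images", list(site = "site02")), "deny")
  # unknown roles are a configuration error
  fake <- structure(list(id = "x", role = "superuser", site = NA,
                         display_name = "x"), class = "account")
  expect_error(authorize(fake, "read_images"), class = "ctimr_config_error")
  expect_error(account("x", "superuser"), class = "ctimr_config_error")
})

test_that("state-changing operations in other modules emit audit events", {
  log <- audit_log(clock = make_clock())
  gen <- generate_study(small_spec(seed = 81L))
  res <- deidentify_study(gen$study, deid_profile(), replacement_context(),
                          log = log, editor = "up1")
  n1 <- nrow(audit_records(log))
  expect_gte(n1, 1L)
  blackout_study(res$study, gen$manifest, res$uid_map, log = log, editor = "up1")
  n2 <- nrow(audit_records(log))
  expect_gt(n2, n1)
  f <- run_auto_qc(gen$study$series[[1]],
                   protocol_spec("CT", list(qc_rule("rows", "eq", 32))))
  record_manual_qc(compile_report(f, clock = make_clock()), "artifact", "pass",
                   "none", qc_account(), log = log, clock = make_clock())
  expect_gt(nrow(audit_records(log)), n2)
  n3 <- nrow(audit_records(log))
  q <- new_query("Q9", "system", "site1", "upload failed", clock = make_clock())
  transition_query(q, "answer", account("crc1", "site_crc"), "retried",
                   log = log, clock = make_clock())
  expect_gt(nrow(audit_records(log)), n3)
  expect_true(verify_chain(log)$valid)
})

test_that("the tracking report merges all sources chronologically and reproducibly", {
  clock <- make_clock()
  log <- audit_log(clock = clock)
  append_event(log, "up1", "upload:1", "create", new = "series A")
  append_event(log, "up1", "upload:2", "create", new = "series B")
  append_event(log, "rev1", "form:1", "modify", old = "a", new = "b",
               reason = "typo in lesion site")
  q <- new_query("Q1", "system", "site1", "checksum mismatch", clock = clock)
  q <- transition_query(q, "answer", account("crc1", "site_crc"), "resent",
                        clock = clock)
  sig1 <- sign_record(log, 3L, reviewer_a(), "review approved", clock = clock)
  sig2 <- sign_record(log, 1L, account("adj1", "adjudicator"), "adjudicated",
                      clock = clock)
  project <- list(id = "P1", audit = log, queries = list(q),
                  signatures = list(sig1, sig2))
  report <- build_tracking_report(project)
  expect_equal(nrow(report), 3L + 2L + 2L)
  expect_false(is.unsorted(report$timestamp))
  # the recorded modification reason is retained
  expect_true(any(report$reason == "typo in lesion site"))
  # regeneration is identical (pure function of the logs)
  expect_identical(build_tracking_report(project), report)
  # empty project: valid empty report with the full header
  empty <- build_tracking_report(list(id = "P0"))
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), c("timestamp", "type", "actor", "entity",
                                   "action", "detail", "reason"))
})

test_that("audit logs persist as JSON lines and reload seamlessly", {
  log <- audit_log(clock = make_clock())
  append_event(log, "a", "e1", "create", new = "v1")
  append_event(log, "a", "e1", "modify", old = "v1", new = "v2", reason = "fix")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_audit_log(log, path)
  back <- read_audit_log(path, clock = make_clock())
  expect_identical(audit_records(back), audit_records(log))
  expect_true(verify_chain(back)$valid)
  # appending to a reloaded log continues the chain
  append_event(back, "b", "e2", "create", new = "v3")
  expect_true(verify_chain(back)$valid)
  expect_equal(audit_records(back)$prev_hash[3], audit_records(log)$this_hash[2])
})
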