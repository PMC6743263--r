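# Quality control: acquisition-parameter extraction, rule evaluation,
# one-factor perturbation soundness, and the quality assessment report.

test_that("interslice gap is center spacing minus thickness", {
  mk <- function(positions, thickness) {
    datasets <- lapply(seq_along(positions), function(i) {
      ds <- dcm_dataset()
      ds <- ds_set(ds, "(0008,0018)", "UI", paste0("1.2.3.", i))
      ds <- ds_set(ds, "(0020,000D)", "UI", "1.2.9")
      ds <- ds_set(ds, "(0020,000E)", "UI", "1.2.10")
      ds <- ds_set(ds, "(0020,0013)", "IS", format(i))
      ds <- ds_set(ds, "(0020,0032)", "DS",
                   paste(c("0", "0", format(positions[i])), collapse = "\\"))
      ds <- ds_set(ds, "(0020,0037)", "DS", "1\\0\\0\\0\\1\\0")
      ds <- ds_set(ds, "(0018,0050)", "DS", format(thickness))
      ds <- ds_set(ds, "(0028,0010)", "US", 16L)
      ds <- ds_set(ds, "(0028,0011)", "US", 16L)
      ds
    })
    dcm_series(datasets)
  }
  expect_equal(derive_acquisition_params(mk(c(0, 5, 10), 5))$interslice_gap, 0)
  expect_equal(derive_acquisition_params(mk(c(0, 6, 12), 5))$interslice_gap, 1.0)
  expect_true(is.na(derive_acquisition_params(mk(0, 5))$interslice_gap))
  # fallback to Spacing Between Slices when positions are absent
  s <- mk(0, 5)
  s$datasets[[1]] <- ds_remove(s$datasets[[1]], "(0020,0032)")
  s$datasets[[1]] <- ds_set(s$datasets[[1]], "(0018,0088)", "DS", "6")
  expect_equal(derive_acquisition_params(s)$interslice_gap, 1.0)
})

test_that("inconsistent matrix size within a series is an integrity error", {
  gen <- generate_study(small_spec(seed = 3L))
  s <- gen$study$series[[1]]
  s$datasets[[2]] <- ds_set(s$datasets[[2]], "(0028,0010)", "US", 16L)
  expect_error(derive_acquisition_params(s), class = "ctimr_integrity_error")
})

test_that("a conformant series passes and one-factor perturbations fail their own rule", {
  rules <- protocol_spec("CT", list(
    qc_rule("rows", "eq", 32),
    qc_rule("columns", "eq", 32),
    qc_rule("slice_thickness", "le", 5),
    qc_rule("interslice_gap", "eq", 0)
  ))
  base <- small_spec(seed = 5L)
  f0 <- run_auto_qc(generate_study(base)$study$series[[1]], rules)
  expect_true(all(f0$verdict == "pass"))
  expect_equal(compile_report(f0)$overall, "pass")

  cases <- list(
    list(field = "matrix", value = c(16L, 16L), fails = c("rows", "columns")),
    list(field = "slice_thickness", value = 6, fails = "slice_thickness"),
    list(field = "interslice_gap", value = 1, fails = "interslice_gap")
  )
  for (cs in cases) {
    pert <- perturb_protocol(base, cs$field, cs$value)
    f <- run_auto_qc(generate_study(pert)$study$series[[1]], rules)
    expect_setequal(f$parameter[f$verdict == "fail"], cs$fails)
    expect_equal(compile_report(f)$overall, "fail")
  }
})

test_that("absent parameters are reported missing, never defaulted", {
  gen <- generate_study(small_spec(seed = 6L))
  s <- gen$study$series[[1]]
  s$datasets <- lapply(s$datasets, ds_remove, tag = "(0028,0030)")
  spec <- protocol_spec("CT", list(qc_rule("field_of_view", "le", 500, units = "mm")))
  f <- run_auto_qc(s, spec)
  expect_equal(f$verdict, "missing")
  expect_equal(compile_report(f)$overall, "fail")
  expect_equal(compile_report(f, missing_fails = FALSE)$overall, "pass")
  spec_opt <- protocol_spec("CT", list(
    qc_rule("rows", "eq", 32),
    qc_rule("field_of_view", "le", 500, optional = TRUE)))
  expect_equal(compile_report(run_auto_qc(s, spec_opt))$overall, "pass")
})

test_that("le/ge findings are monotone in the observed value", {
  params <- structure(list(slice_thickness = NA_real_), class = "acq_params")
  spec_le <- protocol_spec("CT", list(qc_rule("slice_thickness", "le", 5)))
  spec_ge <- protocol_spec("CT", list(qc_rule("slice_thickness", "ge", 5)))
  verdicts_le <- verdicts_ge <- character(0)
  for (v in c(1, 3, 5, 5.5, 7, 9)) {
    params$slice_thickness <- v
    verdicts_le <- c(verdicts_le, run_auto_qc(params, spec_le)$verdict)
    verdicts_ge <- c(verdicts_ge, run_auto_qc(params, spec_ge)$verdict)
  }
  # once failing under le, higher values keep failing (and dually for ge)
  expect_equal(verdicts_le, c("pass", "pass", "pass", "fail", "fail", "fail"))
  expect_equal(verdicts_ge, c("fail", "fail", "pass", "pass", "pass", "pass"))
})

test_that("manual QC respects roles and drives the overall verdict", {
  gen <- generate_study(small_spec(seed = 8L))
  f <- run_auto_qc(gen$study$series[[1]],
                   protocol_spec("CT", list(qc_rule("rows", "eq", 32))))
  clock <- make_clock()
  rep <- compile_report(f, clock = clock)
  expect_error(record_manual_qc(rep, "artifact", "fail", "motion",
                                account("up1", "uploader"), clock = clock),
               class = "ctimr_access_error")
  for (item in c("artifact", "coverage", "reconstruction", "contrast")) {
    rep <- record_manual_qc(rep, item, "pass", "ok", qc_account(), clock = clock)
  }
  expect_equal(rep$overall, "pass")
  expect_equal(nrow(rep$qualitative), 4L)
  rep2 <- record_manual_qc(rep, "artifact", "fail", "motion artifact",
                           qc_account(), clock = clock)
  expect_equal(rep2$overall, "fail")
  expect_error(record_manual_qc(rep, "sharpness", "pass", "", qc_account()),
               class = "ctimr_config_error")
})

test_that("failing rules raise protocol deviations and queries", {
  gen <- generate_study(small_spec(seed = 9L, slice_thickness = 7))
  f <- run_auto_qc(gen$study$series[[1]],
                   protocol_spec("CT", list(qc_rule("rows", "eq", 32),
                                            qc_rule("slice_thickness", "le", 5))))
  rep <- compile_report(f, clock = make_clock())
  expect_equal(rep$overall, "fail")
  expect_equal(nrow(rep$deviations), 1L)
  expect_length(rep$queries, 1L)
  expect_equal(rep$queries[[1]]$state, "open")
  expect_match(rep$queries[[1]]$messages$text[1], "slice_thickness")
  # qualitative-only failure also fails overall
  f_ok <- run_auto_qc(generate_study(small_spec(seed = 9L))$study$series[[1]],
                      protocol_spec("CT", list(qc_rule("rows", "eq", 32))))
  rep_q <- record_manual_qc(compile_report(f_ok, clock = make_clock()),
                            "coverage", "fail", "incomplete", qc_account(),
                            clock = make_clock())
  expect_equal(rep_q$overall, "fail")
})

test_that("the quality assessment report round-trips through JSON", {
  gen <- generate_study(small_spec(seed = 10L, slice_thickness = 6))
  f <- run_auto_qc(gen$study$series[[1]],
                   protocol_spec("CT", list(qc_rule("rows", "eq", 32),
                                            qc_rule("slice_thickness", "le", 5))))
  clock <- make_clock()
  rep <- compile_report(f, modality = "CT", series_uid = "1.2.3", clock = clock)
  rep <- record_manual_qc(rep, "contrast", "pass", "good enhancement",
                          qc_account(), clock = clock)
  back <- parse_qc_report_json(qc_report_json(rep))
  expect_equal(back$overall, rep$overall)
  expect_equal(back$findings, rep$findings)
  expect_equal(back$qualitative, rep$qualitative)
  expect_equal(back$deviations, rep$deviations)
  expect_length(back$queries, length(rep$queries))
  expect_equal(back$queries[[1]]$id, rep$queries[[1]]$id)
  expect_equal(back$queries[[1]]$state, rep$queries[[1]]$state)
  # the plain-text rendering carries the verdict
  expect_true(any(grepl("OVERALL: FAIL", format(rep))))
})
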