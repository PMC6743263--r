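# Deidentification engine: action codes, UID remapping, residual-PHI scan,
# blackout, and the end-to-end cleanliness oracle.

ctx01 <- replacement_context("Subject01", "Project01", "patient01")

test_that("each action code transforms its worked example correctly", {
  uids <- uid_map("1.2.410.200001")
  # D: institution name replaced with the 9-character literal
  out <- apply_rule(dcm_attr("(0008,0080)", "LO", "AMC"),
                    deid_rule("(0008,0080)", "D"), ctx01, uids)
  expect_equal(out$value, "DE-IDENTI")
  expect_equal(nchar(out$value), 9L)
  # R: birth date reduced to year + 0101
  out <- apply_rule(dcm_attr("(0010,0030)", "DA", "19890215"),
                    deid_rule("(0010,0030)", "R"), ctx01, uids)
  expect_equal(out$value, "19890101")
  # R with full-blank alternative
  out <- apply_rule(dcm_attr("(0010,0030)", "DA", "19890215"),
                    deid_rule("(0010,0030)", "R"), ctx01, uids, date_blank = TRUE)
  expect_equal(out$value, "")
  # E: accession number removed
  out <- apply_rule(dcm_attr("(0008,0050)", "SH", "00009"),
                    deid_rule("(0008,0050)", "E"), ctx01, uids)
  expect_true(is_removed(out))
  # N: patient ID replaced with the subject number
  out <- apply_rule(dcm_attr("(0010,0020)", "LO", "11112222"),
                    deid_rule("(0010,0020)", "N", "subject_no"), ctx01, uids)
  expect_equal(out$value, "Subject01")
  # C: same original UID remaps identically on both sightings
  a1 <- apply_rule(dcm_attr("(0008,0018)", "UI", "1.3.12.2.1107.5.9"),
                   deid_rule("(0008,0018)", "C"), ctx01, uids)
  a2 <- apply_rule(dcm_attr("(0008,0018)", "UI", "1.3.12.2.1107.5.9"),
                   deid_rule("(0008,0018)", "C"), ctx01, uids)
  expect_equal(a1$value, a2$value)
  expect_match(a1$value, "^1\\.2\\.410\\.200001\\.")
  expect_lte(nchar(a1$value), 64L)
  # C demands a UID-valued element
  expect_error(apply_rule(dcm_attr("(0010,0010)", "PN", "x"),
                          deid_rule("(0010,0010)", "C"), ctx01, uids),
               class = "ctimr_profile_error")
})

test_that("the default profile removes every manifest metadata token", {
  gen <- generate_study(small_spec(seed = 21L, n_series = 2L))
  res <- deidentify_study(gen$study, deid_profile(), ctx01)
  vals <- all_values(res$study)
  for (tok in gen$manifest$tokens$text) {
    expect_false(any(grepl(tok, vals, fixed = TRUE)), info = tok)
  }
  # report stores hashes, not original values
  expect_false(any(gen$manifest$tokens$text %in% unlist(res$report)))
  # protocol elements survive for downstream QC
  ds <- study_datasets(res$study)[[1]]
  expect_equal(ds_value(ds, "(0008,0070)"), "SIEMENS")
  expect_equal(ds_value(ds, "(0018,1030)"), "ABDOMEN ROUTINE")
  expect_false(is.na(ds_value(ds, "(0018,0050)")))
})

test_that("UID remapping preserves referential integrity and injectivity", {
  gen <- generate_study(small_spec(seed = 31L, n_series = 2L, n_slices = 4L))
  before <- gen$study
  res <- deidentify_study(before, deid_profile(), ctx01)
  after <- res$study
  # partition preserved: slice i of series j still shares its series UID
  expect_length(after$series, length(before$series))
  for (s in after$series) {
    uids <- vapply(s$datasets, function(d) ds_value(d, "(0020,000E)"), "")
    expect_length(unique(uids), 1L)
  }
  expect_length(unique(vapply(after$series, function(s) s$uid, "")), 2L)
  # file meta (0002,0003) equals remapped (0008,0018) for every instance
  for (ds in study_datasets(after)) {
    expect_identical(ds$meta[["(0002,0003)"]]$value, ds_value(ds, "(0008,0018)"))
    expect_match(ds_value(ds, "(0008,0018)"), "^1\\.2\\.410\\.200001\\.")
  }
  entries <- uid_map_entries(res$uid_map)
  expect_false(anyDuplicated(entries$new) > 0L)
  expect_true(all(startsWith(entries$new, "1.2.410.200001.")))
})

test_that("deidentification is idempotent", {
  gen <- generate_study(small_spec(seed = 41L))
  res1 <- deidentify_study(gen$study, deid_profile(), ctx01)
  res2 <- deidentify_study(res1$study, deid_profile(), ctx01, uids = res1$uid_map)
  expect_identical(study_attr_values(res2$study), study_attr_values(res1$study))
})

test_that("scan_for_phi agrees with an independent regex oracle", {
  spec <- small_spec(seed = 51L, private_elements = list(
    list(tag = "(0009,1001)", kind = "phone", text = "tel: 010-1234-5678"),
    list(tag = "(0009,1002)", kind = "name", text = "physician: Jane Roe")
  ))
  gen <- generate_study(spec)
  profile <- deid_profile()
  findings <- scan_for_phi(gen$study, profile, ctx01)
  # the phone-format private element is flagged as number-format
  expect_true(any(findings$tag == "(0009,1001)" & findings$reason == "number-format"))
  # the name-bearing private element is flagged by keyword
  expect_true(any(findings$tag == "(0009,1002)" & findings$reason == "keyword"))

  # oracle: scan every element value with plain regexes, independently
  oracle_hits <- 0L
  for (ds in study_datasets(gen$study)) {
    for (a in c(ds$attributes, ds$meta)) {
      v <- a$value
      if (!is.character(v) || is.na(v) || !nzchar(v)) next
      if (trimws(v) %in% c("DE-IDENTI", "Subject01", "Project01", "patient01")) next
      if (!(a$vr %in% c("UI", "DA", "TM", "DT", "AS", "DS", "IS", "US", "UL")) &&
          grepl("[0-9]{3}-[0-9]{4}-[0-9]{4}", v)) {
        oracle_hits <- oracle_hits + 1L
      }
    }
  }
  expect_equal(sum(findings$reason == "number-format" &
                   findings$matched == "phone"), oracle_hits)

  # a freshly deidentified fixture without private payloads scans clean
  clean_gen <- generate_study(small_spec(seed = 52L, private_elements = list(),
                                         burned_in = list()))
  res <- deidentify_study(clean_gen$study, profile, ctx01)
  expect_equal(nrow(scan_for_phi(res$study, profile, ctx01)), 0L)
})

test_that("blackout fills regions with the minimum value and renumbers SOP UIDs", {
  gen <- generate_study(small_spec(seed = 61L, n_slices = 10L))
  uids <- uid_map()
  series <- gen$study$series[[1]]
  before_px <- lapply(series$datasets, function(d) d$pixel)
  before_uids <- vapply(series$datasets, function(d) ds_value(d, "(0008,0018)"), "")
  regs <- gen$manifest$regions
  out <- blackout(series, regs, uids)
  for (i in seq_len(nrow(regs))) {
    px <- out$datasets[[regs$slice[i]]]$pixel
    expect_true(all(px[regs$r0[i]:regs$r1[i], regs$c0[i]:regs$c1[i]] == 0L))
  }
  # pixels outside every region are bit-identical
  msk <- matrix(FALSE, 32L, 32L)
  msk[regs$r0[1]:regs$r1[1], regs$c0[1]:regs$c1[1]] <- TRUE
  for (zi in seq_along(out$datasets)) {
    expect_identical(out$datasets[[zi]]$pixel[!msk], before_px[[zi]][!msk])
  }
  # predefined region across a 10-slice series: 10 modified slices, 10 new UIDs
  after_uids <- vapply(out$datasets, function(d) ds_value(d, "(0008,0018)"), "")
  expect_length(unique(after_uids), 10L)
  expect_true(all(after_uids != before_uids))
  for (d in out$datasets) {
    expect_identical(d$meta[["(0002,0003)"]]$value, ds_value(d, "(0008,0018)"))
  }
  expect_error(
    blackout(series, list(list(rows = c(1L, 40L), cols = c(1L, 5L))), uids),
    class = "ctimr_geometry_error")
})

test_that("verify_clean passes end-to-end and catches omissions", {
  gen <- generate_study(small_spec(seed = 71L))
  res <- deidentify_study(gen$study, deid_profile(), ctx01)
  full <- blackout_study(res$study, gen$manifest, res$uid_map)
  expect_true(verify_clean(full, gen$manifest)$clean)

  # skipping blackout leaves the burned-in findings
  v <- verify_clean(res$study, gen$manifest)
  expect_false(v$clean)
  expect_true(all(v$findings$type == "burned-in"))

  # keeping private elements leaks their tokens, named by tag
  keep <- deid_profile(default_private_action = "keep")
  res2 <- deidentify_study(gen$study, keep, ctx01)
  leaked <- blackout_study(res2$study, gen$manifest, res2$uid_map)
  v2 <- verify_clean(leaked, gen$manifest)
  expect_false(v2$clean)
  expect_true(any(grepl("(0009,1001)", v2$findings$detail, fixed = TRUE)))
})

test_that("profiles reject duplicate tags and malformed N rules", {
  expect_error(deid_profile(rules = list(deid_rule("(0010,0010)", "D"),
                                         deid_rule("(0010,0010)", "E"))),
               class = "ctimr_config_error")
  expect_error(deid_rule("(0010,0010)", "N"), class = "ctimr_config_error")
  expect_error(deid_rule("(0010,0010)", "Q"), class = "ctimr_config_error")
  expect_error(deid_rule("(0010,0010)", "D", n_source = "initial"),
               class = "ctimr_config_error")
})
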