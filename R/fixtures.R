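# Synthetic DICOM study generator with a ground-truth PHI manifest.
#
# The generator emulates what a site would upload in a CT-based oncology
# trial: multi-slice axial series carrying patient-identifying text in the
# standard elements, PHI-like payloads in private elements, and simulated
# burned-in annotations as bright rectangles. Every identifying token placed
# is recorded in a manifest so deidentification can be verified against
# ground truth. Background pixel noise is confined to 0..100 so that raw
# pixel bytes can never alias an ASCII token during byte-scan verification.

FIXTURE_NAMES <- c("Jhon Doe", "Jane Roe", "Richard Miles", "Mary Major",
                   "Kwan Minsu", "Erika Mustermann", "Taro Yamada")
FIXTURE_INSTITUTIONS <- c("AMC", "Severance Hospital", "Samsung Medical Center",
                          "SNU Hospital", "St Elsewhere General")
FIXTURE_ADDRESSES <- c("88, Olympic-ro 43-gil, Songpa-gu, Seoul",
                       "17, Misagangbyeon-daero, Hanam",
                       "101 Main Street, Springfield",
                       "5 Rue de la Sante, Paris")
RESERVED_REPLACEMENTS <- c("patient01", "Subject01", "Project01", "DE-IDENTI")
FIXTURE_UID_ROOT <- "1.3.12.2.1107.5"
SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"
BURNED_IN_VALUE <- 3000L

#' Specify a synthetic DICOM study
#'
#' Defaults describe the acquisition the package's QC example protocol
#' expects: a 512 x 512 CT series with 5 mm slice thickness and 0 mm
#' interslice gap. Slice positions are derived from thickness + gap unless
#' given explicitly, so perturbing one acquisition parameter perturbs only
#' that parameter.
#'
#' @param n_series Number of series in the study.
#' @param n_slices Slices per series.
#' @param modality Modality code, e.g. `"CT"`.
#' @param matrix Integer vector `c(rows, cols)`.
#' @param slice_thickness Slice thickness in mm.
#' @param interslice_gap Gap between slice edges in mm (0 = contiguous).
#' @param slice_positions Optional explicit z positions (mm), strictly
#'   monotone; overrides thickness/gap-derived positions.
#' @param phi PHI kinds to embed: subset of
#'   `c("name", "id", "date", "institution", "phone", "address")`.
#' @param burned_in List of burned-in text regions, each
#'   `list(rows = c(r0, r1), cols = c(c0, c1), slices = NULL)` with 1-based
#'   inclusive pixel indices; `slices = NULL` means every slice.
#' @param private_elements Optional list of extra private payloads, each
#'   `list(tag = "(0009,10xx)", kind = "phone", text = "...")`.
#' @param pixel_spacing Numeric `c(row mm, col mm)`.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_series = 1L, n_slices = 3L, modality = "CT",
                         matrix = c(512L, 512L), slice_thickness = 5,
                         interslice_gap = 0, slice_positions = NULL,
                         phi = c("name", "id", "date", "institution",
                                 "phone", "address"),
                         burned_in = list(list(rows = c(1L, 10L),
                                               cols = c(1L, 40L),
                                               slices = NULL)),
                         private_elements = NULL,
                         pixel_spacing = c(0.7, 0.7),
                         seed = 1L) {
  spec <- structure(
    list(n_series = as.integer(n_series), n_slices = as.integer(n_slices),
         modality = modality, matrix = as.integer(matrix),
         slice_thickness = as.numeric(slice_thickness),
         interslice_gap = as.numeric(interslice_gap),
         slice_positions = slice_positions,
         phi = phi, burned_in = burned_in,
         private_elements = private_elements,
         pixel_spacing = as.numeric(pixel_spacing),
         seed = as.integer(seed)),
    class = "fixture_spec")
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  if (spec$n_series < 0L || spec$n_slices < 1L) {
    ctimr_abort("n_series must be >= 0 and n_slices >= 1", "ctimr_config_error")
  }
  if (length(spec$matrix) != 2L || any(spec$matrix < 1L)) {
    ctimr_abort("matrix must be c(rows, cols) of positive integers", "ctimr_config_error")
  }
  pos <- fixture_positions(spec)
  if (length(pos) > 1L && any(diff(pos) <= 0)) {
    ctimr_abort("slice positions must be strictly monotone", "ctimr_config_error")
  }
  for (b in spec$burned_in) {
    if (b$rows[1] < 1L || b$rows[2] > spec$matrix[1] ||
        b$cols[1] < 1L || b$cols[2] > spec$matrix[2] ||
        b$rows[1] > b$rows[2] || b$cols[1] > b$cols[2]) {
      ctimr_abort("burned-in region lies outside the pixel matrix",
                  "ctimr_geometry_error")
    }
  }
  unknown <- setdiff(spec$phi, c("name", "id", "date", "institution", "phone", "address"))
  if (length(unknown)) {
    ctimr_abort(sprintf("unknown phi kind(s): %s", paste(unknown, collapse = ", ")),
                "ctimr_config_error")
  }
  invisible(spec)
}

fixture_positions <- function(spec) {
  if (!is.null(spec$slice_positions)) return(as.numeric(spec$slice_positions))
  step <- spec$slice_thickness + spec$interslice_gap
  seq(0, by = step, length.out = spec$n_slices)
}

#' Perturb one acquisition parameter of a fixture spec
#'
#' Returns a copy of `spec` differing only in the named field. Used to build
#' one-factor protocol-deviation cases for QC testing.
#'
#' @param spec A `fixture_spec`.
#' @param field One of `n_series`, `n_slices`, `modality`, `matrix`,
#'   `slice_thickness`, `interslice_gap`, `slice_positions`, `pixel_spacing`.
#' @param value The new value.
#' @return A `fixture_spec`.
#' @export
perturb_protocol <- function(spec, field, value) {
  allowed <- c("n_series", "n_slices", "modality", "matrix",
               "slice_thickness", "interslice_gap", "slice_positions",
               "pixel_spacing")
  if (!is_string(field) || !(field %in% allowed)) {
    ctimr_abort(sprintf("unknown acquisition parameter: '%s'", field),
                "ctimr_config_error")
  }
  spec[[field]] <- if (field %in% c("n_series", "n_slices", "matrix"))
    as.integer(value) else value
  validate_fixture_spec(spec)
  spec
}

random_digits <- function(n) paste(sample(0:9, n, replace = TRUE), collapse = "")

# Draw a token, rejecting collisions with reserved replacement values.
draw_token <- function(pool) {
  repeat {
    tok <- if (is.character(pool)) sample(pool, 1L) else pool()
    if (!(tok %in% RESERVED_REPLACEMENTS)) return(tok)
  }
}

new_fixture_uid <- function(scope) {
  paste0(FIXTURE_UID_ROOT, ".", scope, ".",
         random_digits(1), ".", paste0(sample(1:9, 1), random_digits(5)))
}

#' Generate a synthetic DICOM study with known PHI
#'
#' Deterministic given `spec$seed`. PHI tokens are placed in the standard
#' patient/institution/physician elements, in private elements, and as
#' bright rectangles at the burned-in regions; every placement is recorded
#' in the returned manifest. File-meta (0002,0003) always equals
#' (0008,0018); all slices of a series share the Series/Study UIDs.
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `study` (a `dcm_study`) and `manifest` (a
#'   `phi_manifest`: tibbles `tokens`, `regions`, `uids`).
#' @export
generate_study <- function(spec) {
  validate_fixture_spec(spec)
  with_seed(spec$seed, generate_study_impl(spec))
}

generate_study_impl <- function(spec) {
  tokens <- list()
  regions <- list()
  uids <- list()
  add_token <- function(location, kind, text) {
    tokens[[length(tokens) + 1L]] <<- tibble(location = location, kind = kind, text = text)
  }

  phi <- spec$phi
  patient_name <- if ("name" %in% phi) draw_token(FIXTURE_NAMES) else NA
  other_name <- if ("name" %in% phi) draw_token(setdiff(FIXTURE_NAMES, patient_name)) else NA
  ref_phys <- if ("name" %in% phi) draw_token(setdiff(FIXTURE_NAMES, c(patient_name, other_name))) else NA
  perf_phys <- if ("name" %in% phi) draw_token(setdiff(FIXTURE_NAMES, c(patient_name, other_name, ref_phys))) else NA
  patient_id <- if ("id" %in% phi) draw_token(function() random_digits(8)) else NA
  other_id <- if ("id" %in% phi) draw_token(function() random_digits(8)) else NA
  accession <- if ("id" %in% phi) draw_token(function() random_digits(5)) else NA
  study_id <- if ("id" %in% phi) draw_token(function() random_digits(8)) else NA
  birth_date <- if ("date" %in% phi) {
    # never draw January 1: a YYYY0101 birth date would equal its own
    # reduced (year-preserving) replacement and break token/replacement
    # disjointness
    repeat {
      bd <- sprintf("%04d%02d%02d", sample(1940:2000, 1), sample(1:12, 1),
                    sample(1:28, 1))
      if (!endsWith(bd, "0101")) break
    }
    bd
  } else NA
  institution <- if ("institution" %in% phi) draw_token(FIXTURE_INSTITUTIONS) else NA
  inst_addr <- if ("address" %in% phi) draw_token(FIXTURE_ADDRESSES) else NA
  pat_addr <- if ("address" %in% phi) draw_token(setdiff(FIXTURE_ADDRESSES, inst_addr)) else NA
  phone <- if ("phone" %in% phi) {
    paste0("010-", random_digits(4), "-", random_digits(4))
  } else NA

  study_uid <- new_fixture_uid("1")
  uids[[length(uids) + 1L]] <- tibble(scope = "study", uid = study_uid)

  private <- spec$private_elements
  if (is.null(private)) {
    private <- list()
    if ("phone" %in% phi) {
      private <- c(private, list(list(tag = "(0009,1001)", kind = "phone",
                                      text = paste0("tel: ", phone))))
    }
    if ("id" %in% phi) {
      private <- c(private, list(list(tag = "(0009,1002)", kind = "id",
                                      text = draw_token(function() random_digits(7)))))
    }
    if ("name" %in% phi) {
      private <- c(private, list(list(tag = "(0009,1003)", kind = "name",
                                      text = paste("physician:", draw_token(FIXTURE_NAMES)))))
    }
  }

  series <- vector("list", spec$n_series)
  positions <- fixture_positions(spec)
  for (si in seq_len(spec$n_series)) {
    series_uid <- new_fixture_uid(paste0("2.", si))
    uids[[length(uids) + 1L]] <- tibble(scope = "series", uid = series_uid)
    datasets <- vector("list", spec$n_slices)
    for (zi in seq_len(spec$n_slices)) {
      sop_uid <- new_fixture_uid(paste0("3.", si, ".", zi))
      uids[[length(uids) + 1L]] <- tibble(scope = "instance", uid = sop_uid)

      pixel <- matrix(sample.int(101L, spec$matrix[1] * spec$matrix[2],
                                 replace = TRUE) - 1L,
                      nrow = spec$matrix[1], ncol = spec$matrix[2])
      for (bi in seq_along(spec$burned_in)) {
        b <- spec$burned_in[[bi]]
        slices <- b$slices %||% seq_len(spec$n_slices)
        if (zi %in% slices) {
          pixel[b$rows[1]:b$rows[2], b$cols[1]:b$cols[2]] <- BURNED_IN_VALUE
          regions[[length(regions) + 1L]] <- tibble(
            series = si, slice = zi,
            r0 = b$rows[1], r1 = b$rows[2], c0 = b$cols[1], c1 = b$cols[2],
            token = b$token %||%
              (if (!is.na(patient_name)) patient_name else "burned-in text"))
        }
      }

      ds <- dcm_dataset()
      ds <- ds_set(ds, "(0008,0016)", "UI", SOP_CLASS_CT)
      ds <- ds_set(ds, TAG_SOP_INSTANCE, "UI", sop_uid)
      ds <- ds_set(ds, "(0008,0020)", "DA", "20230101")
      ds <- ds_set(ds, "(0008,0060)", "CS", spec$modality)
      ds <- ds_set(ds, "(0008,0070)", "LO", "SIEMENS")
      ds <- ds_set(ds, "(0018,1030)", "LO", "ABDOMEN ROUTINE")
      ds <- ds_set(ds, "(0008,103E)", "LO", sprintf("AXIAL %d", si))
      if (!is.na(accession)) ds <- ds_set(ds, "(0008,0050)", "SH", accession)
      if (!is.na(institution)) ds <- ds_set(ds, "(0008,0080)", "LO", institution)
      if (!is.na(inst_addr)) ds <- ds_set(ds, "(0008,0081)", "ST", inst_addr)
      if (!is.na(ref_phys)) ds <- ds_set(ds, "(0008,0090)", "PN", ref_phys)
      if (!is.na(perf_phys)) ds <- ds_set(ds, "(0008,1050)", "PN", perf_phys)
      if (!is.na(patient_name)) ds <- ds_set(ds, "(0010,0010)", "PN", patient_name)
      if (!is.na(patient_id)) ds <- ds_set(ds, "(0010,0020)", "LO", patient_id)
      if (!is.na(birth_date)) ds <- ds_set(ds, "(0010,0030)", "DA", birth_date)
      if (!is.na(other_name)) ds <- ds_set(ds, "(0010,1001)", "PN", other_name)
      if (!is.na(other_id)) ds <- ds_set(ds, "(0010,1002)", "LO", other_id)
      if (!is.na(pat_addr)) ds <- ds_set(ds, "(0010,1040)", "LO", pat_addr)
      ds <- ds_set(ds, "(0018,0050)", "DS", format(spec$slice_thickness))
      ds <- ds_set(ds, TAG_STUDY_UID, "UI", study_uid)
      ds <- ds_set(ds, TAG_SERIES_UID, "UI", series_uid)
      if (!is.na(study_id)) ds <- ds_set(ds, "(0020,0010)", "SH", study_id)
      ds <- ds_set(ds, "(0020,0011)", "IS", format(si))
      ds <- ds_set(ds, "(0020,0013)", "IS", format(zi))
      ds <- ds_set(ds, "(0020,0032)", "DS",
                   paste(c("0", "0", format(positions[zi])), collapse = "\\"))
      ds <- ds_set(ds, "(0020,0037)", "DS", "1\\0\\0\\0\\1\\0")
      ds <- ds_set(ds, "(0028,0002)", "US", 1L)
      ds <- ds_set(ds, "(0028,0004)", "CS", "MONOCHROME2")
      ds <- ds_set(ds, "(0028,0030)", "DS",
                   paste(format(spec$pixel_spacing), collapse = "\\"))
      ds <- ds_set(ds, "(0028,0100)", "US", 16L)
      ds <- ds_set(ds, "(0028,0101)", "US", 16L)
      ds <- ds_set(ds, "(0028,0102)", "US", 15L)
      ds <- ds_set(ds, "(0028,0103)", "US", 0L)
      for (p in private) ds <- ds_set(ds, p$tag, "LO", p$text)
      ds$meta[[TAG_MEDIA_SOP_INSTANCE]] <- dcm_attr(TAG_MEDIA_SOP_INSTANCE, "UI", sop_uid)
      ds <- ds_set_pixel(ds, pixel)
      datasets[[zi]] <- ds
    }
    series[[si]] <- dcm_series(datasets)
  }

  if (!is.na(patient_name)) add_token("(0010,0010)", "name", patient_name)
  if (!is.na(other_name)) add_token("(0010,1001)", "name", other_name)
  if (!is.na(ref_phys)) add_token("(0008,0090)", "name", ref_phys)
  if (!is.na(perf_phys)) add_token("(0008,1050)", "name", perf_phys)
  if (!is.na(patient_id)) add_token("(0010,0020)", "id", patient_id)
  if (!is.na(other_id)) add_token("(0010,1002)", "id", other_id)
  if (!is.na(accession)) add_token("(0008,0050)", "id", accession)
  if (!is.na(study_id)) add_token("(0020,0010)", "id", study_id)
  if (!is.na(birth_date)) add_token("(0010,0030)", "date", birth_date)
  if (!is.na(institution)) add_token("(0008,0080)", "institution", institution)
  if (!is.na(inst_addr)) add_token("(0008,0081)", "address", inst_addr)
  if (!is.na(pat_addr)) add_token("(0010,1040)", "address", pat_addr)
  for (p in private) add_token(p$tag, p$kind %||% "private", p$text)

  manifest <- structure(
    list(tokens = if (length(tokens)) bind_rows(tokens) else
           tibble(location = character(), kind = character(), text = character()),
         regions = if (length(regions)) bind_rows(regions) else
           tibble(series = integer(), slice = integer(), r0 = integer(),
                  r1 = integer(), c0 = integer(), c1 = integer(),
                  token = character()),
         uids = bind_rows(uids)),
    class = "phi_manifest")

  list(study = dcm_study(series), manifest = manifest)
}

#' @export
print.phi_manifest <- function(x, ...) {
  cat(sprintf("<phi_manifest> %d token(s), %d burned-in region(s), %d UID(s)\n",
              nrow(x$tokens), nrow(x$regions), nrow(x$uids)))
  invisible(x)
}

#' Write or read a PHI manifest as JSON
#'
#' @param manifest A `phi_manifest`.
#' @param path File path.
#' @name manifest-io
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(
    list(tokens = manifest$tokens, regions = manifest$regions, uids = manifest$uids),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname manifest-io
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(tokens = as_tibble(x$tokens), regions = as_tibble(x$regions),
                 uids = as_tibble(x$uids)),
            class = "phi_manifest")
}
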