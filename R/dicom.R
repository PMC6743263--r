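# Minimal DICOM data model and Part 10 file I/O.
#
# The package operates on uncompressed explicit-VR little-endian files only
# (transfer syntax 1.2.840.10008.1.2.1): the blackout step must be able to
# edit pixels, so compressed syntaxes are rejected on read. Sequences (SQ)
# are out of scope.

STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                "PN", "SH", "ST", "TM", "UC", "UI", "UR", "UT")
LONG_FORM_VRS <- c("OB", "OW", "OF", "SQ", "UC", "UR", "UT", "UN")
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

TAG_PIXEL_DATA <- "(7FE0,0010)"
TAG_ROWS <- "(0028,0010)"
TAG_COLS <- "(0028,0011)"
TAG_SOP_INSTANCE <- "(0008,0018)"
TAG_MEDIA_SOP_INSTANCE <- "(0002,0003)"
TAG_SERIES_UID <- "(0020,000E)"
TAG_STUDY_UID <- "(0020,000D)"

# ---- Tags -------------------------------------------------------------------

#' Construct a DICOM tag
#'
#' A tag addresses one attribute by its (group, element) pair. Tags render
#' canonically as `"(GGGG,EEEE)"` in uppercase hex; ordering is lexicographic
#' on (group, element); a tag is private iff its group number is odd.
#'
#' @param group,element Integers in `0:65535`.
#' @return An object of class `dcm_tag`.
#' @examples
#' dcm_tag(0x0010, 0x0010)
#' @export
dcm_tag <- function(group, element) {
  group <- as.integer(group)
  element <- as.integer(element)
  if (is.na(group) || is.na(element) ||
      group < 0L || group > 0xFFFFL || element < 0L || element > 0xFFFFL) {
    ctimr_abort("tag group/element must be 16-bit integers", "ctimr_parse_error")
  }
  structure(list(group = group, element = element), class = "dcm_tag")
}

#' Parse a tag string
#'
#' Accepts the common dialects: `"GGGG,EEEE"`, `"GGGG, EEEE"`,
#' `"(GGGG,EEEE)"`, and eight contiguous hex digits (`"GGGGEEEE"`).
#' Case-insensitive. The canonical output form is `"(GGGG,EEEE)"`.
#'
#' @param text A tag string.
#' @return A `dcm_tag`.
#' @examples
#' parse_tag("0010, 0010")
#' parse_tag("(0008,0018)")
#' parse_tag("00100010")
#' @export
parse_tag <- function(text) {
  if (!is_string(text)) ctimr_abort("tag must be a single string", "ctimr_parse_error")
  m <- regmatches(text, regexec(
    "^\\s*\\(?\\s*([0-9a-fA-F]{4})\\s*[, ]?\\s*([0-9a-fA-F]{4})\\s*\\)?\\s*$",
    text))[[1]]
  if (length(m) != 3L) {
    ctimr_abort(sprintf("malformed tag string: '%s'", text), "ctimr_parse_error")
  }
  dcm_tag(strtoi(m[2], 16L), strtoi(m[3], 16L))
}

#' @export
format.dcm_tag <- function(x, ...) sprintf("(%04X,%04X)", x$group, x$element)

#' @export
print.dcm_tag <- function(x, ...) {
  cat("<dcm_tag> ", format(x), if (tag_is_private(x)) " [private]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.dcm_tag <- function(x, ...) format(x)

tag_key <- function(tag) {
  if (inherits(tag, "dcm_tag")) format(tag) else format(parse_tag(tag))
}

#' Is a tag private?
#'
#' @param tag A `dcm_tag` or tag string.
#' @return `TRUE` iff the group number is odd.
#' @export
tag_is_private <- function(tag) {
  if (!inherits(tag, "dcm_tag")) tag <- parse_tag(tag)
  tag$group %% 2L == 1L
}

tag_sort_value <- function(keys) {
  g <- strtoi(substr(keys, 2L, 5L), 16L)
  e <- strtoi(substr(keys, 7L, 10L), 16L)
  g * 65536 + e
}

# ---- Attributes and datasets ------------------------------------------------

#' Construct a DICOM attribute
#'
#' @param tag A `dcm_tag` or tag string.
#' @param vr Two-letter value representation code.
#' @param value Character scalar (string VRs, multi-values joined with
#'   backslashes), integer/numeric vector (binary VRs), or raw vector (OB/UN).
#' @return An object of class `dcm_attr`.
#' @export
dcm_attr <- function(tag, vr, value) {
  key <- tag_key(tag)
  if (!is_string(vr) || nchar(vr) != 2L) {
    ctimr_abort("vr must be a 2-letter code", "ctimr_parse_error")
  }
  if (vr == "UI") validate_uid(value)
  structure(list(tag = key, vr = vr, value = value), class = "dcm_attr")
}

validate_uid <- function(value) {
  if (is.na(value) || value == "") return(invisible(TRUE))
  for (v in strsplit(value, "\\\\")[[1]]) {
    if (nchar(v) > 64L || !grepl("^(0|[1-9][0-9]*)(\\.(0|[1-9][0-9]*))*$", v)) {
      ctimr_abort(sprintf("invalid UID value: '%s'", v), "ctimr_parse_error")
    }
  }
  invisible(TRUE)
}

#' Construct a DICOM dataset
#'
#' A dataset is an ordered map of attributes, an optional 2-D integer pixel
#' array, and the group-0002 file-meta attributes. If a pixel array is
#' present, Rows (0028,0010) and Columns (0028,0011) are kept in step with
#' its dimensions.
#'
#' @param attributes Named list of `dcm_attr` (names are canonical tag keys).
#' @param pixel Integer matrix or `NULL`.
#' @param meta Named list of file-meta `dcm_attr`.
#' @return An object of class `dcm_dataset`.
#' @export
dcm_dataset <- function(attributes = list(), pixel = NULL, meta = list()) {
  ds <- structure(list(attributes = attributes, pixel = NULL, meta = meta),
                  class = "dcm_dataset")
  ds$attributes <- ds$attributes[order(tag_sort_value(names(ds$attributes)))]
  if (!is.null(pixel)) ds <- ds_set_pixel(ds, pixel)
  ds
}

#' Set or read dataset attributes
#'
#' `ds_set()` inserts or replaces an attribute (keeping tag order);
#' `ds_get()` returns the `dcm_attr` or `NULL`; `ds_value()` returns the
#' stored value or `NA`; `ds_num()` parses a DS/IS/US value into a numeric
#' vector; `ds_remove()` drops an attribute.
#'
#' @param ds A `dcm_dataset`.
#' @param tag A `dcm_tag` or tag string.
#' @param vr,value Passed to [dcm_attr()].
#' @name dataset-access
#' @export
ds_set <- function(ds, tag, vr, value) {
  key <- tag_key(tag)
  ds$attributes[[key]] <- dcm_attr(key, vr, value)
  ds$attributes <- ds$attributes[order(tag_sort_value(names(ds$attributes)))]
  ds
}

#' @rdname dataset-access
#' @export
ds_get <- function(ds, tag) ds$attributes[[tag_key(tag)]]

#' @rdname dataset-access
#' @export
ds_value <- function(ds, tag) {
  a <- ds_get(ds, tag)
  if (is.null(a)) NA_character_ else a$value
}

#' @rdname dataset-access
#' @export
ds_num <- function(ds, tag) {
  a <- ds_get(ds, tag)
  if (is.null(a)) return(NULL)
  if (is.numeric(a$value)) return(as.numeric(a$value))
  suppressWarnings(as.numeric(strsplit(a$value, "\\\\")[[1]]))
}

#' @rdname dataset-access
#' @export
ds_remove <- function(ds, tag) {
  ds$attributes[[tag_key(tag)]] <- NULL
  ds
}

ds_set_pixel <- function(ds, pixel) {
  if (!is.matrix(pixel)) ctimr_abort("pixel array must be a matrix", "ctimr_geometry_error")
  storage.mode(pixel) <- "integer"
  ds$pixel <- pixel
  ds <- ds_set(ds, TAG_ROWS, "US", nrow(pixel))
  ds <- ds_set(ds, TAG_COLS, "US", ncol(pixel))
  ds
}

#' @export
print.dcm_dataset <- function(x, ...) {
  cat(sprintf("<dcm_dataset> %d attributes%s\n", length(x$attributes),
              if (is.null(x$pixel)) "" else
                sprintf(", %dx%d pixel array", nrow(x$pixel), ncol(x$pixel))))
  invisible(x)
}

#' Tabulate dataset attributes
#'
#' @param ds A `dcm_dataset`.
#' @param meta Include file-meta (group 0002) attributes?
#' @return A tibble with columns `tag`, `vr`, `value` (values rendered as
#'   character; binary payloads as `<n bytes>`).
#' @export
ds_table <- function(ds, meta = FALSE) {
  attrs <- c(if (meta) ds$meta else list(), ds$attributes)
  tibble(
    tag = vapply(attrs, function(a) a$tag, ""),
    vr = vapply(attrs, function(a) a$vr, ""),
    value = vapply(attrs, function(a) render_value(a$value), "")
  )
}

render_value <- function(v) {
  if (is.raw(v)) sprintf("<%d bytes>", length(v))
  else if (is.numeric(v)) paste(v, collapse = "\\")
  else as.character(v)
}

# ---- Series and studies -----------------------------------------------------

#' Series and study containers
#'
#' A series is an ordered list of datasets sharing one Series Instance UID,
#' sorted by the projection of Image Position (Patient) on the slice normal
#' (ties broken by Instance Number). A study set is a list of series sharing
#' one Study Instance UID.
#'
#' @param datasets List of `dcm_dataset`.
#' @param series List of `dcm_series`.
#' @name dicom-containers
#' @export
dcm_series <- function(datasets) {
  uids <- unique(vapply(datasets, function(d) ds_value(d, TAG_SERIES_UID), ""))
  if (length(datasets) > 0L && length(uids) != 1L) {
    ctimr_abort("datasets in a series must share one Series Instance UID",
                "ctimr_integrity_error")
  }
  structure(list(uid = if (length(uids)) uids else NA_character_,
                 datasets = sort_slices(datasets)),
            class = "dcm_series")
}

#' @rdname dicom-containers
#' @export
dcm_study <- function(series = list()) {
  uids <- unique(unlist(lapply(series, function(s)
    vapply(s$datasets, function(d) ds_value(d, TAG_STUDY_UID), ""))))
  if (length(uids) > 1L) {
    ctimr_abort("series in a study must share one Study Instance UID",
                "ctimr_integrity_error")
  }
  structure(list(uid = if (length(uids)) uids else NA_character_, series = series),
            class = "dcm_study")
}

#' @export
print.dcm_series <- function(x, ...) {
  cat(sprintf("<dcm_series> %s: %d slice(s)\n", x$uid, length(x$datasets)))
  invisible(x)
}

#' @export
print.dcm_study <- function(x, ...) {
  cat(sprintf("<dcm_study> %s: %d series\n", x$uid, length(x$series)))
  for (s in x$series) print(s)
  invisible(x)
}

slice_position <- function(ds) {
  ipp <- ds_num(ds, "(0020,0032)")
  iop <- ds_num(ds, "(0020,0037)")
  if (!is.null(ipp) && length(ipp) == 3L && !is.null(iop) && length(iop) == 6L &&
      !anyNA(ipp) && !anyNA(iop)) {
    r <- iop[1:3]; c <- iop[4:6]
    normal <- c(r[2] * c[3] - r[3] * c[2],
                r[3] * c[1] - r[1] * c[3],
                r[1] * c[2] - r[2] * c[1])
    sum(ipp * normal)
  } else NA_real_
}

sort_slices <- function(datasets) {
  if (length(datasets) <= 1L) return(datasets)
  pos <- vapply(datasets, slice_position, 0)
  inst <- vapply(datasets, function(d) {
    v <- ds_num(d, "(0020,0013)")
    if (is.null(v) || anyNA(v)) Inf else v[1]
  }, 0)
  datasets[order(pos, inst, na.last = TRUE)]
}

#' Iterate over all datasets of a study
#'
#' `study_datasets()` flattens to a list; `study_map()` applies a function to
#' every dataset, returning a rebuilt study (series membership preserved).
#'
#' @param study A `dcm_study`.
#' @param f Function `dcm_dataset -> dcm_dataset`.
#' @name study-iterate
#' @export
study_datasets <- function(study) {
  unlist(lapply(study$series, function(s) s$datasets), recursive = FALSE)
}

#' @rdname study-iterate
#' @export
study_map <- function(study, f) {
  study$series <- lapply(study$series, function(s) {
    s$datasets <- lapply(s$datasets, f)
    s$uid <- ds_value(s$datasets[[1]], TAG_SERIES_UID)
    s
  })
  if (length(study$series)) {
    study$uid <- ds_value(study$series[[1]]$datasets[[1]], TAG_STUDY_UID)
  }
  study
}

# ---- Binary helpers ---------------------------------------------------------

u16le <- function(x) as.raw(c(rbind(x %% 256L, x %/% 256L)))
u32le <- function(x) {
  as.raw(c(rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
                 (x %/% 16777216) %% 256)))
}
rd_u16 <- function(buf, i) as.integer(buf[i]) + 256L * as.integer(buf[i + 1L])
rd_u32 <- function(buf, i) {
  as.integer(buf[i]) + 256 * as.integer(buf[i + 1L]) +
    65536 * as.integer(buf[i + 2L]) + 16777216 * as.integer(buf[i + 3L])
}

encode_value <- function(vr, value) {
  if (vr %in% STRING_VRS) {
    if (is.na(value)) value <- ""
    b <- charToRaw(as.character(value))
    if (length(b) %% 2L == 1L) {
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    }
    b
  } else if (vr %in% c("US", "SS")) {
    u16le(as.integer(value))
  } else if (vr %in% c("UL", "SL")) {
    u32le(as.numeric(value))
  } else if (vr %in% c("OB", "UN")) {
    b <- as.raw(value)
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0L))
    b
  } else {
    ctimr_abort(sprintf("unsupported VR for writing: %s", vr), "ctimr_format_error")
  }
}

encode_element <- function(group, element, vr, bytes) {
  head <- c(u16le(c(group, element)), charToRaw(vr))
  if (vr %in% LONG_FORM_VRS) {
    c(head, as.raw(c(0L, 0L)), u32le(length(bytes)), bytes)
  } else {
    if (length(bytes) > 0xFFFF) {
      ctimr_abort("value too long for short-form VR", "ctimr_format_error")
    }
    c(head, u16le(length(bytes)), bytes)
  }
}

encode_attr <- function(a) {
  t <- parse_tag(a$tag)
  encode_element(t$group, t$element, a$vr, encode_value(a$vr, a$value))
}

# ---- File write -------------------------------------------------------------

#' Write one dataset as a DICOM Part 10 file
#'
#' Emits explicit-VR little-endian encoding with a standard file-meta group.
#' Attributes are written in ascending tag order; the pixel array (if any) is
#' written as 16-bit OW Pixel Data.
#'
#' @param ds A `dcm_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(ds, path) {
  meta <- ds$meta
  need <- function(key, vr, value) {
    if (is.null(meta[[key]])) meta[[key]] <<- dcm_attr(key, vr, value)
  }
  need("(0002,0001)", "OB", as.raw(c(0L, 1L)))
  need("(0002,0002)", "UI", ds_value(ds, "(0008,0016)"))
  need(TAG_MEDIA_SOP_INSTANCE, "UI", ds_value(ds, TAG_SOP_INSTANCE))
  need("(0002,0010)", "UI", TS_EXPLICIT_LE)
  need("(0002,0012)", "UI", "1.2.826.0.1.3680043.9.7484.1")
  need("(0002,0013)", "SH", "CTIMR_01")
  meta[["(0002,0000)"]] <- NULL
  meta <- meta[order(tag_sort_value(names(meta)))]
  meta_bytes <- unlist(lapply(meta, encode_attr), use.names = FALSE)
  if (is.null(meta_bytes)) meta_bytes <- raw(0)

  attrs <- ds$attributes[order(tag_sort_value(names(ds$attributes)))]
  body <- unlist(lapply(attrs, encode_attr), use.names = FALSE)
  if (is.null(body)) body <- raw(0)

  if (!is.null(ds$pixel)) {
    if (!identical(dim(ds$pixel),
                   c(as.integer(ds_num(ds, TAG_ROWS)), as.integer(ds_num(ds, TAG_COLS))))) {
      ctimr_abort("Rows/Columns do not match pixel array shape", "ctimr_integrity_error")
    }
    px <- u16le(as.integer(t(ds$pixel)))
    body <- c(body, encode_element(0x7FE0L, 0x0010L, "OW", px))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(encode_element(0x0002L, 0x0000L, "UL", u32le(length(meta_bytes))), con)
  writeBin(meta_bytes, con)
  writeBin(body, con)
  invisible(path)
}

# ---- File read --------------------------------------------------------------

decode_value <- function(vr, bytes) {
  if (vr %in% STRING_VRS) {
    while (length(bytes) && bytes[length(bytes)] == as.raw(0L)) {
      bytes <- bytes[-length(bytes)]
    }
    sub("[ ]+$", "", rawToChar(bytes))
  } else if (vr %in% c("US", "SS")) {
    readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
            signed = (vr == "SS"), endian = "little")
  } else if (vr %in% c("UL", "SL")) {
    readBin(bytes, "integer", n = length(bytes) %/% 4L, size = 4L, endian = "little")
  } else if (vr == "FL") {
    readBin(bytes, "double", n = length(bytes) %/% 4L, size = 4L, endian = "little")
  } else if (vr == "FD") {
    readBin(bytes, "double", n = length(bytes) %/% 8L, size = 8L, endian = "little")
  } else {
    bytes
  }
}

parse_elements <- function(buf, pos, end) {
  out <- list()
  while (pos + 7L <= end + 1L && pos <= end) {
    group <- rd_u16(buf, pos)
    element <- rd_u16(buf, pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      ctimr_abort(sprintf("unsupported (implicit-VR or corrupt) element near byte %d", pos),
                  "ctimr_format_error")
    }
    if (vr == "SQ") {
      ctimr_abort("sequence (SQ) elements are not supported", "ctimr_format_error")
    }
    if (vr %in% LONG_FORM_VRS) {
      len <- rd_u32(buf, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- rd_u16(buf, pos + 6L)
      vstart <- pos + 8L
    }
    if (vstart + len - 1L > end + 1L) {
      ctimr_abort("element length exceeds file size", "ctimr_format_error")
    }
    bytes <- if (len > 0L) buf[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("(%04X,%04X)", group, element)
    out[[key]] <- structure(list(tag = key, vr = vr, value = decode_value(vr, bytes)),
                            class = "dcm_attr")
    pos <- vstart + len
  }
  list(attrs = out, pos = pos)
}

#' Read one DICOM Part 10 file
#'
#' @param path Path to a DICOM file (explicit VR little endian).
#' @return A `dcm_dataset`.
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) {
    ctimr_abort(sprintf("no such file: %s", path), "ctimr_format_error")
  }
  n <- file.size(path)
  buf <- readBin(path, "raw", n)
  if (n < 140L || rawToChar(buf[129:132]) != "DICM") {
    ctimr_abort(sprintf("not a DICOM Part 10 file: %s", path), "ctimr_format_error")
  }
  # file meta group: (0002,0000) UL group length
  if (rd_u16(buf, 133L) != 2L || rd_u16(buf, 135L) != 0L) {
    ctimr_abort(sprintf("missing file-meta group length: %s", path), "ctimr_format_error")
  }
  # the element is (0002,0000) UL, short form: value starts at byte 141
  glen <- rd_u32(buf, 141L)
  meta_end <- 144L + glen
  meta <- parse_elements(buf, 145L, meta_end)$attrs
  ts <- meta[["(0002,0010)"]]
  if (!is.null(ts) && ts$value != TS_EXPLICIT_LE) {
    ctimr_abort(sprintf("unsupported transfer syntax '%s' in %s", ts$value, path),
                "ctimr_format_error")
  }
  parsed <- parse_elements(buf, meta_end + 1L, n)
  attrs <- parsed$attrs

  pixel <- NULL
  px <- attrs[[TAG_PIXEL_DATA]]
  if (!is.null(px)) {
    attrs[[TAG_PIXEL_DATA]] <- NULL
    rows <- as.integer(attrs[[TAG_ROWS]]$value)
    cols <- as.integer(attrs[[TAG_COLS]]$value)
    vals <- if (is.raw(px$value)) {
      readBin(px$value, "integer", n = length(px$value) %/% 2L, size = 2L,
              signed = FALSE, endian = "little")
    } else as.integer(px$value)
    if (length(vals) != rows * cols) {
      ctimr_abort(sprintf("pixel data length does not match Rows x Columns in %s", path),
                  "ctimr_integrity_error")
    }
    pixel <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  }
  ds <- dcm_dataset(attributes = attrs, meta = meta)
  if (!is.null(pixel)) ds <- ds_set_pixel(ds, pixel)
  ds
}

#' Read a set of DICOM files into a study
#'
#' Files are grouped by Study and Series Instance UID; slices within a series
#' are sorted by the projection of Image Position (Patient) on the slice
#' normal, ties broken by Instance Number.
#'
#' @param paths Character vector of file paths.
#' @return A `dcm_study` (empty for an empty input).
#' @export
read_series <- function(paths) {
  if (length(paths) == 0L) return(dcm_study())
  datasets <- lapply(paths, read_dicom)
  study_uids <- unique(vapply(datasets, function(d) ds_value(d, TAG_STUDY_UID), ""))
  if (length(study_uids) > 1L) {
    ctimr_abort("files span multiple Study Instance UIDs", "ctimr_integrity_error")
  }
  series_uid <- vapply(datasets, function(d) ds_value(d, TAG_SERIES_UID), "")
  groups <- split(datasets, factor(series_uid, levels = unique(series_uid)))
  dcm_study(lapply(unname(groups), dcm_series))
}

#' Write all datasets of a study as DICOM files
#'
#' @param study A `dcm_study`.
#' @param directory Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
write_series <- function(study, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    ctimr_abort(sprintf("cannot create directory: %s", directory), "ctimr_format_error")
  }
  paths <- character(0)
  for (si in seq_along(study$series)) {
    s <- study$series[[si]]
    for (ii in seq_along(s$datasets)) {
      p <- file.path(directory, sprintf("series%02d_inst%03d.dcm", si, ii))
      write_dicom(s$datasets[[ii]], p)
      paths <- c(paths, p)
    }
  }
  paths
}
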