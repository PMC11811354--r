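# DICOM Structured Report build/read. Follows the standard measurement-report
# pattern: a root CONTAINER holding one NUM content item per numeric CDE and
# one CODE item for the steatosis flag, referencing the source study.

.UNIT_CODES <- list(
  HU = list(value = "[hnsf'U]", scheme = "UCUM", meaning = "HU"),
  mL = list(value = "mL", scheme = "UCUM", meaning = "mL")
)

.sr_num_item <- function(cde) {
  unit <- .UNIT_CODES[[cde$units]] %||%
    list(value = "1", scheme = "UCUM", meaning = cde$units)
  measured <- c(
    el_code_sq(0x0040, 0x08EA, unit$value, unit$scheme, unit$meaning),
    el_ds(0x0040, 0xA30A, cde$value)
  )
  c(
    el_str(0x0040, 0xA010, "CS", "CONTAINS"),
    el_str(0x0040, 0xA040, "CS", "NUM"),
    el_code_sq(0x0040, 0xA043, cde$code, "RADELEMENT", cde$meaning),
    el_sq(0x0040, 0xA300, list(measured))
  )
}

.sr_code_item <- function(cde) {
  state <- if (isTRUE(cde$value)) "present" else "absent"
  c(
    el_str(0x0040, 0xA010, "CS", "CONTAINS"),
    el_str(0x0040, 0xA040, "CS", "CODE"),
    el_code_sq(0x0040, 0xA043, cde$code, "RADELEMENT", cde$meaning),
    el_code_sq(0x0040, 0xA168, state, "99HSCRN",
               paste("Hepatic steatosis", state))
  )
}

#' Write a measurement structured report for one study
#'
#' Numeric CDEs become NUM content items (value + units code); the steatosis
#' flag becomes a CODE item. The SR shares the source study UID (so it
#' groups with the study) and lists the source series/instances as evidence.
#'
#' @param cdes A [build_cde_set()] result (nonempty).
#' @param study_refs List of [instance_meta()] from the analyzed series (the
#'   first supplies study/series UIDs; all are referenced as evidence).
#' @param path Output file path.
#' @return Invisibly, a list with `path`, `sop_uid`, `series_uid`.
#' @export
build_sr <- function(cdes, study_refs, path) {
  if (length(cdes) == 0L) hs_abort("empty CDE set", "hepascreen_cde_error")
  src <- study_refs[[1]]
  sop_uid <- dicom_uid(); series_uid <- dicom_uid()

  items <- lapply(unname(cdes), function(cde) {
    if (is.logical(cde$value)) .sr_code_item(cde) else .sr_num_item(cde)
  })

  ref_sops <- lapply(study_refs, function(m) {
    c(el_str(0x0008, 0x1150, "UI", UID_CT_IMAGE_STORAGE),
      el_str(0x0008, 0x1155, "UI", m$sop_uid))
  })
  series_item <- c(el_sq(0x0008, 0x1199, ref_sops),
                   el_str(0x0020, 0x000E, "UI", src$series_uid))
  evidence_item <- c(el_sq(0x0008, 0x1115, list(series_item)),
                     el_str(0x0020, 0x000D, "UI", src$study_uid))

  dataset <- c(
    el_str(0x0008, 0x0016, "UI", UID_COMPREHENSIVE_SR),
    el_str(0x0008, 0x0018, "UI", sop_uid),
    el_str(0x0008, 0x0020, "DA", format(Sys.Date(), "%Y%m%d")),
    el_str(0x0008, 0x0023, "DA", format(Sys.Date(), "%Y%m%d")),
    el_str(0x0008, 0x0033, "TM", format(Sys.time(), "%H%M%S")),
    el_str(0x0008, 0x0060, "CS", "SR"),
    el_str(0x0008, 0x0070, "LO", "hepascreen"),
    el_str(0x0010, 0x0010, "PN", "PHANTOM^CT"),
    el_str(0x0010, 0x0020, "LO", "HS-PHANTOM"),
    el_str(0x0020, 0x000D, "UI", src$study_uid),
    el_str(0x0020, 0x000E, "UI", series_uid),
    el_str(0x0020, 0x0010, "SH", "1"),
    el_is(0x0020, 0x0011, 9002L),
    el_is(0x0020, 0x0013, 1L),
    el_str(0x0040, 0xA040, "CS", "CONTAINER"),
    el_code_sq(0x0040, 0xA043, "126000", "DCM", "Imaging Measurement Report"),
    el_str(0x0040, 0xA050, "CS", "SEPARATE"),
    el_sq(0x0040, 0xA375, list(evidence_item)),
    el_str(0x0040, 0xA491, "CS", "COMPLETE"),
    el_str(0x0040, 0xA493, "CS", "UNVERIFIED"),
    el_sq(0x0040, 0xA730, items)
  )
  write_part10(path, UID_COMPREHENSIVE_SR, sop_uid, dataset)
  invisible(list(path = path, sop_uid = sop_uid, series_uid = series_uid))
}

#' Read back the content items of a structured report
#'
#' @param path Path to an SR file written by [build_sr()].
#' @return A list: `study_uid`, `sop_uid`, and `items`, a data frame with
#'   columns `code`, `meaning`, `type`, `value` (numeric, `NA` for CODE
#'   items), `state` (character, `NA` for NUM items) and `units`.
#' @export
read_sr <- function(path) {
  ds <- read_dicom_file(path)
  if (!identical(dcm_get(ds, "0008,0016"), UID_COMPREHENSIVE_SR)) {
    hs_parse_error(sprintf("'%s' is not a structured report", path), path)
  }
  content <- dcm_get(ds, "0040,A730", list())
  rows <- lapply(content, function(item) {
    name <- item[["0040,A043"]]$value[[1]]
    type <- item[["0040,A040"]]$value
    code <- name[["0008,0100"]]$value
    meaning <- name[["0008,0104"]]$value
    if (identical(type, "NUM")) {
      mv <- item[["0040,A300"]]$value[[1]]
      unit <- mv[["0040,08EA"]]$value[[1]]
      data.frame(code = code, meaning = meaning, type = "NUM",
                 value = mv[["0040,A30A"]]$value,
                 state = NA_character_,
                 units = unit[["0008,0104"]]$value,
                 stringsAsFactors = FALSE)
    } else {
      cc <- item[["0040,A168"]]$value[[1]]
      data.frame(code = code, meaning = meaning, type = "CODE",
                 value = NA_real_, state = cc[["0008,0100"]]$value,
                 units = NA_character_, stringsAsFactors = FALSE)
    }
  })
  list(study_uid = dcm_get(ds, "0020,000D"),
       sop_uid = dcm_get(ds, "0008,0018"),
       items = do.call(rbind, rows))
}
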