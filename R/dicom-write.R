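# Minimal DICOM Part-10 writer, uncompressed explicit-VR little endian.
#
# Scope: exactly the IOD subset this pipeline emits (CT Image Storage,
# Secondary Capture RGB, Comprehensive SR). Elements are assembled as raw
# vectors in ascending tag order by the callers; sequences use defined
# lengths throughout so files are byte-deterministic.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_CT_IMAGE_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
UID_COMPREHENSIVE_SR <- "1.2.840.10008.5.1.4.1.1.88.33"

# Unregistered-style numeric root kept constant so all UIDs the package mints
# are recognizable; uniqueness comes from the RNG draw plus a session counter.
HS_UID_ROOT <- "1.2.826.0.1.3680043.10.1457"

.hs_state <- new.env(parent = emptyenv())
.hs_state$uid_counter <- 0L

#' Mint a DICOM unique identifier
#'
#' UIDs are drawn from the package's numeric root. The random component comes
#' from R's RNG, so seeded pipelines mint reproducible identifiers; a session
#' counter guarantees uniqueness within a process even at a fixed seed.
#'
#' @return A single UID string (<= 64 characters).
#' @export
dicom_uid <- function() {
  .hs_state$uid_counter <- .hs_state$uid_counter + 1L
  sprintf("%s.%d.%d", HS_UID_ROOT,
          sample.int(.Machine$integer.max, 1L),
          .hs_state$uid_counter)
}

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32le <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(.u16le(lo), .u16le(hi))
}

.tag_raw <- function(group, elem) c(.u16le(group), .u16le(elem))

# VRs that use the 12-byte (reserved + 32-bit length) header form.
.LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

.encode_element <- function(group, elem, vr, bytes) {
  n <- length(bytes)
  if (n %% 2L != 0L) stop("internal: odd element length for VR ", vr)
  if (vr %in% .LONG_VRS) {
    c(.tag_raw(group, elem), charToRaw(vr), as.raw(c(0, 0)), .u32le(n), bytes)
  } else {
    if (n > 65534) stop("internal: value too long for short-form VR ", vr)
    c(.tag_raw(group, elem), charToRaw(vr), .u16le(n), bytes)
  }
}

.pad_bytes <- function(bytes, pad) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# String-family element; multi-valued inputs joined with backslash.
el_str <- function(group, elem, vr, values) {
  s <- paste(as.character(values), collapse = "\\")
  pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
  .encode_element(group, elem, vr, .pad_bytes(charToRaw(s), pad))
}

# Decimal string with DICOM's 16-byte-per-value limit.
el_ds <- function(group, elem, values) {
  s <- vapply(values, function(v) {
    out <- sprintf("%.10g", v)
    if (nchar(out) > 16L) out <- sprintf("%.8g", v)
    out
  }, character(1))
  el_str(group, elem, "DS", s)
}

el_is <- function(group, elem, values) el_str(group, elem, "IS", sprintf("%d", as.integer(values)))

el_us <- function(group, elem, values) {
  .encode_element(group, elem, "US", unlist(lapply(values, .u16le)))
}

el_ul <- function(group, elem, values) {
  .encode_element(group, elem, "UL", unlist(lapply(values, .u32le)))
}

el_ob <- function(group, elem, bytes) {
  .encode_element(group, elem, "OB", .pad_bytes(bytes, as.raw(0L)))
}

el_ow <- function(group, elem, bytes) .encode_element(group, elem, "OW", bytes)

# Sequence with defined lengths; items are raw datasets already in tag order.
el_sq <- function(group, elem, items) {
  body <- raw(0)
  for (it in items) {
    body <- c(body, .tag_raw(0xFFFE, 0xE000), .u32le(length(it)), it)
  }
  .encode_element(group, elem, "SQ", body)
}

# One-item code sequence (value, scheme, meaning) -- the workhorse for
# procedure codes, SR concept names and units.
el_code_sq <- function(group, elem, code_value, scheme, meaning) {
  item <- c(
    el_str(0x0008, 0x0100, "SH", code_value),
    el_str(0x0008, 0x0102, "SH", scheme),
    el_str(0x0008, 0x0104, "LO", meaning)
  )
  el_sq(group, elem, list(item))
}

# Part-10 envelope: 128-byte preamble, "DICM", group-0002 file meta
# (always explicit little endian), then the dataset bytes.
write_part10 <- function(path, sop_class_uid, sop_instance_uid, dataset_bytes) {
  meta_body <- c(
    el_ob(0x0002, 0x0001, as.raw(c(0L, 1L))),
    el_str(0x0002, 0x0002, "UI", sop_class_uid),
    el_str(0x0002, 0x0003, "UI", sop_instance_uid),
    el_str(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
    el_str(0x0002, 0x0012, "UI", paste0(HS_UID_ROOT, ".1.1")),
    el_str(0x0002, 0x0013, "SH", "HEPASCREEN")
  )
  meta <- c(el_ul(0x0002, 0x0000, length(meta_body)), meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset_bytes), con)
  invisible(path)
}
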