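# DICOM Part-10 parser for uncompressed explicit-VR little endian datasets.
# Returns a flat named list keyed "GGGG,EEEE"; each element is
# list(vr, value) with the value decoded per VR (SQ recurses into item
# datasets). Defined and undefined sequence/item lengths are both accepted.

.rd_u16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}

.rd_u32 <- function(buf, pos) {
  .rd_u16(buf, pos) + 65536 * .rd_u16(buf, pos + 2L)
}

.tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

.STRING_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST",
                 "TM", "UC", "UI", "UR", "UT")

.bytes_to_string <- function(bytes) {
  nz <- which(bytes != as.raw(0L))          # strip NUL padding before rawToChar
  if (length(nz) == 0L) return("")
  sub(" +$", "", rawToChar(bytes[seq_len(max(nz))]))
}

.decode_value <- function(vr, bytes) {
  if (vr %in% .STRING_VRS) {
    s <- .bytes_to_string(bytes)
    if (vr %in% c("LT", "ST", "UT")) return(s)       # no multiplicity
    return(strsplit(s, "\\", fixed = TRUE)[[1]])
  }
  switch(vr,
    DS = , IS = {
      s <- .bytes_to_string(bytes)
      if (!nzchar(s)) return(numeric(0))
      as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
    },
    US = readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    SS = readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                 signed = TRUE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    SL = readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    FL = readBin(bytes, "double", n = length(bytes) / 4L, size = 4L,
                 endian = "little"),
    FD = readBin(bytes, "double", n = length(bytes) / 8L, size = 8L,
                 endian = "little"),
    bytes  # OB/OW/UN and anything else stays raw
  )
}

# Parse one explicit-VR dataset region [pos, end]; returns list(elements, pos).
.parse_dataset <- function(buf, pos, end, path) {
  out <- list()
  while (pos <= end) {
    if (pos + 7L > length(buf) + 1L) {
      hs_parse_error(sprintf("truncated DICOM element in '%s'", path), path)
    }
    group <- .rd_u16(buf, pos); elem <- .rd_u16(buf, pos + 2L)
    if (group == 0xFFFE && elem == 0xE00D) {       # item delimiter
      return(list(elements = out, pos = pos + 8L, delimited = TRUE))
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- .rd_u32(buf, pos + 8L); pos <- pos + 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- .rd_u16(buf, pos + 6L); pos <- pos + 8L
    } else {
      hs_parse_error(sprintf(
        "unsupported (implicit-VR or corrupt) element at byte %d in '%s'",
        pos, path), path)
    }
    key <- .tag_key(group, elem)
    if (vr == "SQ") {
      sq_end <- if (len == 0xFFFFFFFF) length(buf) else pos + len - 1L
      items <- list()
      while (pos <= sq_end) {
        ig <- .rd_u16(buf, pos); ie <- .rd_u16(buf, pos + 2L)
        ilen <- .rd_u32(buf, pos + 4L); pos <- pos + 8L
        if (ig == 0xFFFE && ie == 0xE0DD) break     # sequence delimiter
        if (!(ig == 0xFFFE && ie == 0xE000)) {
          hs_parse_error(sprintf("malformed sequence item in '%s'", path), path)
        }
        item_end <- if (ilen == 0xFFFFFFFF) sq_end else pos + ilen - 1L
        res <- .parse_dataset(buf, pos, item_end, path)
        items[[length(items) + 1L]] <- res$elements
        pos <- res$pos
      }
      out[[key]] <- list(vr = "SQ", value = items)
    } else {
      if (len == 0xFFFFFFFF) {
        hs_parse_error(sprintf(
          "undefined-length non-sequence element (%s) in '%s'", key, path), path)
      }
      bytes <- if (len > 0L) buf[pos:(pos + len - 1L)] else raw(0)
      pos <- pos + len
      out[[key]] <- list(vr = vr, value = .decode_value(vr, bytes))
    }
  }
  list(elements = out, pos = pos, delimited = FALSE)
}

#' Parse a DICOM Part-10 file
#'
#' Low-level reader for uncompressed explicit-VR little-endian files (the only
#' transfer syntax this pipeline emits or accepts). Compressed or implicit-VR
#' files are rejected with a parse error naming the path.
#'
#' @param path Path to a DICOM Part-10 file.
#' @return A list with components `meta` (file meta group elements) and
#'   `elements` (the dataset), both keyed by `"GGGG,EEEE"` tag strings.
#' @export
read_dicom_file <- function(path) {
  if (!file.exists(path)) hs_parse_error(sprintf("no such file: '%s'", path), path)
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM") {
    hs_parse_error(sprintf("'%s' is not a DICOM Part-10 file", path), path)
  }
  res <- .parse_dataset(buf, 133L, length(buf), path)
  meta_keys <- grepl("^0002,", names(res$elements))
  meta <- res$elements[meta_keys]
  elements <- res$elements[!meta_keys]
  ts <- meta[["0002,0010"]]$value
  if (!is.null(ts) && !identical(ts, UID_EXPLICIT_VR_LE)) {
    hs_parse_error(sprintf(
      "unsupported transfer syntax '%s' in '%s' (only explicit-VR little endian)",
      ts, path), path)
  }
  list(meta = meta, elements = elements)
}

# Convenience accessor: decoded value of tag "GGGG,EEEE" or default.
dcm_get <- function(ds, key, default = NULL) {
  el <- ds$elements[[key]]
  if (is.null(el)) default else el$value
}
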