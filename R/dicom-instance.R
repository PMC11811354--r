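# Instance-level I/O: single-frame CT read, CT phantom write, RGB secondary
# capture write. The unit of exchange is an "instance": metadata plus one
# stored pixel plane. Rescale to HU is deferred to series assembly so the
# stored integers survive round trips bit-exactly.

#' Instance metadata
#'
#' Geometry, rescale and procedure metadata extracted from one single-frame
#' CT (or derived secondary-capture) DICOM instance. Optional tags that are
#' absent in the file are reported as `NA` ("absent"), never silently
#' defaulted.
#'
#' @param study_uid,series_uid,sop_uid DICOM unique identifiers.
#' @param instance_number Integer instance number within the series.
#' @param image_position Length-3 numeric, mm (patient coordinates of the
#'   first transmitted voxel centre).
#' @param image_orientation Length-6 direction cosines (row then column).
#' @param pixel_spacing Length-2 numeric, mm (row spacing, column spacing).
#' @param slice_thickness Slice thickness, mm.
#' @param rescale_slope,rescale_intercept Affine map from stored values to HU.
#' @param rows,cols Plane dimensions in pixels.
#' @param modality Modality code string (e.g. `"CT"`).
#' @param procedure_code CPT procedure code string, or `NA` if absent.
#' @param contrast_agent Contrast agent tag value; `NA` when the tag is
#'   absent, possibly `""` when present but empty.
#' @param series_number Integer series number, or `NA`.
#' @param received_at Receipt timestamp (`POSIXct`).
#' @return An object of class `instance_meta`.
#' @export
instance_meta <- function(study_uid, series_uid, sop_uid, instance_number,
                          image_position, image_orientation, pixel_spacing,
                          slice_thickness, rescale_slope, rescale_intercept,
                          rows, cols, modality = "CT",
                          procedure_code = NA_character_,
                          contrast_agent = NA_character_,
                          series_number = NA_integer_,
                          received_at = Sys.time()) {
  r <- image_orientation[1:3]; c_ <- image_orientation[4:6]
  if (abs(sum(r^2) - 1) > 1e-3 || abs(sum(c_^2) - 1) > 1e-3 ||
      abs(sum(r * c_)) > 1e-3) {
    hs_ineligible_instance(
      "image orientation cosines are not two orthogonal unit vectors")
  }
  if (any(pixel_spacing <= 0)) hs_ineligible_instance("pixel spacing must be > 0")
  if (!is.na(slice_thickness) && slice_thickness <= 0) {
    hs_ineligible_instance("slice thickness must be > 0")
  }
  structure(list(
    study_uid = study_uid, series_uid = series_uid, sop_uid = sop_uid,
    instance_number = as.integer(instance_number),
    image_position = as.numeric(image_position),
    image_orientation = as.numeric(image_orientation),
    pixel_spacing = as.numeric(pixel_spacing),
    slice_thickness = as.numeric(slice_thickness),
    rescale_slope = rescale_slope, rescale_intercept = rescale_intercept,
    rows = as.integer(rows), cols = as.integer(cols),
    modality = modality, procedure_code = procedure_code,
    contrast_agent = contrast_agent,
    series_number = as.integer(series_number),
    received_at = received_at
  ), class = "instance_meta")
}

#' @export
print.instance_meta <- function(x, ...) {
  cat(sprintf("<instance %s> series %s #%d %dx%d px, thickness %s mm\n",
              substr(x$sop_uid, nchar(x$sop_uid) - 11L, nchar(x$sop_uid)),
              substr(x$series_uid, nchar(x$series_uid) - 11L, nchar(x$series_uid)),
              x$instance_number, x$rows, x$cols,
              format(x$slice_thickness)))
  invisible(x)
}

.slice_normal <- function(orient) {
  r <- orient[1:3]; c_ <- orient[4:6]
  c(r[2] * c_[3] - r[3] * c_[2],
    r[3] * c_[1] - r[1] * c_[3],
    r[1] * c_[2] - r[2] * c_[1])
}

#' Read a single-frame CT DICOM instance
#'
#' Parses one Part-10 file and extracts the metadata the pipeline routes on,
#' plus the stored pixel plane (rescale to HU is applied later, at series
#' assembly). Enhanced multi-frame objects and instances missing geometry
#' tags are rejected with an "ineligible instance" error; unparsable files
#' raise a parse error naming the path.
#'
#' @param path Path to a DICOM file.
#' @return A list with components `meta` (an [instance_meta()]) and `plane`
#'   (a rows x cols matrix of stored values, or an rows x cols x 3 array for
#'   RGB secondary captures).
#' @export
read_instance <- function(path) {
  ds <- read_dicom_file(path)
  g <- function(key, default = NULL) dcm_get(ds, key, default)

  nframes <- g("0028,0008")
  if (!is.null(nframes) && as.integer(nframes[1]) > 1L) {
    hs_ineligible_instance(sprintf(
      "'%s': enhanced multi-frame objects are not supported", path), path)
  }

  pos <- g("0020,0032"); orient <- g("0020,0037")
  spacing <- g("0028,0030"); thick <- g("0018,0050")
  rows <- g("0028,0010"); cols <- g("0028,0011")
  if (is.null(pos) || is.null(orient) || is.null(spacing) ||
      is.null(rows) || is.null(cols)) {
    hs_ineligible_instance(sprintf(
      "'%s': missing geometry tags required for series assembly", path), path)
  }

  # Procedure code lives in the first item of the procedure code sequence.
  proc_sq <- g("0008,1032")
  proc_code <- NA_character_
  if (!is.null(proc_sq) && length(proc_sq) >= 1L) {
    cv <- proc_sq[[1]][["0008,0100"]]$value
    if (!is.null(cv)) proc_code <- cv
  }

  contrast <- g("0018,0010")
  contrast <- if (is.null(contrast)) NA_character_ else
    if (length(contrast) == 0L) "" else contrast[1]

  slope <- g("0028,1053"); intercept <- g("0028,1052")
  samples <- g("0028,0002", 1L)

  meta <- instance_meta(
    study_uid = g("0020,000D"), series_uid = g("0020,000E"),
    sop_uid = g("0008,0018"),
    instance_number = g("0020,0013", NA_integer_),
    image_position = pos, image_orientation = orient,
    pixel_spacing = spacing,
    slice_thickness = if (is.null(thick)) NA_real_ else thick,
    rescale_slope = if (is.null(slope)) NA_real_ else slope,
    rescale_intercept = if (is.null(intercept)) NA_real_ else intercept,
    rows = rows, cols = cols,
    modality = g("0008,0060", NA_character_),
    procedure_code = proc_code, contrast_agent = contrast,
    series_number = g("0020,0011", NA_integer_),
    received_at = file.mtime(path)
  )

  px <- ds$elements[["7FE0,0010"]]
  if (is.null(px)) hs_ineligible_instance(sprintf("'%s': no pixel data", path), path)
  if (samples == 3L) {
    v <- as.integer(px$value)                     # OB bytes, interleaved RGB
    plane <- aperm(array(v, dim = c(3L, cols, rows)), c(3L, 2L, 1L))
  } else {
    v <- readBin(px$value, "integer", n = rows * cols, size = 2L,
                 signed = FALSE, endian = "little")
    plane <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  }
  list(meta = meta, plane = plane)
}

# Shared dataset prefix for image objects, in ascending tag order.
.image_dataset_head <- function(sop_class, sop_uid, meta, image_type,
                                series_desc, source_refs = NULL,
                                procedure_code = NULL, contrast_agent = NULL) {
  out <- c(
    el_str(0x0008, 0x0008, "CS", image_type),
    el_str(0x0008, 0x0016, "UI", sop_class),
    el_str(0x0008, 0x0018, "UI", sop_uid),
    el_str(0x0008, 0x0020, "DA", format(Sys.Date(), "%Y%m%d")),
    el_str(0x0008, 0x0060, "CS", meta$modality),
    el_str(0x0008, 0x0070, "LO", "hepascreen"),
    el_str(0x0008, 0x103E, "LO", series_desc)
  )
  if (!is.null(procedure_code) && !is.na(procedure_code)) {
    out <- c(out, el_code_sq(0x0008, 0x1032, procedure_code, "C4",
                             "CT procedure"))
  }
  if (!is.null(source_refs) && length(source_refs) > 0L) {
    items <- lapply(source_refs, function(ref) {
      c(el_str(0x0008, 0x1150, "UI", UID_CT_IMAGE_STORAGE),
        el_str(0x0008, 0x1155, "UI", ref$sop_uid))
    })
    out <- c(out,
             el_str(0x0008, 0x2111, "ST", "AI organ segmentation QC overlay"),
             el_sq(0x0008, 0x2112, items))
  }
  out <- c(out,
    el_str(0x0010, 0x0010, "PN", "PHANTOM^CT"),
    el_str(0x0010, 0x0020, "LO", "HS-PHANTOM")
  )
  if (!is.null(contrast_agent) && !is.na(contrast_agent)) {
    out <- c(out, el_str(0x0018, 0x0010, "LO", contrast_agent))
  }
  c(out,
    el_ds(0x0018, 0x0050, meta$slice_thickness),
    el_str(0x0020, 0x000D, "UI", meta$study_uid),
    el_str(0x0020, 0x000E, "UI", meta$series_uid),
    el_str(0x0020, 0x0010, "SH", "1"),
    el_is(0x0020, 0x0011, meta$series_number),
    el_is(0x0020, 0x0013, meta$instance_number),
    el_ds(0x0020, 0x0032, meta$image_position),
    el_ds(0x0020, 0x0037, meta$image_orientation)
  )
}

#' Write one single-frame CT instance
#'
#' Stored values are 16-bit unsigned with the rescale map recorded in the
#' header; callers pass stored integers (HU conversion is the reader's job).
#'
#' @param path Output file path.
#' @param meta An [instance_meta()] describing the slice.
#' @param stored Matrix (rows x cols) of stored integer pixel values in
#'   `[0, 65535]`.
#' @return The path, invisibly.
#' @export
write_ct_instance <- function(path, meta, stored) {
  if (!all(dim(stored) == c(meta$rows, meta$cols))) {
    hs_abort("pixel plane does not match Rows/Columns", "hepascreen_write_error")
  }
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")
  dataset <- c(
    .image_dataset_head(UID_CT_IMAGE_STORAGE, meta$sop_uid, meta,
                        c("ORIGINAL", "PRIMARY", "AXIAL"),
                        "Synthetic abdominal CT",
                        procedure_code = meta$procedure_code,
                        contrast_agent = meta$contrast_agent),
    el_us(0x0028, 0x0002, 1L),
    el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el_us(0x0028, 0x0010, meta$rows),
    el_us(0x0028, 0x0011, meta$cols),
    el_ds(0x0028, 0x0030, meta$pixel_spacing),
    el_us(0x0028, 0x0100, 16L),
    el_us(0x0028, 0x0101, 16L),
    el_us(0x0028, 0x0102, 15L),
    el_us(0x0028, 0x0103, 0L),
    el_ds(0x0028, 0x1052, meta$rescale_intercept),
    el_ds(0x0028, 0x1053, meta$rescale_slope),
    el_ow(0x7FE0, 0x0010, pix)
  )
  write_part10(path, UID_CT_IMAGE_STORAGE, meta$sop_uid, dataset)
}

#' Write a QC overlay as a DICOM secondary-capture series
#'
#' One RGB secondary-capture instance is written per source slice, under a
#' freshly minted series UID but the *same* study UID as the source series,
#' so a PACS-style viewer groups the overlay with the original study. Each
#' derived instance references its source SOP instance.
#'
#' @param stack A [series_stack()] (geometry source).
#' @param rgb_planes List of rows x cols x 3 arrays of 8-bit values, one per
#'   source slice.
#' @param source_refs List of [instance_meta()] for the source slices (same
#'   length and order as `rgb_planes`).
#' @param out_dir Directory to write into (created if needed).
#' @param series_description Series description string marking the series as
#'   AI-derived QC.
#' @return Character vector of written file paths (class `sc_series`), with
#'   the new series UID as attribute `series_uid`.
#' @export
write_secondary_capture <- function(stack, rgb_planes, source_refs, out_dir,
                                    series_description = "AI QC: liver/spleen overlay") {
  if (length(source_refs) == 0L) {
    hs_abort("source_refs is empty: a derived series needs source instances",
             "hepascreen_write_error")
  }
  if (length(rgb_planes) != length(source_refs)) {
    hs_abort(sprintf("got %d RGB planes for %d source slices",
                     length(rgb_planes), length(source_refs)),
             "hepascreen_write_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  series_uid <- dicom_uid()
  paths <- character(length(rgb_planes))
  for (i in seq_along(rgb_planes)) {
    src <- source_refs[[i]]
    sop_uid <- dicom_uid()
    meta <- instance_meta(
      study_uid = src$study_uid, series_uid = series_uid, sop_uid = sop_uid,
      instance_number = i,
      image_position = src$image_position,
      image_orientation = src$image_orientation,
      pixel_spacing = src$pixel_spacing,
      slice_thickness = src$slice_thickness,
      rescale_slope = NA_real_, rescale_intercept = NA_real_,
      rows = src$rows, cols = src$cols, modality = "OT",
      series_number = 9001L
    )
    plane <- rgb_planes[[i]]
    if (!all(dim(plane) == c(src$rows, src$cols, 3L))) {
      hs_abort("RGB plane does not match source slice dimensions",
               "hepascreen_write_error")
    }
    # Interleaved RGB, row-major: channel fastest, then column, then row.
    pix <- as.raw(as.integer(aperm(plane, c(3L, 2L, 1L))))
    dataset <- c(
      .image_dataset_head(UID_SECONDARY_CAPTURE, sop_uid, meta,
                          c("DERIVED", "SECONDARY"), series_description,
                          source_refs = list(src)),
      el_us(0x0028, 0x0002, 3L),
      el_str(0x0028, 0x0004, "CS", "RGB"),
      el_us(0x0028, 0x0006, 0L),
      el_us(0x0028, 0x0010, meta$rows),
      el_us(0x0028, 0x0011, meta$cols),
      el_ds(0x0028, 0x0030, meta$pixel_spacing),
      el_us(0x0028, 0x0100, 8L),
      el_us(0x0028, 0x0101, 8L),
      el_us(0x0028, 0x0102, 7L),
      el_us(0x0028, 0x0103, 0L),
      el_ob(0x7FE0, 0x0010, pix)
    )
    paths[i] <- file.path(out_dir, paste0(sop_uid, ".dcm"))
    write_part10(paths[i], UID_SECONDARY_CAPTURE, sop_uid, dataset)
  }
  structure(paths, series_uid = series_uid, class = "sc_series")
}
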