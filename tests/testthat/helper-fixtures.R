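# Shared fixtures, built in code: in-memory stacks, tiny instances, synthetic
# event logs. No binary fixtures on disk.

axial_cosines <- c(1, 0, 0, 0, 1, 0)
coronal_cosines <- c(1, 0, 0, 0, 0, -1)

mk_meta <- function(i, study_uid = "1.2.3", series_uid = "1.2.3.4",
                    z = (i - 1) * 3, thickness = 3,
                    orientation = axial_cosines,
                    pixel_spacing = c(1.5, 1.5), rows = 64, cols = 64,
                    cpt = "74176", contrast = NA_character_,
                    series_number = 1L, slope = 1, intercept = -1024) {
  pos <- if (identical(orientation, axial_cosines)) c(0, 0, z) else c(0, z, 0)
  instance_meta(
    study_uid = study_uid, series_uid = series_uid,
    sop_uid = paste0(series_uid, ".", i), instance_number = i,
    image_position = pos, image_orientation = orientation,
    pixel_spacing = pixel_spacing, slice_thickness = thickness,
    rescale_slope = slope, rescale_intercept = intercept,
    rows = rows, cols = cols, procedure_code = cpt,
    contrast_agent = contrast, series_number = series_number
  )
}

# Build a series_stack directly from an HU volume (slice, row, col).
mk_stack <- function(vox, spacing = c(1.5, 1.5, 3),
                     thickness = rep(spacing[3], dim(vox)[1]), ...) {
  n <- dim(vox)[1]
  metas <- lapply(seq_len(n), function(i) {
    mk_meta(i, z = (i - 1) * spacing[3], thickness = thickness[i],
            rows = dim(vox)[2], cols = dim(vox)[3],
            pixel_spacing = spacing[1:2], ...)
  })
  series_stack(metas, vox, spacing, thickness)
}

# In-memory phantom: stack plus ground truth, no disk round trip.
phantom_stack <- function(config) {
  pv <- phantom_volume(config)
  list(stack = mk_stack(pv$voxels, spacing = config$spacing,
                        cpt = config$procedure_code,
                        contrast = if (is.null(config$contrast_agent))
                          NA_character_ else config$contrast_agent),
       truth = pv$truth)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Fabricate a steatosis_result for CDE-layer tests.
mk_result <- function(liver, spleen, volume = 100, present = NULL) {
  shad <- spleen - liver
  structure(list(
    liver_mean_hu = liver, spleen_mean_hu = spleen,
    liver_minus_spleen_hu = -shad, shad = shad,
    liver_volume_ml = volume,
    steatosis_present = present %||% classify_steatosis(liver, shad),
    voxel_counts = c(liver = 10L, spleen = 5L)
  ), class = "steatosis_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic per-study event log written through the public logging API.
log_study <- function(config, uid, receipts, routing = NULL, algo = NULL,
                      exports = NULL) {
  for (i in seq_along(receipts)) {
    log_event(config, uid, "INSTANCE_RECEIVED", paste0("i", i),
              time = as.POSIXct(receipts[i], origin = "1970-01-01"))
  }
  if (!is.null(routing)) {
    log_event(config, uid, "ROUTING_DONE",
              jsonlite::toJSON(routing, auto_unbox = TRUE, null = "null"))
  }
  if (!is.null(algo)) {
    log_event(config, uid, "ALGO_START", "",
              time = as.POSIXct(algo[1], origin = "1970-01-01"))
    if (length(algo) > 1L) {
      log_event(config, uid, "ALGO_END", "",
                time = as.POSIXct(algo[2], origin = "1970-01-01"))
    }
  }
  if (!is.null(exports)) {
    log_event(config, uid, "EXPORT_PACS_DONE", "",
              time = as.POSIXct(exports[1], origin = "1970-01-01"))
    if (length(exports) > 1L) {
      log_event(config, uid, "EXPORT_REPORT_DONE", "",
                time = as.POSIXct(exports[2], origin = "1970-01-01"))
    }
  }
  invisible(uid)
}
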