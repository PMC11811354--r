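# Series assembly: order single-frame instances along the slice normal and
# stack them into one HU volume with derived geometry.

#' Assembled CT series stack
#'
#' @param meta List of [instance_meta()], sorted along the slice normal.
#' @param voxels 3-D array of HU values, dimension (n_slices, rows, cols).
#' @param spacing Length-3 numeric, mm: row spacing, column spacing,
#'   inter-slice spacing (derived from positions, not the thickness tag).
#' @param slice_thickness_set Sorted distinct slice-thickness tag values, mm.
#' @return An object of class `series_stack`.
#' @export
series_stack <- function(meta, voxels, spacing, slice_thickness_set) {
  stopifnot(length(dim(voxels)) == 3L, dim(voxels)[1] == length(meta))
  structure(list(
    meta = meta, voxels = voxels, spacing = as.numeric(spacing),
    slice_thickness_set = sort(unique(as.numeric(slice_thickness_set))),
    study_uid = meta[[1]]$study_uid, series_uid = meta[[1]]$series_uid
  ), class = "series_stack")
}

#' @export
print.series_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<series_stack> %d slices x %d x %d, spacing %s mm, thickness {%s} mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              paste(x$slice_thickness_set, collapse = ", ")))
  invisible(x)
}

#' Assemble instances into a geometrically ordered HU volume
#'
#' Slices are sorted by their position projected onto the slice normal (the
#' cross product of the row and column direction cosines), so the result is
#' independent of the order instances arrived in. Stored values are converted
#' to HU here via `stored * rescale_slope + rescale_intercept`. Inter-slice
#' spacing comes from consecutive projected positions; the slice-thickness
#' *tag* values are collected separately because routing checks the tag.
#'
#' @param instances List of `list(meta=, plane=)` as returned by
#'   [read_instance()]. All must share a series UID and plane geometry;
#'   at least two slices are required.
#' @return A [series_stack()].
#' @export
assemble_series <- function(instances) {
  if (length(instances) < 2L) {
    hs_abort("a series needs at least 2 slices to assemble",
             "hepascreen_assembly_error")
  }
  metas <- lapply(instances, `[[`, "meta")
  suid <- unique(vapply(metas, `[[`, "", "series_uid"))
  if (length(suid) != 1L) {
    hs_abort("instances span multiple series UIDs", "hepascreen_assembly_error")
  }
  rows <- vapply(metas, `[[`, 0L, "rows"); cols <- vapply(metas, `[[`, 0L, "cols")
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L) {
    hs_abort("mixed Rows/Columns within one series", "hepascreen_assembly_error")
  }
  ps <- vapply(metas, function(m) paste(format(m$pixel_spacing), collapse = ","), "")
  if (length(unique(ps)) != 1L) {
    hs_abort("mixed pixel spacing within one series", "hepascreen_assembly_error")
  }

  normal <- .slice_normal(metas[[1]]$image_orientation)
  proj <- vapply(metas, function(m) sum(m$image_position * normal), 0)
  if (anyDuplicated(signif(proj, 10))) {
    hs_abort("duplicate slice positions along the normal",
             "hepascreen_assembly_error")
  }
  ord <- order(proj)
  metas <- metas[ord]; instances <- instances[ord]; proj <- proj[ord]

  n <- length(instances)
  vox <- array(NA_real_, dim = c(n, rows[1], cols[1]))
  for (i in seq_len(n)) {
    m <- metas[[i]]
    slope <- if (is.na(m$rescale_slope)) 1 else m$rescale_slope
    intercept <- if (is.na(m$rescale_intercept)) 0 else m$rescale_intercept
    vox[i, , ] <- instances[[i]]$plane * slope + intercept
  }
  dz <- if (n > 1L) mean(diff(proj)) else metas[[1]]$slice_thickness
  series_stack(
    meta = metas, voxels = vox,
    spacing = c(metas[[1]]$pixel_spacing, dz),
    slice_thickness_set = vapply(metas, `[[`, 0, "slice_thickness")
  )
}
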