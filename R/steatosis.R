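# Hepatic steatosis assessment: organ mean attenuation, the spleen-hepatic
# attenuation difference (SHAD), hepatic volume, and the radiologic
# determinant for moderate-to-severe steatosis.

#' Steatosis analysis configuration
#'
#' The radiologic determinant flags steatosis when mean hepatic attenuation
#' falls below `liver_hu_threshold` (default 40 HU) *or* SHAD exceeds
#' `shad_threshold` (default 10 HU); both comparisons are strict. The two
#' printed forms of the rule — `SHAD > 10` and `liver - spleen < -10` — are
#' the same predicate.
#'
#' @param liver_hu_threshold HU threshold for mean hepatic attenuation.
#' @param shad_threshold HU threshold for SHAD (spleen minus liver).
#' @param hu_rounding Decimal places used when rendering HU into reports.
#' @return An object of class `steatosis_config`.
#' @export
steatosis_config <- function(liver_hu_threshold = 40, shad_threshold = 10,
                             hu_rounding = 0L) {
  stopifnot(is.finite(liver_hu_threshold), is.finite(shad_threshold))
  structure(list(liver_hu_threshold = liver_hu_threshold,
                 shad_threshold = shad_threshold,
                 hu_rounding = as.integer(hu_rounding)),
            class = "steatosis_config")
}

#' Mean attenuation over a voxel mask
#'
#' Unweighted arithmetic mean of HU over in-mask voxels. (Uniform-thickness
#' routing makes volume weighting across slices a non-issue; the unweighted
#' choice is deliberate and documented.)
#'
#' @param stack A [series_stack()].
#' @param mask Logical array aligned to `stack$voxels`.
#' @return Mean HU (full precision; rounding happens at report rendering).
#' @export
mean_attenuation <- function(stack, mask) {
  if (!any(mask)) hs_abort("empty mask: no voxels to average",
                           "hepascreen_analysis_error")
  mean(stack$voxels[mask])
}

#' Organ volume from a voxel mask
#'
#' @param mask Logical voxel array.
#' @param spacing Length-3 voxel spacing, mm.
#' @return Volume in mL (`count * prod(spacing) / 1000`).
#' @export
organ_volume <- function(mask, spacing) {
  stopifnot(all(spacing > 0))
  sum(mask) * prod(spacing) / 1000
}

#' Spleen-hepatic attenuation difference (SHAD)
#'
#' @param liver_mean,spleen_mean Mean organ attenuations, HU.
#' @return `spleen_mean - liver_mean` (so fatty livers give positive SHAD).
#' @export
compute_shad <- function(liver_mean, spleen_mean) {
  stopifnot(is.finite(liver_mean), is.finite(spleen_mean))
  spleen_mean - liver_mean
}

#' Radiologic determinant for moderate-to-severe hepatic steatosis
#'
#' @param liver_mean Mean hepatic attenuation, HU.
#' @param shad SHAD, HU.
#' @param config A [steatosis_config()].
#' @return Logical: steatosis present.
#' @export
classify_steatosis <- function(liver_mean, shad, config = steatosis_config()) {
  stopifnot(is.finite(liver_mean), is.finite(shad))
  (liver_mean < config$liver_hu_threshold) | (shad > config$shad_threshold)
}

#' Run the steatosis stage on an assembled series
#'
#' Applies a segmenter (the phantom-grade fallback by default, or any
#' callable honouring the plug-in contract `stack -> list(liver=, spleen=)`),
#' then computes organ means, SHAD, hepatic volume and the steatosis flag.
#'
#' @param stack A [series_stack()].
#' @param segmenter A function `stack -> list(liver, spleen)` of logical
#'   voxel masks; defaults to [fallback_segment()].
#' @param config A [steatosis_config()].
#' @return A `steatosis_result`: `liver_mean_hu`, `spleen_mean_hu`,
#'   `liver_minus_spleen_hu`, `shad`, `liver_volume_ml`,
#'   `steatosis_present`, `voxel_counts` (named integer vector).
#' @export
analyze_steatosis <- function(stack, segmenter = fallback_segment,
                              config = steatosis_config()) {
  masks <- segmenter(stack)
  if (any(masks$liver & masks$spleen)) {
    hs_segmentation_failed("segmenter returned overlapping liver/spleen masks")
  }
  liver_mean <- mean_attenuation(stack, masks$liver)
  spleen_mean <- mean_attenuation(stack, masks$spleen)
  shad <- compute_shad(liver_mean, spleen_mean)
  structure(list(
    liver_mean_hu = liver_mean,
    spleen_mean_hu = spleen_mean,
    liver_minus_spleen_hu = -shad,
    shad = shad,
    liver_volume_ml = organ_volume(masks$liver, stack$spacing),
    steatosis_present = classify_steatosis(liver_mean, shad, config),
    voxel_counts = c(liver = sum(masks$liver), spleen = sum(masks$spleen)),
    masks = masks
  ), class = "steatosis_result")
}

#' @export
print.steatosis_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<steatosis_result>\n",
    "  liver mean:  %.1f HU (%d voxels, %.1f mL)\n",
    "  spleen mean: %.1f HU (%d voxels)\n",
    "  SHAD:        %.1f HU\n",
    "  steatosis:   %s\n"),
    x$liver_mean_hu, x$voxel_counts["liver"], x$liver_volume_ml,
    x$spleen_mean_hu, x$voxel_counts["spleen"], x$shad,
    if (x$steatosis_present) "present" else "absent"))
  invisible(x)
}
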