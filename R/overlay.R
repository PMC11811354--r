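# Quality-control overlay rendering: windowed CT slices with transparent
# colored organ masks, exported as a DICOM secondary-capture series for
# radiologist review in the PACS.

#' Overlay rendering style
#'
#' @param palette Named list organ -> RGB triple (0-255). Organs are blended
#'   in list order and *earlier* organs take precedence where masks overlap.
#' @param alpha Blend fraction in `[0, 1]` (1 = opaque color).
#' @param window_center,window_width CT display window, HU (default 40/400,
#'   the usual abdominal soft-tissue window).
#' @return An object of class `overlay_style`.
#' @export
overlay_style <- function(palette = list(liver = c(255, 0, 0),
                                         spleen = c(0, 0, 255),
                                         fat_visceral = c(255, 255, 0),
                                         fat_subcutaneous = c(0, 255, 0)),
                          alpha = 0.4, window_center = 40, window_width = 400) {
  stopifnot(alpha >= 0, alpha <= 1, window_width > 0)
  structure(list(palette = palette, alpha = alpha,
                 window_center = window_center, window_width = window_width),
            class = "overlay_style")
}

#' Window an HU plane to 8-bit grayscale
#'
#' Linear map of `[center - width/2, center + width/2]` onto `[0, 255]`,
#' clipped outside the window.
#'
#' @param plane Numeric matrix of HU values.
#' @param center,width Window center and width, HU (`width > 0`).
#' @return Integer matrix of 8-bit gray values.
#' @export
window_slice <- function(plane, center = 40, width = 400) {
  stopifnot(width > 0)
  g <- round((plane - (center - width / 2)) / width * 255)
  g[] <- pmin(pmax(g, 0), 255)
  storage.mode(g) <- "integer"
  g
}

#' Blend colored organ masks onto a grayscale plane
#'
#' Out-of-mask pixels replicate the gray value to all channels; in-mask
#' pixels become `(1 - alpha) * gray + alpha * color` per channel, rounded.
#' Where masks overlap, the first organ in the palette order wins (liver,
#' then spleen, then extras).
#'
#' @param gray Integer matrix of 8-bit gray values ([window_slice()] output).
#' @param masks Named list of logical matrices (same shape as `gray`); names
#'   must appear in `style$palette`.
#' @param style An [overlay_style()].
#' @return An rows x cols x 3 integer array of 8-bit RGB values.
#' @export
blend_overlay <- function(gray, masks, style = overlay_style()) {
  d <- dim(gray)
  rgb <- array(rep(gray, 3L), dim = c(d, 3L))
  organs <- intersect(names(style$palette), names(masks))
  # Apply in reverse precedence so earlier organs overwrite overlaps.
  for (organ in rev(organs)) {
    m <- masks[[organ]]
    if (is.null(m) || !any(m)) next
    stopifnot(all(dim(m) == d))
    col <- style$palette[[organ]]
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[m] <- round((1 - style$alpha) * gray[m] + style$alpha * col[ch])
      rgb[, , ch] <- plane
    }
  }
  storage.mode(rgb) <- "integer"
  rgb
}

#' Render and export the QC overlay series
#'
#' Windows every slice of the stack, blends the organ masks, and writes one
#' RGB secondary-capture instance per source slice under the source study
#' UID (via [write_secondary_capture()]), so the QC series appears alongside
#' the original study in a PACS-style viewer.
#'
#' @param stack A [series_stack()].
#' @param masks Named list of logical 3-D arrays aligned to `stack$voxels`
#'   (e.g. `list(liver=, spleen=)`).
#' @param style An [overlay_style()].
#' @param out_dir Output directory for the secondary-capture files.
#' @return The written file paths (class `sc_series`).
#' @export
render_qc_series <- function(stack, masks, style = overlay_style(), out_dir) {
  n <- dim(stack$voxels)[1]
  planes <- vector("list", n)
  for (i in seq_len(n)) {
    gray <- window_slice(stack$voxels[i, , ], style$window_center,
                         style$window_width)
    slice_masks <- lapply(masks, function(m) m[i, , ])
    planes[[i]] <- blend_overlay(gray, slice_masks, style)
  }
  write_secondary_capture(stack, planes, stack$meta, out_dir,
                          series_description = "AI QC: liver/spleen segmentation overlay")
}
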