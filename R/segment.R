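# Phantom-grade fallback segmentation. This is NOT a clinical segmenter: it
# exists so the pipeline runs end-to-end without the production deep-learning
# model, which plugs in behind the same contract (stack -> liver/spleen masks).

# 6-connected component labelling by minimum-label propagation using
# raster / anti-raster sweeps (blob-like components converge in a couple of
# passes; worst-case spirals take more but remain bounded).
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(Inf, dim = d)
  lab[mask] <- which(mask)
  sweep_dim <- function(lab, along, idx_seq, dir) {
    for (i in idx_seq) {
      prev <- i - dir
      cur <- switch(along, lab[i, , ], lab[, i, ], lab[, , i])
      nb <- switch(along, lab[prev, , ], lab[, prev, ], lab[, , prev])
      upd <- pmin(cur, nb)
      upd[!is.finite(cur)] <- Inf          # non-mask voxels never carry labels
      switch(along, lab[i, , ] <- upd, lab[, i, ] <- upd, lab[, , i] <- upd)
    }
    lab
  }
  repeat {
    old <- lab
    for (along in 1:3) {
      if (d[along] > 1L) {
        lab <- sweep_dim(lab, along, 2:d[along], 1L)
        lab <- sweep_dim(lab, along, (d[along] - 1L):1L, -1L)
      }
    }
    if (identical(lab, old)) break
  }
  out <- array(0L, dim = d)
  out[mask] <- as.integer(factor(lab[mask]))
  out
}

# Dilate a logical mask by one voxel, 6-connectivity.
.dilate6 <- function(mask) {
  d <- dim(mask); out <- mask
  if (d[1] > 1L) { out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
                   out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ] }
  if (d[2] > 1L) { out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
                   out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ] }
  if (d[3] > 1L) { out[, , -1] <- out[, , -1] | mask[, , -d[3]]
                   out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1] }
  out
}

#' Threshold-and-label fallback organ segmentation
#'
#' Voxels inside a soft-tissue HU window are labelled into 6-connected
#' components; components touching air (or the volume edge) are discarded as
#' body wall, as are components below a minimum volume. The largest
#' remaining component is called liver and the next largest spleen — a size
#' heuristic that is valid for the phantom geometry and documented as *not
#' clinically valid*. The production segmentation model is expected to
#' replace this via the segmenter plug-in seam.
#'
#' @param stack A [series_stack()].
#' @param hu_window Length-2 numeric: soft-tissue HU window (inclusive).
#' @param min_volume_ml Minimum component volume retained, mL.
#' @param air_hu Values at or below this are treated as air.
#' @return A list of two logical arrays, `liver` and `spleen`, aligned to
#'   `stack$voxels`.
#' @export
fallback_segment <- function(stack, hu_window = c(-20, 200),
                             min_volume_ml = 1, air_hu = -500) {
  v <- stack$voxels
  soft <- v >= hu_window[1] & v <= hu_window[2]
  # Air adjacency: anything touching air or the volume boundary is wall.
  air <- v <= air_hu
  edge <- array(FALSE, dim = dim(v))
  edge[c(1, dim(v)[1]), , ] <- TRUE
  edge[, c(1, dim(v)[2]), ] <- TRUE
  edge[, , c(1, dim(v)[3])] <- TRUE
  near_air <- .dilate6(air | edge)

  lab <- label_components_3d(soft)
  n_comp <- max(lab)
  if (n_comp == 0L) hs_segmentation_failed("no soft-tissue components found")
  sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
  touches_wall <- rep(FALSE, n_comp)
  wall_ids <- unique(lab[lab > 0L & near_air])
  touches_wall[wall_ids] <- TRUE
  min_vox <- min_volume_ml * 1000 / prod(stack$spacing)
  keep <- which(!touches_wall & sizes >= min_vox)
  if (length(keep) < 2L) {
    hs_segmentation_failed(sprintf(
      "found %d interior soft-tissue component(s); need liver and spleen",
      length(keep)))
  }
  keep <- keep[order(-sizes[keep])]
  list(liver = lab == keep[1], spleen = lab == keep[2])
}

#' Read organ masks supplied alongside a study ("masks-on-disk" mode)
#'
#' Expects `liver_mask.json` / `spleen_mask.json` or a `truth.json` manifest
#' (as written by [generate_phantom()]) in the study directory, with
#' run-length-encoded voxel masks co-registered to the assembled stack.
#'
#' @param stack A [series_stack()].
#' @param study_dir Directory holding the mask files.
#' @return A list of logical arrays `liver`, `spleen`.
#' @export
masks_on_disk_segment <- function(stack, study_dir) {
  manifest <- file.path(study_dir, "truth.json")
  if (!file.exists(manifest)) {
    hs_segmentation_failed(sprintf("no truth.json manifest in '%s'", study_dir))
  }
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  decode <- function(r) {
    array(as.logical(inverse.rle(structure(
      list(lengths = r$lengths, values = r$values), class = "rle"
    ))), dim = r$dim)
  }
  liver <- decode(m$liver_mask_rle); spleen <- decode(m$spleen_mask_rle)
  if (!all(dim(liver) == dim(stack$voxels))) {
    hs_segmentation_failed("mask dimensions do not match the assembled stack")
  }
  list(liver = liver, spleen = spleen)
}
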