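# Synthetic abdominal CT phantom: a body ellipse with a soft-tissue wall,
# visceral fat interior, and two embedded "organ" ellipsoids (liver, spleen)
# of configurable mean attenuation, written as a standards-compliant DICOM
# study with known ground truth.

#' Phantom configuration
#'
#' Describes one synthetic abdominal CT study. Defaults are desk-scale: a
#' 20 x 64 x 64 grid at 1.5 x 1.5 mm in-plane / 3 mm slices, liver and spleen
#' ellipsoids embedded in visceral fat (-100 HU) inside a soft-tissue body
#' wall (50 HU), air (-1000 HU) outside the body ellipse. Organ voxels are
#' drawn from Normal(mean, noise_sd) and quantized to integer HU, so the
#' zero-noise phantom recovers organ means exactly downstream.
#'
#' @param grid Integer length-3: (n_slices, rows, cols).
#' @param spacing Numeric length-3, mm: (row, column, inter-slice).
#' @param liver_mean_hu,spleen_mean_hu Mean organ attenuation, HU.
#' @param background_hu Soft-tissue body-wall attenuation, HU.
#' @param fat_hu Visceral/subcutaneous fat attenuation, HU.
#' @param noise_sd Gaussian noise SD inside organs, HU (>= 0).
#' @param liver_ellipsoid,spleen_ellipsoid Lists with `center` and `semi`
#'   (voxel units, (slice, row, col) order).
#' @param procedure_code CPT code string stamped into every instance.
#' @param contrast_agent Optional contrast-agent tag value (`NULL` = tag absent).
#' @param slice_thickness_schedule Per-slice thickness tag values, mm
#'   (recycled to `n_slices`); geometry spacing is `spacing[3]` regardless.
#' @param orientation `"axial"` or `"coronal"` (coronal exists to exercise
#'   the non-axial rejection path).
#' @param seed Integer RNG seed; the phantom is byte-deterministic given it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(20L, 64L, 64L),
                           spacing = c(1.5, 1.5, 3),
                           liver_mean_hu = 30, spleen_mean_hu = 49,
                           background_hu = 50, fat_hu = -100,
                           noise_sd = 0,
                           liver_ellipsoid = list(center = c(10.5, 28, 24),
                                                  semi = c(5, 11, 9)),
                           spleen_ellipsoid = list(center = c(10.5, 40, 44),
                                                   semi = c(3, 6, 5)),
                           procedure_code = "74176",
                           contrast_agent = NULL,
                           slice_thickness_schedule = NULL,
                           orientation = c("axial", "coronal"),
                           seed = 1L) {
  orientation <- match.arg(orientation)
  if (noise_sd < 0) hs_abort("noise_sd must be >= 0", "hepascreen_config_error")
  if (is.null(slice_thickness_schedule)) slice_thickness_schedule <- spacing[3]
  structure(list(
    grid = as.integer(grid), spacing = as.numeric(spacing),
    liver_mean_hu = liver_mean_hu, spleen_mean_hu = spleen_mean_hu,
    background_hu = background_hu, fat_hu = fat_hu, noise_sd = noise_sd,
    liver_ellipsoid = liver_ellipsoid, spleen_ellipsoid = spleen_ellipsoid,
    procedure_code = procedure_code, contrast_agent = contrast_agent,
    slice_thickness_schedule = rep(as.numeric(slice_thickness_schedule),
                                   length.out = grid[1]),
    orientation = orientation, seed = as.integer(seed)
  ), class = "phantom_config")
}

# Logical mask of an axis-aligned ellipsoid on the (slice, row, col) grid.
.ellipsoid_mask <- function(grid, center, semi) {
  ds <- ((seq_len(grid[1]) - center[1]) / semi[1])^2
  dr <- ((seq_len(grid[2]) - center[2]) / semi[2])^2
  dc <- ((seq_len(grid[3]) - center[3]) / semi[3])^2
  outer(outer(ds, dr, "+"), dc, "+") <= 1
}

# Per-slice body ellipse, replicated across slices.
.body_masks <- function(grid) {
  cr <- (grid[2] + 1) / 2; cc <- (grid[3] + 1) / 2
  ar <- 0.82 * grid[2] / 2; ac <- 0.94 * grid[3] / 2
  rr <- ((seq_len(grid[2]) - cr) / ar)^2
  cv <- ((seq_len(grid[3]) - cc) / ac)^2
  rho2 <- outer(rr, cv, "+")
  to3 <- function(m) aperm(array(m, dim = c(grid[2], grid[3], grid[1])), c(3, 1, 2))
  list(body = to3(rho2 <= 1), interior = to3(rho2 <= 0.88^2))
}

#' Build the phantom voxel volume and its ground truth in memory
#'
#' The on-disk generator is a thin wrapper around this; tests and
#' simulations that do not need DICOM files call it directly.
#'
#' @param config A [phantom_config()].
#' @return A list: `voxels` (integer HU array, (slice, row, col)),
#'   `truth` (a `phantom_truth` list: `liver_mask`, `spleen_mask`,
#'   `liver_volume_ml`, `spleen_volume_ml`, `true_means`, `voxel_volume_mm3`).
#' @export
phantom_volume <- function(config) {
  g <- config$grid
  liver <- .ellipsoid_mask(g, config$liver_ellipsoid$center, config$liver_ellipsoid$semi)
  spleen <- .ellipsoid_mask(g, config$spleen_ellipsoid$center, config$spleen_ellipsoid$semi)
  if (any(liver & spleen)) {
    hs_abort("liver and spleen ellipsoids overlap", "hepascreen_config_error")
  }
  bm <- .body_masks(g)
  if (any(liver & !bm$interior) || any(spleen & !bm$interior)) {
    hs_abort("organ ellipsoid extends outside the body interior",
             "hepascreen_config_error")
  }
  set.seed(config$seed)
  vox <- array(-1000, dim = g)
  vox[bm$body] <- config$background_hu          # soft-tissue wall ...
  vox[bm$interior] <- config$fat_hu             # ... enclosing visceral fat
  nl <- sum(liver); ns <- sum(spleen)
  vox[liver] <- config$liver_mean_hu + if (config$noise_sd > 0)
    stats::rnorm(nl, 0, config$noise_sd) else 0
  vox[spleen] <- config$spleen_mean_hu + if (config$noise_sd > 0)
    stats::rnorm(ns, 0, config$noise_sd) else 0
  storage.mode(vox) <- "double"
  vox <- round(vox)                             # CT pixel data is integral
  voxvol <- prod(config$spacing)
  truth <- structure(list(
    liver_mask = liver, spleen_mask = spleen,
    liver_volume_ml = nl * voxvol / 1000,
    spleen_volume_ml = ns * voxvol / 1000,
    true_means = c(liver = config$liver_mean_hu, spleen = config$spleen_mean_hu),
    voxel_volume_mm3 = voxvol
  ), class = "phantom_truth")
  list(voxels = vox, truth = truth)
}

.orientation_cosines <- function(orientation) {
  switch(orientation,
    axial   = c(1, 0, 0, 0, 1, 0),    # normal (0, 0, 1)
    coronal = c(1, 0, 0, 0, 0, -1)    # normal (0, 1, 0)
  )
}

#' Generate a phantom DICOM study on disk
#'
#' Writes one single-frame CT instance per slice under
#' `out_dir/<study_uid>/<sop_uid>.dcm` (the pipeline's inbox layout), with
#' rescale slope 1 / intercept -1024 and per-slice thickness tags from the
#' schedule. Deterministic given `config$seed`: pixel data and every minted
#' UID repeat exactly.
#'
#' @param config A [phantom_config()].
#' @param out_dir Directory that will receive the study folder.
#' @param write_truth If `TRUE`, a `truth.json` manifest (organ means,
#'   volumes, run-length-encoded masks) is written next to the slices.
#' @return Invisibly, a list: `study_dir`, `study_uid`, `series_uid`,
#'   `paths`, `truth`.
#' @export
generate_phantom <- function(config, out_dir, write_truth = FALSE) {
  pv <- phantom_volume(config)     # also seeds the RNG for UID minting
  g <- config$grid
  # Phantom UIDs are purely seed-derived (RNG draw + in-study ordinal), so a
  # fixed seed reproduces the study byte-for-byte even within one session.
  phantom_uid <- function(k) {
    sprintf("%s.%d.%d", HS_UID_ROOT, sample.int(.Machine$integer.max, 1L), k)
  }
  study_uid <- phantom_uid(1L); series_uid <- phantom_uid(2L)
  study_dir <- file.path(out_dir, study_uid)
  dir.create(study_dir, recursive = TRUE, showWarnings = FALSE)
  orient <- .orientation_cosines(config$orientation)
  normal <- .slice_normal(orient)
  stored_all <- pmin(pmax(pv$voxels + 1024, 0), 32000)
  paths <- character(g[1])
  for (i in seq_len(g[1])) {
    sop_uid <- phantom_uid(2L + i)
    meta <- instance_meta(
      study_uid = study_uid, series_uid = series_uid, sop_uid = sop_uid,
      instance_number = i,
      image_position = (i - 1) * config$spacing[3] * normal,
      image_orientation = orient,
      pixel_spacing = config$spacing[1:2],
      slice_thickness = config$slice_thickness_schedule[i],
      rescale_slope = 1, rescale_intercept = -1024,
      rows = g[2], cols = g[3],
      procedure_code = config$procedure_code,
      contrast_agent = if (is.null(config$contrast_agent)) NA_character_
                       else config$contrast_agent,
      series_number = 1L
    )
    paths[i] <- file.path(study_dir, paste0(sop_uid, ".dcm"))
    write_ct_instance(paths[i], meta, stored_all[i, , ])
  }
  if (write_truth) {
    rle_mask <- function(m) {
      r <- rle(as.integer(m))
      list(lengths = r$lengths, values = r$values, dim = dim(m))
    }
    manifest <- list(
      study_uid = study_uid, series_uid = series_uid,
      true_means = as.list(pv$truth$true_means),
      liver_volume_ml = pv$truth$liver_volume_ml,
      spleen_volume_ml = pv$truth$spleen_volume_ml,
      liver_mask_rle = rle_mask(pv$truth$liver_mask),
      spleen_mask_rle = rle_mask(pv$truth$spleen_mask)
    )
    jsonlite::write_json(manifest, file.path(study_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(study_dir = study_dir, study_uid = study_uid,
                 series_uid = series_uid, paths = paths, truth = pv$truth))
}

#' Named phantom scenarios mirroring the pipeline's routing outcomes
#'
#' Each scenario is a [phantom_config()] engineered to trigger exactly one
#' routing outcome: `steatotic` and `normal` are fully eligible (and differ
#' only in organ attenuation), the rest each violate one eligibility rule.
#'
#' @param name One of `"steatotic"`, `"normal"`, `"nonuniform_thickness"`,
#'   `"contrast_tagged"`, `"wrong_cpt"`, `"nonaxial"`.
#' @param seed RNG seed passed through to the config.
#' @param noise_sd Organ noise SD, HU (scenarios default to noiseless so
#'   expected statistics are exact).
#' @return A [phantom_config()].
#' @export
make_scenario <- function(name, seed = 1L, noise_sd = 0) {
  base <- function(...) phantom_config(seed = seed, noise_sd = noise_sd, ...)
  switch(name,
    steatotic = base(liver_mean_hu = 30, spleen_mean_hu = 49),
    normal = base(liver_mean_hu = 55, spleen_mean_hu = 48),
    nonuniform_thickness = base(slice_thickness_schedule = c(3, 5)),
    contrast_tagged = base(contrast_agent = "OMNIPAQUE 350"),
    wrong_cpt = base(procedure_code = "71250"),
    nonaxial = base(orientation = "coronal"),
    hs_abort(sprintf("unknown scenario '%s'", name), "hepascreen_config_error")
  )
}
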