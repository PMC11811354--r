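# Part-10 read/write round trips, HU rescale, and series assembly geometry.

test_that("a written phantom slice round-trips every geometry field", {
  out <- withr::local_tempdir()
  cfg <- make_scenario("steatotic", seed = 11)
  p <- generate_phantom(cfg, out)
  inst <- read_instance(p$paths[4])
  m <- inst$meta
  expect_identical(m$study_uid, p$study_uid)
  expect_identical(m$series_uid, p$series_uid)
  expect_equal(m$instance_number, 4L)
  expect_equal(m$image_position, c(0, 0, 3 * 3))
  expect_equal(m$image_orientation, c(1, 0, 0, 0, 1, 0))
  expect_equal(m$pixel_spacing, c(1.5, 1.5))
  expect_equal(m$slice_thickness, 3)
  expect_equal(m$rescale_slope, 1)
  expect_equal(m$rescale_intercept, -1024)
  expect_equal(c(m$rows, m$cols), c(64L, 64L))
  expect_identical(m$procedure_code, "74176")
  expect_true(is.na(m$contrast_agent))   # tag absent, not defaulted
})

test_that("non-DICOM input raises a parse error naming the path", {
  bad <- withr::local_tempfile(fileext = ".dcm")
  file.create(bad)                      # zero bytes
  expect_error(read_instance(bad), class = "hepascreen_parse_error")
  expect_error(read_instance(bad), basename(bad))
  txt <- withr::local_tempfile(fileext = ".dcm")
  writeLines(strrep("not dicom ", 50), txt)
  expect_error(read_instance(txt), class = "hepascreen_parse_error")
})

test_that("HU rescale at assembly is affine and exact for integer inputs", {
  out <- withr::local_tempdir()
  # stored 1054, slope 1, intercept -1024 -> 30 HU
  stored <- matrix(1054L, 4, 4)
  for (i in 1:2) {
    m <- mk_meta(i, rows = 4, cols = 4, z = (i - 1) * 3)
    write_ct_instance(file.path(out, paste0(i, ".dcm")), m, stored)
  }
  stk <- assemble_series(lapply(list.files(out, full.names = TRUE), read_instance))
  expect_identical(unique(as.vector(stk$voxels)), 30)
})

test_that("assembly sorts along the normal and derives spacing from positions", {
  planes <- lapply(1:3, function(i) list(meta = mk_meta(i, z = (i - 1) * 2, thickness = 2,
                                                        rows = 4, cols = 4),
                                         plane = matrix(i, 4, 4)))
  stk <- assemble_series(planes)
  expect_equal(stk$spacing[3], 2)
  expect_equal(stk$slice_thickness_set, 2)
  shuffled <- assemble_series(planes[c(3, 1, 2)])
  expect_identical(shuffled$voxels, stk$voxels)
  expect_identical(vapply(shuffled$meta, `[[`, "", "sop_uid"),
                   vapply(stk$meta, `[[`, "", "sop_uid"))
})

test_that("mixed thickness tags are recorded; inconsistent geometry errors", {
  mixed <- lapply(1:3, function(i) {
    list(meta = mk_meta(i, z = c(0, 2, 5)[i], thickness = c(2, 2, 3)[i],
                        rows = 4, cols = 4),
         plane = matrix(0, 4, 4))
  })
  expect_equal(assemble_series(mixed)$slice_thickness_set, c(2, 3))

  dup <- lapply(1:2, function(i) list(meta = mk_meta(i, z = 0, rows = 4, cols = 4),
                                      plane = matrix(0, 4, 4)))
  expect_error(assemble_series(dup), class = "hepascreen_assembly_error")

  sizes <- lapply(1:2, function(i) {
    list(meta = mk_meta(i, z = (i - 1) * 3, rows = c(4L, 8L)[i], cols = 4),
         plane = matrix(0, c(4, 8)[i], 4))
  })
  expect_error(assemble_series(sizes), class = "hepascreen_assembly_error")
  expect_error(assemble_series(sizes[1]), class = "hepascreen_assembly_error")
})

test_that("secondary capture shares the study UID and round-trips", {
  vox <- array(0, c(5, 8, 8))
  stk <- mk_stack(vox)
  planes <- lapply(1:5, function(i) array(17L, c(8, 8, 3)))
  out <- withr::local_tempdir()
  sc <- write_secondary_capture(stk, planes, stk$meta, out)
  expect_length(sc, 5L)
  expect_false(attr(sc, "series_uid") == stk$series_uid)
  back <- read_instance(sc[2])
  expect_identical(back$meta$study_uid, stk$study_uid)
  expect_identical(back$meta$modality, "OT")
  expect_identical(unique(as.vector(back$plane)), 17L)

  expect_error(write_secondary_capture(stk, planes[1:4], stk$meta, out),
               class = "hepascreen_write_error")
  expect_error(write_secondary_capture(stk, list(), list(), out),
               class = "hepascreen_write_error")
})

test_that("written CT instances parse identically under an independent reader", {
  out <- withr::local_tempdir()
  p <- generate_phantom(make_scenario("steatotic", seed = 3), out)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "arr = ds.pixel_array * ds.RescaleSlope + ds.RescaleIntercept",
    "print(int(ds.Rows), int(ds.Columns), ds.ProcedureCodeSequence[0].CodeValue,",
    "      int(arr.sum()), float(ds.SliceThickness))"
  ), script)
  res <- system2("python", c(script, p$paths[10]), stdout = TRUE)
  fields <- strsplit(res, " +")[[1]]
  ours <- read_instance(p$paths[10])
  hu <- ours$plane * ours$meta$rescale_slope + ours$meta$rescale_intercept
  expect_equal(as.integer(fields[1:2]), c(64L, 64L))
  expect_identical(fields[3], "74176")
  expect_equal(as.numeric(fields[4]), sum(hu))
  expect_equal(as.numeric(fields[5]), 3)
})
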