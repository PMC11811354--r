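# Routing: CPT normalization, contrast verification, technical checks,
# series selection policy, and the decision invariant.

small_vox <- function(n = 3) array(0, c(n, 4, 4))

test_that("CPT eligibility normalizes thousands separators", {
  expect_true(study_eligible(mk_meta(1, cpt = "74176"))$pass)
  expect_true(study_eligible(mk_meta(1, cpt = "74,176"))$pass)
  expect_true(study_eligible(mk_meta(1, cpt = "74,150"))$pass)
  chest <- study_eligible(mk_meta(1, cpt = "71250"))
  expect_false(chest$pass)
  expect_identical(chest$reasons, "WRONG_CPT")
  expect_false(study_eligible(mk_meta(1, cpt = NA_character_))$pass)
})

test_that("non-contrast verification applies the any-instance rule", {
  expect_true(verify_non_contrast(mk_stack(small_vox()))$pass)
  expect_true(verify_non_contrast(mk_stack(small_vox(), contrast = ""))$pass)
  tagged <- mk_stack(small_vox(), contrast = "OMNIPAQUE 350")
  expect_identical(verify_non_contrast(tagged)$reasons, "CONTRAST_PRESENT")
  # one tagged instance in an otherwise clean series fails the study
  mixed <- mk_stack(small_vox())
  mixed$meta[[2]]$contrast_agent <- "OMNIPAQUE 350"
  expect_false(verify_non_contrast(mixed)$pass)
})

test_that("technical check enforces axial, uniform, in-range thickness", {
  ok <- series_technical_check(mk_stack(small_vox()))
  expect_true(ok$pass)
  thick <- series_technical_check(mk_stack(small_vox(), spacing = c(1.5, 1.5, 7),
                                           thickness = rep(7, 3)))
  expect_identical(thick$reasons, "THICKNESS_OUT_OF_RANGE")
  nonuni <- series_technical_check(mk_stack(small_vox(), thickness = c(2, 3, 2)))
  expect_identical(nonuni$reasons, "NONUNIFORM_THICKNESS")
  cor <- series_technical_check(mk_stack(small_vox(), orientation = coronal_cosines))
  expect_identical(cor$reasons, "NO_AXIAL_SERIES")
  # inclusive bounds
  edge <- series_technical_check(mk_stack(small_vox(), spacing = c(1.5, 1.5, 5),
                                          thickness = rep(5, 3)))
  expect_true(edge$pass)
})

test_that("the thickest passing series wins, independent of candidate order", {
  s2 <- mk_stack(small_vox(), spacing = c(1.5, 1.5, 2), thickness = rep(2, 3),
                 series_uid = "1.2.3.20", series_number = 2L)
  s5 <- mk_stack(small_vox(), spacing = c(1.5, 1.5, 5), thickness = rep(5, 3),
                 series_uid = "1.2.3.50", series_number = 3L)
  for (cand in list(list(s2, s5), list(s5, s2))) {
    d <- select_series(cand)
    expect_true(d$eligible)
    expect_identical(d$selected_series_uid, "1.2.3.50")
  }
  single <- select_series(list(s2))
  expect_identical(single$selected_series_uid, "1.2.3.20")
})

test_that("all-failing candidates aggregate reasons; empty list is NO_SERIES", {
  bad1 <- mk_stack(small_vox(), cpt = "71250", series_uid = "1.2.3.61")
  bad2 <- mk_stack(small_vox(), thickness = c(2, 3, 2), series_uid = "1.2.3.62")
  d <- select_series(list(bad1, bad2))
  expect_false(d$eligible)
  expect_true(is.na(d$selected_series_uid))
  expect_identical(d$reasons, c("WRONG_CPT", "NONUNIFORM_THICKNESS"))
  empty <- select_series(list())
  expect_false(empty$eligible)
  expect_identical(empty$reasons, "NO_SERIES")
})

test_that("decision invariant holds on randomized candidate sets", {
  set.seed(20)
  for (rep in 1:40) {
    n <- sample(0:4, 1)
    cands <- lapply(seq_len(n), function(i) {
      mk_stack(small_vox(),
               spacing = c(1.5, 1.5, sample(c(0.5, 2, 5, 8), 1)),
               thickness = rep(sample(c(0.5, 2, 5, 8), 1), 3),
               orientation = if (runif(1) < 0.3) coronal_cosines else axial_cosines,
               cpt = sample(c("74176", "74150", "71250"), 1),
               contrast = sample(c(NA_character_, "IV contrast"), 1),
               series_uid = paste0("1.2.9.", i), series_number = i)
    })
    d <- select_series(cands)
    expect_identical(d$eligible, !is.na(d$selected_series_uid))
    expect_identical(d$eligible, length(d$reasons) == 0L)
    if (n > 1) {
      d2 <- select_series(rev(cands))
      expect_identical(d2$selected_series_uid, d$selected_series_uid)
      expect_identical(sort(d2$reasons), sort(d$reasons))
    }
  }
})

test_that("every scenario maps to exactly its intended routing outcome", {
  out <- withr::local_tempdir()
  expected <- list(
    steatotic = character(0), normal = character(0),
    nonuniform_thickness = "NONUNIFORM_THICKNESS",
    contrast_tagged = "CONTRAST_PRESENT",
    wrong_cpt = "WRONG_CPT", nonaxial = "NO_AXIAL_SERIES"
  )
  for (nm in names(expected)) {
    p <- generate_phantom(make_scenario(nm, seed = 5), file.path(out, nm))
    stk <- assemble_series(lapply(p$paths, read_instance))
    d <- select_series(list(stk))
    expect_identical(d$reasons, expected[[nm]], label = nm)
    expect_identical(d$eligible, length(expected[[nm]]) == 0L, label = nm)
  }
})
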