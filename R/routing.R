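# Eligibility routing: decide from study metadata and series technical
# parameters whether and on which series the steatosis stage runs.

ROUTING_REASONS <- c("WRONG_CPT", "CONTRAST_PRESENT", "NO_AXIAL_SERIES",
                     "THICKNESS_OUT_OF_RANGE", "NONUNIFORM_THICKNESS",
                     "NO_SERIES")

#' Routing configuration
#'
#' @param eligible_cpt_codes CPT codes accepted as non-contrast abdominal CT
#'   (compared after stripping thousands separators, so `"74,176"` matches
#'   `"74176"`).
#' @param min_thickness,max_thickness Accepted slice-thickness range, mm,
#'   inclusive on both ends.
#' @param require_uniform_thickness Require exactly one distinct
#'   slice-thickness tag value in the series.
#' @param require_axial Require the slice normal to be axial.
#' @param axial_tolerance Cosine tolerance: axial means
#'   `|normal_z| >= 1 - axial_tolerance`.
#' @return An object of class `routing_config`.
#' @export
routing_config <- function(eligible_cpt_codes = c("74176", "74150"),
                           min_thickness = 1, max_thickness = 5,
                           require_uniform_thickness = TRUE,
                           require_axial = TRUE,
                           axial_tolerance = 0.01) {
  stopifnot(min_thickness < max_thickness,
            axial_tolerance > 0, axial_tolerance < 0.5)
  structure(list(
    eligible_cpt_codes = .normalize_cpt(eligible_cpt_codes),
    min_thickness = min_thickness, max_thickness = max_thickness,
    require_uniform_thickness = isTRUE(require_uniform_thickness),
    require_axial = isTRUE(require_axial),
    axial_tolerance = axial_tolerance
  ), class = "routing_config")
}

.normalize_cpt <- function(code) gsub("[, ]", "", as.character(code))

#' Study-level CPT eligibility check
#'
#' @param study_meta An [instance_meta()] sampled from the study.
#' @param config A [routing_config()].
#' @return A list: `pass` (logical) and `reasons` (character, empty on pass).
#' @export
study_eligible <- function(study_meta, config = routing_config()) {
  code <- study_meta$procedure_code
  ok <- !is.na(code) && .normalize_cpt(code) %in% config$eligible_cpt_codes
  list(pass = ok, reasons = if (ok) character(0) else "WRONG_CPT")
}

#' Verify a series is non-contrast from its metadata
#'
#' Passes only when the contrast-agent tag is absent or empty on *every*
#' instance of the assembled series. (An image-based contrast heuristic is a
#' documented extension point, not implemented.)
#'
#' @param stack A [series_stack()].
#' @return A list: `pass` and `reasons`.
#' @export
verify_non_contrast <- function(stack) {
  tagged <- vapply(stack$meta, function(m) {
    !is.na(m$contrast_agent) && nzchar(m$contrast_agent)
  }, logical(1))
  ok <- !any(tagged)
  list(pass = ok, reasons = if (ok) character(0) else "CONTRAST_PRESENT")
}

#' Series technical inclusion check
#'
#' Passes iff (a) the slice normal is axial within the configured cosine
#' tolerance, (b) the slice-thickness tag takes exactly one value across the
#' series, and (c) that value lies inside the configured range (inclusive).
#'
#' @param stack A [series_stack()].
#' @param config A [routing_config()].
#' @return A list: `pass` and `reasons` (possibly several).
#' @export
series_technical_check <- function(stack, config = routing_config()) {
  reasons <- character(0)
  if (config$require_axial) {
    nrm <- .slice_normal(stack$meta[[1]]$image_orientation)
    if (abs(nrm[3]) < 1 - config$axial_tolerance) {
      reasons <- c(reasons, "NO_AXIAL_SERIES")
    }
  }
  ths <- stack$slice_thickness_set
  if (config$require_uniform_thickness && length(ths) != 1L) {
    reasons <- c(reasons, "NONUNIFORM_THICKNESS")
  } else if (any(ths < config$min_thickness | ths > config$max_thickness)) {
    reasons <- c(reasons, "THICKNESS_OUT_OF_RANGE")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Decide eligibility and pick the series to analyze
#'
#' Runs the CPT, non-contrast and technical checks on every candidate series
#' of one study. Among fully passing series, the one with the *largest*
#' slice thickness wins (fewest slices, least compute); ties break by lowest
#' series number, then lexicographic series UID. The decision is a pure
#' function of its inputs and is invariant to candidate order.
#'
#' @param candidates List of [series_stack()] objects from one study.
#' @param config A [routing_config()].
#' @return A `routing_decision`: `study_uid`, `eligible`,
#'   `selected_series_uid` (`NA` when ineligible), `reasons` (ordered,
#'   machine-readable rejection codes, empty when eligible), and
#'   `per_series` (reasons per candidate).
#' @export
select_series <- function(candidates, config = routing_config()) {
  if (length(candidates) == 0L) {
    return(.routing_decision(NA_character_, NA_character_, "NO_SERIES", list()))
  }
  study_uid <- candidates[[1]]$study_uid
  per_series <- list()
  passing <- list()
  for (stk in candidates) {
    reasons <- c(
      study_eligible(stk$meta[[1]], config)$reasons,
      verify_non_contrast(stk)$reasons,
      series_technical_check(stk, config)$reasons
    )
    per_series[[stk$series_uid]] <- reasons
    if (length(reasons) == 0L) passing[[length(passing) + 1L]] <- stk
  }
  if (length(passing) == 0L) {
    all_reasons <- unique(unlist(per_series, use.names = FALSE))
    all_reasons <- ROUTING_REASONS[ROUTING_REASONS %in% all_reasons]
    return(.routing_decision(study_uid, NA_character_, all_reasons, per_series))
  }
  thick <- vapply(passing, function(s) s$slice_thickness_set[1], 0)
  sn <- vapply(passing, function(s) {
    v <- s$meta[[1]]$series_number
    if (is.na(v)) .Machine$integer.max else v
  }, 0L)
  uid <- vapply(passing, `[[`, "", "series_uid")
  best <- order(-thick, sn, uid)[1]
  .routing_decision(study_uid, uid[best], character(0), per_series)
}

.routing_decision <- function(study_uid, selected, reasons, per_series) {
  structure(list(
    study_uid = study_uid,
    eligible = length(reasons) == 0L,
    selected_series_uid = if (length(reasons) == 0L) selected else NA_character_,
    reasons = reasons,
    per_series = per_series
  ), class = "routing_decision")
}

#' @export
print.routing_decision <- function(x, ...) {
  if (x$eligible) {
    cat(sprintf("<routing_decision> eligible; series %s selected\n",
                x$selected_series_uid))
  } else {
    cat(sprintf("<routing_decision> ineligible: %s\n",
                paste(x$reasons, collapse = ", ")))
  }
  invisible(x)
}
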