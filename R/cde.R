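# Common data elements (CDEs): registry-coded measurements packaged for
# report-template filling, DICOM-SR export and the research database.

#' Round half away from zero
#'
#' Report rendering uses commercial rounding (half away from zero), not R's
#' banker's rounding, so printed HU values match clinical convention.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' The CDE registry bundled with the package
#'
#' Codes RDE1194 (liver mean attenuation), RDE1207 (spleen mean
#' attenuation) and RDE1193 (liver minus spleen) follow the national
#' RadElement registry; LIVF1 is the steatosis flag; elements without a
#' published code (hepatic volume) carry clearly marked `LOCAL-` codes.
#'
#' @return A data frame with columns `code`, `meaning`, `units`.
#' @export
cde_registry <- function() {
  path <- system.file("extdata", "cde_registry.json", package = "hepascreen")
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg$elements
}

.cde <- function(code, meaning, value, units) {
  if (is.numeric(value) && !is.finite(value)) {
    hs_abort(sprintf("non-finite value for CDE %s", code),
             "hepascreen_cde_error")
  }
  list(code = code, meaning = meaning, value = value, units = units)
}

#' Package a steatosis result as a CDE set
#'
#' HU values are rounded per policy (default integer, half away from zero)
#' and the liver-minus-spleen difference RDE1193 is recomputed *from the
#' rounded* RDE1194/RDE1207, so the printed report is arithmetically
#' self-consistent. Unrounded values are kept in the `unrounded` attribute
#' for the database record.
#'
#' @param result A `steatosis_result` from [analyze_steatosis()].
#' @param rounding Decimal places for HU display values.
#' @return An object of class `cde_set`: named list of CDEs keyed by code.
#' @export
build_cde_set <- function(result, rounding = 0L) {
  liver <- round_half_away(result$liver_mean_hu, rounding)
  spleen <- round_half_away(result$spleen_mean_hu, rounding)
  cdes <- list(
    RDE1194 = .cde("RDE1194", "Liver mean attenuation", liver, "HU"),
    RDE1207 = .cde("RDE1207", "Spleen mean attenuation", spleen, "HU"),
    RDE1193 = .cde("RDE1193", "Liver minus spleen attenuation", liver - spleen, "HU"),
    LIVF1 = .cde("LIVF1", "Hepatic steatosis",
                 isTRUE(result$steatosis_present), ""),
    `LOCAL-LIVVOL` = .cde("LOCAL-LIVVOL", "Hepatic volume",
                          round_half_away(result$liver_volume_ml, 1L), "mL")
  )
  structure(cdes, class = "cde_set",
            rounding = as.integer(rounding),
            unrounded = list(
              liver_mean_hu = result$liver_mean_hu,
              spleen_mean_hu = result$spleen_mean_hu,
              shad = result$shad,
              liver_minus_spleen_hu = result$liver_minus_spleen_hu,
              liver_volume_ml = result$liver_volume_ml,
              steatosis_present = result$steatosis_present
            ))
}

.format_cde_value <- function(cde, rounding = 0L) {
  v <- cde$value
  if (is.logical(v)) return(if (v) "present" else "absent")
  if (rounding <= 0L) sprintf("%d", as.integer(v)) else
    sprintf(paste0("%.", rounding, "f"), v)
}

#' The bundled report-template text
#'
#' The attenuation-measurements section of the radiologist's report, with
#' `[RDE####]`-style placeholders that [render_report()] fills from a CDE
#' set.
#'
#' @return A single string.
#' @export
default_report_template <- function() {
  path <- system.file("extdata", "report_template.txt", package = "hepascreen")
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

#' Fill a report template from a CDE set
#'
#' Replaces every `[CODE]` placeholder with the formatted CDE value and the
#' `[yes/no]` placeholder with `present`/`absent` from the steatosis flag.
#' Rendering is byte-deterministic. Unresolvable placeholders raise an error
#' naming the missing codes.
#'
#' @param template Template text (default: the bundled Table-style section).
#' @param cdes A [build_cde_set()] result.
#' @return Rendered report text with no placeholders left.
#' @export
render_report <- function(template = default_report_template(), cdes) {
  rounding <- attr(cdes, "rounding") %||% 0L
  m <- gregexpr("\\[([A-Za-z0-9/_-]+)\\]", template)[[1]]
  if (m[1] == -1L) return(template)
  tokens <- unique(regmatches(template, list(m))[[1]])
  out <- template
  missing <- character(0)
  for (tok in tokens) {
    code <- substr(tok, 2L, nchar(tok) - 1L)
    if (code == "yes/no") {
      flag <- cdes[["LIVF1"]]
      if (is.null(flag)) { missing <- c(missing, "LIVF1"); next }
      repl <- if (isTRUE(flag$value)) "present" else "absent"
    } else {
      cde <- cdes[[code]]
      if (is.null(cde)) { missing <- c(missing, code); next }
      repl <- .format_cde_value(cde, rounding)
    }
    out <- gsub(tok, repl, out, fixed = TRUE)
  }
  if (length(missing) > 0L) {
    hs_abort(sprintf("unresolved report placeholders: %s",
                     paste(sort(unique(missing)), collapse = ", ")),
             "hepascreen_cde_error")
  }
  out
}

#' @export
print.cde_set <- function(x, ...) {
  cat("<cde_set>\n")
  for (cde in x) {
    cat(sprintf("  %-12s %-32s %s %s\n", cde$code, cde$meaning,
                .format_cde_value(cde, attr(x, "rounding") %||% 0L), cde$units))
  }
  invisible(x)
}
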