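# Structured error helpers: every pipeline failure carries a condition class so
# the orchestrator can route failures (parse vs. ineligible vs. segmentation).

hs_abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "hepascreen_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

hs_parse_error <- function(message, path = NULL) {
  hs_abort(message, "hepascreen_parse_error", path = path)
}

hs_ineligible_instance <- function(message, path = NULL) {
  hs_abort(message, "hepascreen_ineligible_instance", path = path)
}

hs_segmentation_failed <- function(message) {
  hs_abort(message, "hepascreen_segmentation_failed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
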