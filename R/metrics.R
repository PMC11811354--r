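# Throughput and turnaround-time statistics computed from event logs:
# TAT decomposition (transfer + processing), threshold fractions, and the
# staged eligibility funnel with rounded percentages.

#' Turnaround-time record for one study
#'
#' Transfer time is the span between receipt of the first and last DICOM
#' instance; processing time runs from the last receipt to the completion of
#' *all* exports; TAT is their sum by construction. All values in minutes.
#'
#' @param events Event data frame for one study (see [read_study_events()]),
#'   containing `INSTANCE_RECEIVED` and both `EXPORT_PACS_DONE` /
#'   `EXPORT_REPORT_DONE` events.
#' @return A list of class `tat_record`: `study_uid`, `transfer_time`,
#'   `processing_time`, `tat` (minutes).
#' @export
compute_tat <- function(events) {
  rec <- events[events$event == "INSTANCE_RECEIVED", "time"]
  exp_done <- events[events$event %in% c("EXPORT_PACS_DONE", "EXPORT_REPORT_DONE"), ]
  if (length(rec) == 0L || !all(c("EXPORT_PACS_DONE", "EXPORT_REPORT_DONE") %in%
                                exp_done$event)) {
    hs_abort("study lacks receipt or export events; excluded from TAT set",
             "hepascreen_tat_incomplete")
  }
  transfer <- (max(rec) - min(rec)) / 60
  processing <- (max(exp_done$time) - max(rec)) / 60
  structure(list(study_uid = events$study_uid[1],
                 transfer_time = transfer, processing_time = processing,
                 tat = transfer + processing),
            class = "tat_record")
}

#' TAT records for every exportable study in a log directory
#'
#' @param config An [orchestrator_config()] (its `log_dir` is scanned).
#' @return List of `tat_record`s; studies without complete export events are
#'   skipped (they sit in the failure category of the funnel instead).
#' @export
tat_records <- function(config) {
  logs <- list.files(config$log_dir, pattern = "\\.jsonl$", full.names = TRUE)
  out <- list()
  for (f in logs) {
    uid <- sub("\\.jsonl$", "", basename(f))
    ev <- read_study_events(config, uid)
    rec <- tryCatch(compute_tat(ev), hepascreen_tat_incomplete = function(e) NULL)
    if (!is.null(rec)) out[[uid]] <- rec
  }
  out
}

#' Summary statistics over TAT records
#'
#' @param records Nonempty list of `tat_record`s.
#' @param threshold Minutes; the reported fraction counts studies with TAT
#'   *strictly less than* this threshold.
#' @return A list: `mean_transfer`, `mean_processing`, `mean_tat`,
#'   `fraction_under_threshold`, `max_tat`, `n` (minutes; full precision —
#'   display rounding is the caller's concern).
#' @export
tat_summary <- function(records, threshold = 5) {
  if (length(records) == 0L) {
    hs_abort("no TAT records to summarize", "hepascreen_metrics_error")
  }
  tr <- vapply(records, `[[`, 0, "transfer_time")
  pr <- vapply(records, `[[`, 0, "processing_time")
  tat <- vapply(records, `[[`, 0, "tat")
  list(mean_transfer = mean(tr), mean_processing = mean(pr),
       mean_tat = mean(tat),
       fraction_under_threshold = sum(tat < threshold) / length(tat),
       max_tat = max(tat), n = length(tat))
}

#' Staged eligibility-funnel counts
#'
#' @param eligible_by_code Studies whose procedure code made them candidates.
#' @param transferred Studies actually transferred to the analysis server.
#' @param rejected_technical Transferred studies rejected by the technical
#'   checks.
#' @param selected Transferred studies selected for analysis.
#' @param completed Selected studies on which the analysis ran to completion.
#' @param exported Completed studies whose results were exported.
#' @return A validated list of class `funnel_counts`.
#' @export
funnel_counts <- function(eligible_by_code, transferred, rejected_technical,
                          selected, completed, exported) {
  x <- list(eligible_by_code = eligible_by_code, transferred = transferred,
            rejected_technical = rejected_technical, selected = selected,
            completed = completed, exported = exported)
  if (transferred > eligible_by_code ||
      rejected_technical + selected != transferred ||
      completed > selected || exported > completed) {
    hs_abort("funnel counts violate the stage ordering invariants",
             "hepascreen_metrics_error")
  }
  structure(x, class = "funnel_counts")
}

.pct <- function(num, den) {
  if (den == 0) return(NA_real_)     # undefined stage, never reported as 0
  round_half_away(100 * num / den)
}

#' Staged funnel percentages
#'
#' Each stage is expressed against its natural denominator and rounded to
#' the nearest integer percent, half away from zero. Zero denominators
#' yield `NA` ("undefined"), never 0.
#'
#' @param counts A [funnel_counts()].
#' @return Named numeric vector: `transferred_pct` (of eligible-by-code),
#'   `rejected_pct` and `selected_pct` (of transferred), `completed_pct`
#'   (of selected), `exported_pct` (of completed).
#' @export
funnel_report <- function(counts) {
  c(transferred_pct = .pct(counts$transferred, counts$eligible_by_code),
    rejected_pct = .pct(counts$rejected_technical, counts$transferred),
    selected_pct = .pct(counts$selected, counts$transferred),
    completed_pct = .pct(counts$completed, counts$selected),
    exported_pct = .pct(counts$exported, counts$completed))
}

#' Derive funnel counts from the orchestrator's event logs
#'
#' Every stage is defined operationally from this pipeline's own logs:
#' `eligible_by_code` counts all studies with a routing record (the desk
#' denominator); `transferred` counts studies whose procedure code passed
#' (emulating the archive-side CPT filter, which in production gates the
#' transfer itself); `rejected_technical`/`selected` split the transferred
#' studies by the routing verdict; `completed` requires an `ALGO_END` event
#' and `exported` requires both export-done events. Logs showing an export
#' without a completed analysis fail validation.
#'
#' @param config An [orchestrator_config()].
#' @return A [funnel_counts()].
#' @export
funnel_from_logs <- function(config) {
  logs <- list.files(config$log_dir, pattern = "\\.jsonl$", full.names = TRUE)
  n_all <- 0L; n_transferred <- 0L; n_rejected <- 0L; n_selected <- 0L
  n_completed <- 0L; n_exported <- 0L
  bad <- character(0)
  for (f in logs) {
    uid <- sub("\\.jsonl$", "", basename(f))
    ev <- read_study_events(config, uid)
    routing <- ev[ev$event == "ROUTING_DONE", "detail"]
    if (length(routing) == 0L) next
    n_all <- n_all + 1L
    verdict <- jsonlite::fromJSON(routing[length(routing)])
    wrong_cpt <- "WRONG_CPT" %in% verdict$reasons
    completed <- "ALGO_END" %in% ev$event
    exported <- all(c("EXPORT_PACS_DONE", "EXPORT_REPORT_DONE") %in% ev$event)
    if (exported && !completed) bad <- c(bad, uid)
    if (wrong_cpt) next                     # never transferred in production
    n_transferred <- n_transferred + 1L
    if (isTRUE(verdict$eligible)) n_selected <- n_selected + 1L
    else n_rejected <- n_rejected + 1L
    if (completed) n_completed <- n_completed + 1L
    if (exported) n_exported <- n_exported + 1L
  }
  if (length(bad) > 0L) {
    hs_abort(sprintf("inconsistent logs (export without completed analysis): %s",
                     paste(bad, collapse = ", ")),
             "hepascreen_metrics_error")
  }
  funnel_counts(n_all, n_transferred, n_rejected, n_selected,
                n_completed, n_exported)
}
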