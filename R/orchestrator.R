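# The orchestrator runtime: scan a file-drop inbox for complete studies,
# route them, run the steatosis stage, export QC and SR artifacts to outbox
# directories (with retries), append the research database, enforce
# retention, and log every event as JSON lines.

#' Orchestrator configuration
#'
#' All DICOM networking is emulated by directories: `inbox` receives studies
#' as `inbox/<study_uid>/<sop_uid>.dcm`, QC series go to `pacs_outbox`, SRs
#' to `report_outbox`. Artifacts are built in a staging area and then
#' "transferred" (copied) to the outboxes; the copy step is the seam where
#' transfer failures occur and are retried.
#'
#' @param root Convenience: when given, all directories default to
#'   subdirectories of `root`.
#' @param inbox,pacs_outbox,report_outbox,log_dir Directory paths (distinct).
#' @param db_path Path of the append-only results database (CSV).
#' @param completion_mode `"signal_file"` (a `study.complete` sentinel in the
#'   study folder marks completion, emulating the production HL7 trigger) or
#'   `"quiescence"` (complete once no instance arrived for
#'   `quiescence_seconds`).
#' @param quiescence_seconds Quiescence window, seconds.
#' @param retention_days Days imaging data is kept after processing ends
#'   before [retention_sweep()] deletes it (default 7, i.e. one week).
#' @param max_retries Retries per artifact after the first transfer attempt.
#' @param retry_backoff Seconds to wait before each retry (recycled).
#' @param routing A [routing_config()].
#' @param steatosis A [steatosis_config()].
#' @param style An [overlay_style()].
#' @param segmenter `"fallback"`, `"masks-on-disk"`, or a function
#'   `stack -> list(liver, spleen)` (the plug-in seam for a production
#'   segmentation model).
#' @param transfer_fn `function(src, dest)` performing the artifact
#'   transfer; defaults to a file copy. Tests inject failing functions here.
#' @return An object of class `orchestrator_config`.
#' @export
orchestrator_config <- function(root = NULL,
                                inbox = file.path(root, "inbox"),
                                pacs_outbox = file.path(root, "pacs-outbox"),
                                report_outbox = file.path(root, "reporting-outbox"),
                                log_dir = file.path(root, "logs"),
                                db_path = file.path(root, "cde_database.csv"),
                                completion_mode = c("signal_file", "quiescence"),
                                quiescence_seconds = 2,
                                retention_days = 7,
                                max_retries = 3L,
                                retry_backoff = 0,
                                routing = routing_config(),
                                steatosis = steatosis_config(),
                                style = overlay_style(),
                                segmenter = "fallback",
                                transfer_fn = NULL) {
  completion_mode <- match.arg(completion_mode)
  dirs <- c(inbox, pacs_outbox, report_outbox, log_dir)
  if (anyDuplicated(normalizePath(dirs, mustWork = FALSE))) {
    hs_abort("inbox, outboxes and log dir must be distinct directories",
             "hepascreen_config_error")
  }
  stopifnot(retention_days >= 0, max_retries >= 0)
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  structure(list(
    inbox = inbox, pacs_outbox = pacs_outbox, report_outbox = report_outbox,
    log_dir = log_dir, db_path = db_path,
    completion_mode = completion_mode,
    quiescence_seconds = quiescence_seconds,
    retention_days = retention_days,
    max_retries = as.integer(max_retries), retry_backoff = retry_backoff,
    routing = routing, steatosis = steatosis, style = style,
    segmenter = segmenter,
    transfer_fn = transfer_fn %||% .default_transfer
  ), class = "orchestrator_config")
}

.default_transfer <- function(src, dest) {
  ok <- file.copy(src, dest, overwrite = TRUE)
  if (!all(ok)) stop("transfer failed: ", paste(src[!ok], collapse = ", "))
  invisible(TRUE)
}

SENTINEL <- "study.complete"

#' Append one event to a study's JSON-lines log
#'
#' @param config An [orchestrator_config()].
#' @param study_uid Study identifier.
#' @param event Event name (e.g. `INSTANCE_RECEIVED`, `ALGO_START`).
#' @param detail Free-form or JSON detail string.
#' @param time Event timestamp (`POSIXct`); stored as epoch seconds.
#' @return Invisibly, the log file path.
#' @export
log_event <- function(config, study_uid, event, detail = "", time = Sys.time()) {
  line <- jsonlite::toJSON(list(
    study_uid = study_uid, event = event,
    time = as.numeric(time), detail = detail
  ), auto_unbox = TRUE, digits = NA)
  path <- file.path(config$log_dir, paste0(study_uid, ".jsonl"))
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' Read one study's event log
#'
#' @param config An [orchestrator_config()].
#' @param study_uid Study identifier.
#' @return A data frame: `study_uid`, `event`, `time` (epoch seconds),
#'   `detail`; zero rows when no log exists.
#' @export
read_study_events <- function(config, study_uid) {
  path <- file.path(config$log_dir, paste0(study_uid, ".jsonl"))
  empty <- data.frame(study_uid = character(0), event = character(0),
                      time = numeric(0), detail = character(0),
                      stringsAsFactors = FALSE)
  if (!file.exists(path)) return(empty)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(empty)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(study_uid = x$study_uid, event = x$event, time = x$time,
               detail = x$detail %||% "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.done_marker <- function(config, study_uid) {
  file.path(config$log_dir, paste0(study_uid, ".done"))
}

#' Has a study finished arriving?
#'
#' Signal-file mode looks for the `study.complete` sentinel (the desk-scale
#' stand-in for the production HL7 "study complete" message); quiescence
#' mode declares the study complete once no file has been modified for the
#' configured window.
#'
#' @param study_dir The study's inbox folder.
#' @param config An [orchestrator_config()].
#' @param now Reference time for quiescence mode.
#' @return Logical.
#' @export
detect_completion <- function(study_dir, config, now = Sys.time()) {
  files <- list.files(study_dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) return(FALSE)
  if (config$completion_mode == "signal_file") {
    return(file.exists(file.path(study_dir, SENTINEL)))
  }
  as.numeric(now) - max(as.numeric(file.mtime(files))) >= config$quiescence_seconds
}

#' Run transfer tasks with bounded retries
#'
#' Each task is attempted once plus up to `config$max_retries` retries with
#' the configured backoff; every failed attempt is logged as
#' `EXPORT_FAILED`. Exhaustion yields a permanent-failure outcome (the
#' study then lands in the processed-but-not-exported funnel category).
#'
#' @param tasks Named list of zero-argument functions performing one
#'   artifact transfer each.
#' @param config An [orchestrator_config()].
#' @param study_uid Study the tasks belong to (for logging).
#' @return Named logical vector: which tasks ultimately succeeded.
#' @export
retry_exports <- function(tasks, config, study_uid) {
  backoff <- rep(config$retry_backoff, length.out = max(1L, config$max_retries))
  out <- logical(length(tasks)); names(out) <- names(tasks)
  for (nm in names(tasks)) {
    for (attempt in seq_len(config$max_retries + 1L)) {
      res <- tryCatch({ tasks[[nm]](); TRUE }, error = function(e) e)
      if (isTRUE(res)) { out[nm] <- TRUE; break }
      log_event(config, study_uid, "EXPORT_FAILED",
                sprintf("%s attempt %d: %s", nm, attempt, conditionMessage(res)))
      if (attempt <= config$max_retries && backoff[attempt] > 0) {
        Sys.sleep(backoff[attempt])
      }
    }
  }
  out
}

.resolve_segmenter <- function(config, study_dir) {
  seg <- config$segmenter
  if (is.function(seg)) return(seg)
  switch(seg,
    "fallback" = fallback_segment,
    "masks-on-disk" = function(stack) masks_on_disk_segment(stack, study_dir),
    hs_abort(sprintf("unknown segmenter '%s'", seg), "hepascreen_config_error")
  )
}

#' Process one complete study end-to-end
#'
#' Reads and assembles every series, makes the routing decision, and — when
#' eligible — segments, computes the steatosis result, renders the QC
#' overlay series and structured report into a staging area, transfers both
#' to their outboxes (with retries), and appends the database row. Every
#' step is logged. Ineligible studies produce only the routing record; a
#' segmentation failure marks the study failed with no partial exports.
#'
#' @param study_dir The study's inbox folder (`inbox/<study_uid>/`).
#' @param config An [orchestrator_config()].
#' @return Invisibly, a record list: `study_uid`, `status` (one of
#'   `"exported"`, `"ineligible"`, `"failed"`), `decision`, and when run,
#'   `result`, `cdes`, `report_text`, artifact paths.
#' @export
process_study <- function(study_dir, config) {
  files <- sort(list.files(study_dir, pattern = "\\.dcm$", full.names = TRUE))
  instances <- lapply(files, read_instance)
  study_uid <- instances[[1]]$meta$study_uid

  # Receipt events from file mtimes, in arrival order.
  mt <- file.mtime(files)
  for (i in order(mt)) {
    log_event(config, study_uid, "INSTANCE_RECEIVED",
              basename(files[i]), time = mt[i])
  }
  log_event(config, study_uid, "STUDY_COMPLETE", sprintf("%d instances", length(files)))

  by_series <- split(instances, vapply(instances, function(x) x$meta$series_uid, ""))
  stacks <- lapply(by_series[lengths(by_series) >= 2L], assemble_series)
  decision <- select_series(unname(stacks), config$routing)
  if (is.na(decision$study_uid)) decision$study_uid <- study_uid
  log_event(config, study_uid, "ROUTING_DONE",
            jsonlite::toJSON(list(eligible = decision$eligible,
                                  selected = decision$selected_series_uid,
                                  reasons = decision$reasons),
                             auto_unbox = TRUE, null = "null"))
  .finish <- function(record) {
    writeLines(jsonlite::toJSON(list(finished_at = as.numeric(Sys.time()),
                                     status = record$status),
                                auto_unbox = TRUE),
               .done_marker(config, study_uid))
    invisible(record)
  }
  if (!decision$eligible) {
    return(.finish(list(study_uid = study_uid, status = "ineligible",
                        decision = decision)))
  }

  stack <- stacks[[vapply(stacks, `[[`, "", "series_uid") == decision$selected_series_uid]]
  log_event(config, study_uid, "ALGO_START", "hepatic steatosis")
  result <- tryCatch(
    analyze_steatosis(stack, .resolve_segmenter(config, study_dir),
                      config$steatosis),
    hepascreen_segmentation_failed = function(e) e
  )
  if (inherits(result, "condition")) {
    log_event(config, study_uid, "ALGO_FAILED", conditionMessage(result))
    return(.finish(list(study_uid = study_uid, status = "failed",
                        decision = decision, error = conditionMessage(result))))
  }
  log_event(config, study_uid, "ALGO_END", "hepatic steatosis")

  cdes <- build_cde_set(result, config$steatosis$hu_rounding)
  report_text <- render_report(default_report_template(), cdes)

  # Build artifacts in staging, then transfer (the retryable leg).
  staging <- file.path(config$log_dir, "staging", study_uid)
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  qc_paths <- render_qc_series(stack, result$masks, config$style,
                               file.path(staging, "qc"))
  sr_info <- build_sr(cdes, stack$meta, file.path(staging, paste0("sr-", study_uid, ".dcm")))

  pacs_dest <- file.path(config$pacs_outbox, study_uid)
  dir.create(pacs_dest, recursive = TRUE, showWarnings = FALSE)
  outcomes <- retry_exports(list(
    qc_to_pacs = function() config$transfer_fn(as.character(qc_paths), pacs_dest),
    sr_to_reporting = function() config$transfer_fn(sr_info$path, config$report_outbox)
  ), config, study_uid)

  if (!all(outcomes)) {
    return(.finish(list(study_uid = study_uid, status = "failed",
                        decision = decision, result = result, cdes = cdes,
                        export_outcomes = outcomes)))
  }
  log_event(config, study_uid, "EXPORT_PACS_DONE",
            sprintf("%d QC instances", length(qc_paths)))
  log_event(config, study_uid, "EXPORT_REPORT_DONE", basename(sr_info$path))

  append_database(config, cdes, study_uid, decision)
  .finish(list(study_uid = study_uid, status = "exported",
               decision = decision, result = result, cdes = cdes,
               report_text = report_text,
               qc_paths = file.path(pacs_dest, basename(qc_paths)),
               sr_path = file.path(config$report_outbox, basename(sr_info$path))))
}

#' Scan the inbox and process every complete, not-yet-processed study
#'
#' Studies are handled sequentially, oldest folder first. A per-study done
#' marker guarantees exactly-once processing across repeated scans; files
#' arriving after a study was processed are logged as late-arrival warnings
#' and never reprocessed.
#'
#' @param config An [orchestrator_config()].
#' @return Invisibly, a list of [process_study()] records for the studies
#'   processed in this scan.
#' @export
run_orchestrator <- function(config) {
  dirs <- list.dirs(config$inbox, recursive = FALSE)
  dirs <- dirs[order(file.mtime(dirs))]
  records <- list()
  for (d in dirs) {
    uid <- basename(d)
    marker <- .done_marker(config, uid)
    if (file.exists(marker)) {
      files <- list.files(d, pattern = "\\.dcm$", full.names = TRUE)
      late <- files[file.mtime(files) > file.mtime(marker)]
      for (f in late) {
        log_event(config, uid, "LATE_ARRIVAL_WARNING", basename(f))
      }
      next
    }
    if (!detect_completion(d, config)) next
    records[[uid]] <- process_study(d, config)
  }
  invisible(records)
}

#' Append one study's CDEs to the research database
#'
#' One append-only CSV row per study: identifiers, timestamp, routing
#' outcome, and the *unrounded* analysis values alongside the rounded CDE
#' display values. A duplicate study append is rejected with a warning and
#' leaves the database unchanged.
#'
#' @param config An [orchestrator_config()].
#' @param cdes A [build_cde_set()] result.
#' @param study_uid Study identifier.
#' @param decision The study's `routing_decision`.
#' @return Invisibly, `TRUE` if a row was appended.
#' @export
append_database <- function(config, cdes, study_uid, decision) {
  if (file.exists(config$db_path)) {
    existing <- utils::read.csv(config$db_path, stringsAsFactors = FALSE)
    if (study_uid %in% existing$study_uid) {
      warning(sprintf("study %s already in database; append rejected", study_uid))
      return(invisible(FALSE))
    }
  }
  u <- attr(cdes, "unrounded")
  row <- data.frame(
    study_uid = study_uid,
    series_uid = decision$selected_series_uid,
    processed_at = as.numeric(Sys.time()),
    eligible = decision$eligible,
    liver_mean_hu = u$liver_mean_hu,
    spleen_mean_hu = u$spleen_mean_hu,
    shad = u$shad,
    liver_minus_spleen_hu = u$liver_minus_spleen_hu,
    liver_volume_ml = u$liver_volume_ml,
    steatosis_present = u$steatosis_present,
    rde1194 = cdes$RDE1194$value,
    rde1207 = cdes$RDE1207$value,
    rde1193 = cdes$RDE1193$value,
    livf1 = cdes$LIVF1$value,
    local_livvol = cdes$`LOCAL-LIVVOL`$value,
    stringsAsFactors = FALSE
  )
  utils::write.table(row, config$db_path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(config$db_path), append = file.exists(config$db_path))
  invisible(TRUE)
}

#' Delete stored imaging data past the retention window
#'
#' Removes inbox imaging data for studies whose processing finished more
#' than `retention_days` ago (one week by default). Derived artifacts — SRs,
#' QC series, database rows, event logs — are never deleted; studies still
#' processing (no done marker) are never touched. Deletions are logged.
#'
#' @param config An [orchestrator_config()].
#' @param now Reference timestamp.
#' @return Character vector of deleted study UIDs.
#' @export
retention_sweep <- function(config, now = Sys.time()) {
  deleted <- character(0)
  for (d in list.dirs(config$inbox, recursive = FALSE)) {
    uid <- basename(d)
    marker <- .done_marker(config, uid)
    if (!file.exists(marker)) next   # still processing or never processed
    finished_at <- jsonlite::fromJSON(readLines(marker, warn = FALSE))$finished_at
    age_days <- (as.numeric(now) - finished_at) / 86400
    if (age_days > config$retention_days) {
      unlink(d, recursive = TRUE)
      log_event(config, uid, "DELETED",
                sprintf("imaging data removed after %.1f days", age_days),
                time = now)
      deleted <- c(deleted, uid)
    }
  }
  deleted
}
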