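# Orchestrator runtime: completion detection, end-to-end processing, export
# retry, exactly-once semantics, retention, database.

orch <- function(..., root = withr::local_tempdir(.local_envir = parent.frame())) {
  orchestrator_config(root = root, ...)
}

drop_study <- function(cfg, scenario = "steatotic", seed = 1L, complete = TRUE) {
  p <- generate_phantom(make_scenario(scenario, seed = seed), cfg$inbox)
  if (complete) file.create(file.path(p$study_dir, "study.complete"))
  p
}

test_that("completion detection: sentinel file and quiescence", {
  cfg <- orch()
  p <- drop_study(cfg, complete = FALSE)
  expect_false(detect_completion(p$study_dir, cfg))
  file.create(file.path(p$study_dir, "study.complete"))
  expect_true(detect_completion(p$study_dir, cfg))

  qcfg <- orch(completion_mode = "quiescence", quiescence_seconds = 2)
  q <- drop_study(qcfg, complete = FALSE)
  now <- max(file.mtime(q$paths))
  expect_false(detect_completion(q$study_dir, qcfg, now = now + 1))
  expect_true(detect_completion(q$study_dir, qcfg, now = now + 3))
})

test_that("an eligible study flows to SR + QC + database with full logging", {
  cfg <- orch()
  p <- drop_study(cfg)
  recs <- run_orchestrator(cfg)
  rec <- recs[[p$study_uid]]
  expect_identical(rec$status, "exported")
  expect_true(rec$result$steatosis_present)
  expect_true(file.exists(rec$sr_path))
  expect_length(rec$qc_paths, 20L)
  expect_true(all(file.exists(rec$qc_paths)))
  db <- read.csv(cfg$db_path)
  expect_identical(db$study_uid, p$study_uid)
  expect_equal(db$liver_mean_hu, rec$result$liver_mean_hu)   # unrounded
  ev <- read_study_events(cfg, p$study_uid)
  expect_true(all(c("INSTANCE_RECEIVED", "STUDY_COMPLETE", "ROUTING_DONE",
                    "ALGO_START", "ALGO_END", "EXPORT_PACS_DONE",
                    "EXPORT_REPORT_DONE") %in% ev$event))
  expect_true(all(diff(ev$time) >= 0))
})

test_that("an ineligible study yields a routing record and no algorithm events", {
  cfg <- orch()
  p <- drop_study(cfg, scenario = "wrong_cpt")
  recs <- run_orchestrator(cfg)
  expect_identical(recs[[p$study_uid]]$status, "ineligible")
  ev <- read_study_events(cfg, p$study_uid)
  expect_true("ROUTING_DONE" %in% ev$event)
  expect_false(any(grepl("^ALGO|^EXPORT", ev$event)))
  expect_false(file.exists(cfg$db_path))
})

test_that("a transient transfer failure is retried and logged", {
  calls <- new.env(); calls$n <- 0L
  flaky <- function(src, dest) {
    calls$n <- calls$n + 1L
    if (calls$n == 1L) stop("simulated network error")
    file.copy(src, dest, overwrite = TRUE)
    invisible(TRUE)
  }
  cfg <- orch(transfer_fn = flaky, max_retries = 3L)
  p <- drop_study(cfg)
  recs <- run_orchestrator(cfg)
  expect_identical(recs[[p$study_uid]]$status, "exported")
  ev <- read_study_events(cfg, p$study_uid)
  expect_identical(sum(ev$event == "EXPORT_FAILED"), 1L)
  expect_true("EXPORT_PACS_DONE" %in% ev$event)
})

test_that("retry exhaustion marks the study processed-but-not-exported", {
  cfg <- orch(transfer_fn = function(src, dest) stop("network down"),
              max_retries = 2L)
  p <- drop_study(cfg)
  recs <- run_orchestrator(cfg)
  expect_identical(recs[[p$study_uid]]$status, "failed")
  ev <- read_study_events(cfg, p$study_uid)
  # 3 attempts for the first artifact, 3 for the second
  expect_identical(sum(ev$event == "EXPORT_FAILED"), 6L)
  expect_false("EXPORT_PACS_DONE" %in% ev$event)
  fc <- funnel_from_logs(cfg)
  expect_identical(c(fc$completed, fc$exported), c(1L, 0L))
})

test_that("max_retries 0 means a single attempt", {
  calls <- new.env(); calls$n <- 0L
  cfg <- orch(transfer_fn = function(src, dest) {
    calls$n <- calls$n + 1L; stop("down")
  }, max_retries = 0L)
  p <- drop_study(cfg)
  run_orchestrator(cfg)
  expect_identical(calls$n, 2L)   # one attempt per artifact (QC, SR)
})

test_that("a double-scanned inbox processes each study exactly once", {
  cfg <- orch()
  p <- drop_study(cfg)
  first <- run_orchestrator(cfg)
  second <- run_orchestrator(cfg)
  expect_length(first, 1L)
  expect_length(second, 0L)
  ev <- read_study_events(cfg, p$study_uid)
  expect_identical(sum(ev$event == "STUDY_COMPLETE"), 1L)
  expect_identical(nrow(read.csv(cfg$db_path)), 1L)
})

test_that("repeat runs over the same phantom study give identical rows", {
  cfg1 <- orch(); cfg2 <- orch()
  drop_study(cfg1, seed = 17); drop_study(cfg2, seed = 17)
  run_orchestrator(cfg1); run_orchestrator(cfg2)
  a <- read.csv(cfg1$db_path); b <- read.csv(cfg2$db_path)
  drop <- "processed_at"                  # timestamps excluded
  expect_identical(a[setdiff(names(a), drop)], b[setdiff(names(b), drop)])
})

test_that("retention sweeps imaging past the window, never derived artifacts", {
  cfg <- orch(retention_days = 7)
  p <- drop_study(cfg)
  rec <- run_orchestrator(cfg)[[p$study_uid]]
  marker <- file.path(cfg$log_dir, paste0(p$study_uid, ".done"))

  backdate <- function(days) {
    m <- jsonlite::fromJSON(readLines(marker))
    m$finished_at <- as.numeric(Sys.time()) - days * 86400
    writeLines(jsonlite::toJSON(m, auto_unbox = TRUE), marker)
  }
  backdate(6)
  expect_length(retention_sweep(cfg), 0L)
  expect_true(dir.exists(p$study_dir))
  backdate(8)
  expect_identical(retention_sweep(cfg), p$study_uid)
  expect_false(dir.exists(p$study_dir))
  # derived artifacts and logs survive the sweep
  expect_true(file.exists(rec$sr_path))
  expect_true(all(file.exists(rec$qc_paths)))
  expect_true(file.exists(cfg$db_path))
  ev <- read_study_events(cfg, p$study_uid)
  expect_true("DELETED" %in% ev$event)

  # unprocessed studies are never deleted
  cfg0 <- orch(retention_days = 0)
  q <- drop_study(cfg0, complete = FALSE)
  expect_length(retention_sweep(cfg0), 0L)
  expect_true(dir.exists(q$study_dir))
  # retention 0: eligible immediately after processing
  file.create(file.path(q$study_dir, "study.complete"))
  run_orchestrator(cfg0)
  expect_identical(retention_sweep(cfg0, now = Sys.time() + 1), q$study_uid)
})

test_that("duplicate database appends are rejected with a warning", {
  cfg <- orch()
  p <- drop_study(cfg)
  rec <- run_orchestrator(cfg)[[p$study_uid]]
  expect_warning(
    append_database(cfg, rec$cdes, p$study_uid, rec$decision),
    "already in database"
  )
  expect_identical(nrow(read.csv(cfg$db_path)), 1L)
})

test_that("late-arriving instances are logged, not reprocessed", {
  cfg <- orch()
  p <- drop_study(cfg)
  run_orchestrator(cfg)
  extra <- file.path(p$study_dir, "late.dcm")
  file.copy(p$paths[1], extra)
  Sys.setFileTime(extra, Sys.time() + 5)
  recs <- run_orchestrator(cfg)
  expect_length(recs, 0L)
  ev <- read_study_events(cfg, p$study_uid)
  expect_true("LATE_ARRIVAL_WARNING" %in% ev$event)
  expect_identical(sum(ev$event == "ALGO_START"), 1L)
})
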