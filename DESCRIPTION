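Package: hepascreen
Title: Desk-Scale AI Orchestrator for Opportunistic CT Hepatic Steatosis Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A file-driven clinical AI orchestration pipeline for opportunistic
    hepatic steatosis screening on non-contrast abdominal CT. Reads and writes
    DICOM CT series (uncompressed explicit-VR little endian), decides study
    eligibility from procedure codes and series technical parameters, computes
    liver and spleen mean attenuation, the spleen-hepatic attenuation
    difference (SHAD) and hepatic volume, renders quality-control segmentation
    overlays as DICOM secondary-capture series, packages results as common
    data elements into DICOM structured reports and report-template text, and
    accounts for throughput and turnaround time from event logs. Includes a
    synthetic abdominal CT phantom generator with known ground truth so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
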