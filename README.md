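# hepascreen

A desk-scale AI orchestration pipeline for **opportunistic hepatic
steatosis screening on non-contrast abdominal CT**, written in R.

Fatty liver lowers hepatic attenuation on CT, and most abdominal CTs are
acquired for unrelated reasons — so every non-contrast abdominal CT is a
free screening opportunity, *if* the measurement, quality control and
reporting happen automatically. `hepascreen` re-creates that clinical
workflow as a file-driven pipeline anyone can run offline:

* **DICOM I/O** — read single-frame CT studies, assemble geometrically
  ordered HU volumes, write secondary-capture and structured-report
  objects (a minimal Part-10 codec, uncompressed explicit-VR little
  endian, is built in; no DICOM package exists for R).
* **Routing** — decide eligibility from CPT procedure codes (74176/74150),
  contrast metadata and series technical parameters (axial, uniform slice
  thickness within 1–5 mm), and select the thickest passing series.
* **Analysis** — liver and spleen mean attenuation, the spleen-hepatic
  attenuation difference (SHAD = spleen − liver, HU), hepatic volume, and
  the steatosis determinant
  `present ⇔ liver < 40 HU or SHAD > 10 HU` (strict inequalities).
  The production deep-learning segmenter plugs in behind a contract; a
  phantom-grade threshold/connected-component fallback keeps the pipeline
  runnable end-to-end.
* **Reporting** — common data elements (RDE1194/RDE1207/RDE1193/LIVF1)
  rendered into the clinical report template, packaged as a DICOM
  Structured Report, plus a colored QC overlay series for the PACS.
* **Orchestration & metrics** — inbox scanning with exactly-once
  processing, export retries, one-week imaging retention, JSON-line event
  logs, and turnaround-time / eligibility-funnel statistics computed from
  those logs.
* **Synthetic phantoms** — abdominal-CT-like DICOM studies with known
  ground truth (organ masks, means, volumes), so everything above is
  testable with no clinical data.

## Worked example

Generate the canonical phantom (liver 30 HU, spleen 49 HU, CPT 74176,
uniform 3 mm axial slices), drop it in an inbox, and run the orchestrator:

```r
library(hepascreen)

cfg <- orchestrator_config(root = tempfile("demo"))
p <- generate_phantom(make_scenario("steatotic", seed = 1), cfg$inbox)
file.create(file.path(p$study_dir, "study.complete"))  # the "study complete" trigger

rec <- run_orchestrator(cfg)[[p$study_uid]]
rec$result
#> <steatosis_result>
#>   liver mean:  30.0 HU (2074 voxels, 14.0 mL)
#>   spleen mean: 49.0 HU (378 voxels)
#>   SHAD:        19.0 HU
#>   steatosis:   present
cat(rec$report_text)
#> ATTENUATION MEASUREMENTS:
#> Liver (30 HU) - Spleen (49 HU) = -19 HU
#> Hepatic steatosis: present
#> Threshold: liver < 40 HU or Liver-Spleen < -10 HU (Hamer O, et al. RadioGraphics 2006)
```

The zero-noise phantom recovers its configured organ means exactly: the
report shows liver 30 HU, spleen 49 HU, a rounded difference of −19 HU,
and a positive steatosis call (SHAD = 19 > 10 and liver = 30 < 40). After
the run, `cfg$pacs_outbox` holds the 20-slice QC overlay series,
`cfg$report_outbox` the structured report, and `cfg$db_path` the
append-only CDE database row.

Funnel accounting works on any staged counts:

```r
funnel_report(funnel_counts(3178, 2697, 1706, 991, 991, 784))
#> transferred_pct    rejected_pct    selected_pct   completed_pct    exported_pct
#>              85              63              37             100              79
```

Command-line wrappers cover the same ground:

```sh
Rscript inst/cli/generate-phantom.R --scenario steatotic --out inbox --seed 1
Rscript inst/cli/orchestrate.R run --root .
Rscript inst/cli/orchestrate.R metrics --root .
```

## Further reading

The methods vignette (`vignettes/hepascreen-methods.Rmd`) documents the
screening statistic, the routing rules, the phantom's design and its
deliberate simplifications, the fallback segmenter's limits, rounding and
tie-break policies, and the TAT/funnel definitions.
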