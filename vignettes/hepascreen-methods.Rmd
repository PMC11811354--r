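---
title: "How hepascreen works: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How hepascreen works: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepascreen)
```

## The problem

Hepatic steatosis — fatty infiltration of the liver — lowers hepatic
attenuation on non-contrast CT, and most abdominal CTs are acquired for
unrelated indications. That makes every non-contrast abdominal CT an
opportunity for *opportunistic screening*: a screening read that costs the
radiologist nothing if the measurement is computed, quality-controlled and
inserted into the report automatically.

`hepascreen` is a desk-scale orchestration pipeline for exactly that
workflow. Studies arrive as DICOM file drops; routing rules decide whether
and on which series the analysis runs; the analysis computes liver and
spleen mean attenuation, the spleen-hepatic attenuation difference (SHAD),
and hepatic volume; results leave as a quality-control overlay series (for
the PACS) and a structured report carrying common data elements (for the
reporting engine); and event logs feed turnaround-time and throughput
accounting. All network legs of the production architecture (PACS, VNA,
HL7 routing) are emulated by directories, which is what makes the whole
system testable on a laptop with synthetic data.

## The screening statistic

For a liver mask $L$ and spleen mask $S$ over an HU volume $v$:

$$\bar{v}_L = \frac{1}{|L|}\sum_{i \in L} v_i, \qquad
  \bar{v}_S = \frac{1}{|S|}\sum_{i \in S} v_i, \qquad
  \mathrm{SHAD} = \bar{v}_S - \bar{v}_L$$

The radiologic determinant for moderate-to-severe steatosis is

$$\text{present} \iff \bar{v}_L < 40\ \mathrm{HU} \;\lor\; \mathrm{SHAD} > 10\ \mathrm{HU},$$

with both inequalities strict. The equivalent published form
"liver − spleen < −10 HU" is the same predicate, since
liver − spleen = −SHAD; the test suite asserts the equivalence over random
inputs rather than trusting the algebra. Means are unweighted voxel means:
routing only admits series with a uniform slice thickness, so
volume-weighting across slices would change nothing, and the simpler
definition is kept and documented.

Organ means are carried at full precision internally and rounded only at
report rendering (integer HU, half away from zero — commercial rounding,
not R's banker's rounding). The displayed liver-minus-spleen difference is
recomputed from the *rounded* liver and spleen values so the printed
arithmetic is self-consistent; the unrounded values go to the research
database.

## Routing rules

A study is analyzed when all of the following hold, checked in order:

1. **Procedure code.** The CPT code is one of the accepted non-contrast
   abdominal codes (defaults `74176`, `74150`). Comparison strips
   thousands separators, so `74,176` matches.
2. **Non-contrast verification.** The contrast-agent tag must be absent or
   empty on *every* instance. The production system also inspected pixel
   data; how is not published, so the metadata rule is implemented and the
   pixel heuristic is left as a documented extension point behind the same
   function.
3. **Technical criteria.** The series must be axial (|z-component of the
   slice normal| ≥ 1 − 0.01), have exactly one distinct slice-thickness
   tag value, and that value must lie in [1, 5] mm inclusive. The bounds
   are configurable because the production range is not published; 1–5 mm
   brackets the thicknesses scanners commonly reconstruct.

Among fully passing series the *thickest* one is selected — fewest slices,
least compute, which is the stated rationale for thickness limits in the
first place. Ties break by lowest series number, then lexicographic series
UID, so the decision is a pure, order-invariant function of its inputs.
The policy sits behind one function and can be swapped.

## The synthetic phantom

No public CT corpus ships with this package; instead the generator builds
abdominal-CT-like studies with known ground truth:

* a per-slice body ellipse; air (−1000 HU) outside;
* a soft-tissue **body wall ring** at 50 HU (outer 12 % of the body
  radius);
* **visceral fat** (−100 HU) filling the interior;
* a liver and a spleen ellipsoid embedded in the fat, drawn as
  `Normal(mean, noise_sd)` per voxel and quantized to integer HU.

The default grid is 20 × 64 × 64 voxels at 1.5 × 1.5 × 3 mm. Organs are
desk-scale (the default liver is ~14 mL, not ~1500 mL): large enough that
the central-limit band 4σ/√N is meaningful, small enough that hundreds of
replicates run in minutes.

Two layout choices deserve a note. First, organs sit in fat rather than in
soft tissue. A soft-tissue background would be indistinguishable from the
organs under any HU threshold, and no threshold-based fallback segmenter
could separate them; embedding the organs in fat makes the phantom
*segmentable by construction*, which is the property the pipeline tests
need. Second, pixel values are quantized to integers before writing
(stored as slope 1 / intercept −1024), so a fixed seed reproduces a study
byte-for-byte — phantom UIDs are likewise derived from the seed — and the
zero-noise phantom recovers organ means *exactly* downstream.

What the phantom deliberately does not emulate: anatomy, partial-volume
effects, beam hardening, scanner noise texture, or contrast enhancement
beyond the metadata tag. Passing tests therefore demonstrate pipeline
correctness (geometry, routing, arithmetic, packaging, logging), not
clinical segmentation performance.

Scenario presets (`make_scenario()`) pin each routing outcome: `steatotic`
(liver 30 / spleen 49 HU — the canonical worked example), `normal` (liver
55 / spleen 48), `nonuniform_thickness`, `contrast_tagged`, `wrong_cpt`
(chest CT code 71250) and `nonaxial` (coronal reformat).

## Fallback segmentation

The production deep-learning liver/spleen model is not published and is
out of scope; it plugs in behind the segmenter contract
(`stack -> list(liver, spleen)`). So the pipeline can run end-to-end, a
phantom-grade fallback is provided: threshold to a soft-tissue window
([−20, 200] HU), 6-connected component labelling, discard components that
touch air or the volume edge (that removes the body wall) or are smaller
than 1 mL, then call the largest remaining component liver and the next
spleen. The size rule is valid for the phantom geometry and **not
clinically valid** — a test documents that enlarging the spleen swaps the
labels. Labelling uses minimum-label propagation with raster/anti-raster
sweeps; blob-like components converge in a few passes.

With organ noise σ = 15 HU the lower tail of the liver distribution
(30 HU mean) crosses the −20 HU window edge at 3.3σ, truncating ~0.04 % of
voxels and biasing the recovered mean by ~0.03 HU — far inside the 4σ/√N
acceptance band (~1.3 HU at the default liver size), which is why the
noisy-phantom recovery test can use the segmenter's own mask rather than
the truth mask.

## Reporting

Five common data elements are packaged per study: RDE1194 (liver mean HU),
RDE1207 (spleen mean HU), RDE1193 (liver − spleen, from rounded values),
LIVF1 (steatosis flag) and LOCAL-LIVVOL (hepatic volume, mL — a local
extension code, since only the first four codes are published). The
bundled report template renders them into the attenuation-measurements
section of the clinical report; rendering is byte-deterministic and fails
loudly on unresolved placeholders.

The same CDEs become a DICOM Structured Report: a root CONTAINER with one
NUM content item per numeric CDE (UCUM-coded units) and a CODE item for
the flag, under the *source* study UID with the analyzed instances listed
as evidence. The QC overlay series is RGB secondary capture, also under
the source study UID, one instance per source slice with derived-image
provenance. Overlays use the standard abdominal window (center 40 / width
400 HU), alpha 0.4, liver red / spleen blue; where masks overlap, the
earlier organ in the palette wins. Because no installed R package reads
or writes DICOM, the package carries its own minimal Part-10 codec, fixed
to uncompressed explicit-VR little endian; enhanced multi-frame objects
and other transfer syntaxes are rejected with clear errors.

## Orchestration and metrics

Completion detection defaults to a `study.complete` sentinel file — the
file-drop stand-in for the production "study complete" HL7 message — with
a quiescence mode (no new file for *n* seconds) for deployments with no
upstream trigger. Processing is sequential FIFO; a per-study done marker
makes processing exactly-once across repeated scans, and late-arriving
instances are logged as warnings, never reprocessed. Artifacts are built
in staging and then transferred to the outboxes; the transfer step retries
up to `max_retries` times (transfer failures were the dominant production
failure mode, arriving in batches), and exhaustion leaves the study in the
processed-but-not-exported category with no partial-export ambiguity.
Imaging data is deleted by `retention_sweep()` once processing finished
more than `retention_days` ago (default 7 — one week); derived artifacts,
logs and database rows are never swept.

Turnaround time is decomposed as

* transfer time = last instance receipt − first instance receipt,
* processing time = completion of all exports − last instance receipt,
* TAT = their sum (an identity by construction, fuzz-tested anyway),

and the "under threshold" fraction is strict (`< 5` min). The eligibility
funnel is computed operationally from the pipeline's own logs:
`eligible_by_code` counts studies with a routing record, `transferred`
those whose CPT passed (the archive-side filter gates the transfer in
production, so CPT-rejected studies never count as transferred),
`rejected_technical`/`selected` split the rest by verdict, `completed`
requires the analysis-end event and `exported` both export events. Stage
percentages round half away from zero; undefined stages (zero
denominator) report `NA`, never 0.

## Problem sizes and tolerances

The test suite and acceptance script use 20-slice 64 × 64 phantoms, 200
noisy replicates for parameter recovery, 10,000 random inputs for the
predicate-equivalence property, and a 20-study inbox for the
completion-rate experiment — sizes chosen so the full suite runs in about
two minutes on one CPU while keeping every statistical band (CLT bounds,
≥ 99 % recovery) meaningful. Numerical tolerances are exact wherever the
phantom is exact (zero noise, integer HU); statistical assertions state
their bands explicitly in the tests.

## Known limitations

* The fallback segmenter is a phantom-grade stand-in; clinical use
  requires a real segmentation model behind the plug-in seam.
* Non-contrast verification is metadata-only.
* Single-frame CT only; one worker; no DICOM networking (directories
  emulate all transport).
* The phantom's simplicity means pipeline-level passes say nothing about
  segmentation accuracy on real anatomy.
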