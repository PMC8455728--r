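---
title: "dicomflow: models, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dicomflow: models, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it models, the
parameters that matter, and the choices made where the design was genuinely
open. The README shows the pipeline in action; here we explain why it is
built the way it is.

## The pipeline model

`dicomflow` models the data path between a hospital PACS and a research
store as five cooperating stages:

1. **Ingestion** — a storage-class listener per source accepts C-STORE
   datasets and files them hierarchically. The crucial modelling decision
   is that *receipt time* is a property of the listener's clock, assigned
   at store time and recorded in a durable index; header timestamps belong
   to the scanner's clock. Everything the clock-skew detector does rests on
   keeping these two clocks distinct.
2. **On-demand retrieval** — query CSVs expand to STUDY-level C-FIND
   followed by one C-MOVE per study. Progress is tracked per query (not per
   instance) because a C-MOVE is atomic from the client's perspective: the
   client cannot usefully resume half a study.
3. **Metadata extraction** — profile-driven, one representative instance
   per series by default, one document per (series, profile), upserted.
4. **Storage lifecycle** — nightly deletion of series whose metadata is
   extracted for *every* active profile, gated by consumer holds and a
   retention floor.
5. **Analytics** — exam windows, utilization, overlap detection, clock
   skew, PNG export, de-identification.

### DIMSE as an in-process service

The DICOM network operations (C-STORE, C-FIND, C-MOVE) are modelled as
in-process service objects: the mock PACS holds an archive index and pushes
instances into a listener's `c_store` handler; destinations are an AE-title
registry; failures carry DIMSE-style status codes, and a fault-injection
mode fails every *k*-th C-MOVE to exercise retry paths. This preserves the
semantics that matter to the pipeline — delivery counts, statuses, retry
and resume behaviour, destination validation — while leaving the TCP wire
protocol (association negotiation, PDU framing) out of scope. A deployment
against a real PACS would swap the service object for a network client; no
other module would change, because all of them interact with the service
only through `c_find`/`c_move`/`c_store`.

### DICOM Part 10 support

The package carries its own minimal Part 10 reader/writer: Explicit VR
Little Endian, simple top-level VRs, no sequences. That subset is exactly
what the pipeline touches (identifiers, dates and times, device identity,
the image pixel module, private tags carried opaquely), and the writer's
output is verified in the test suite against an independent DICOM
implementation. Compressed transfer syntaxes (e.g. JPEG Lossless) are
detected and refused by name rather than mis-parsed; generating or decoding
them is out of scope, which also means the PNG exporter only handles
uncompressed 8/16-bit grayscale.

## The synthetic fleet: what it emulates, and what it does not

The generator is the package's study-condition definition, not a tuning
knob. One synthetic day is:

- per scanner, `exams_per_scanner` exams with durations uniform on
  15–45 min and gaps uniform on 5–30 min, the day opening at 07:00 —
  magnitudes typical of MRI schedules, where slots run tens of minutes.
  Exams never overlap within a scanner (a scanner performs one exam at a
  time); scanners are independent. If the drawn schedule would run past
  midnight, generation fails loudly rather than truncating.
- per exam, 1–3 series of 2–4 instances; instance acquisition instants are
  spread evenly across the exam so the min/max over instances recovers the
  true window exactly.
- per scanner, a signed `clock_offset_min`: every header date/time is the
  true instant *plus* the offset. The offset is therefore exactly
  recoverable from any instance, which turns the skew detector's test into
  a parameter-recovery problem with a known answer.
- receipt times in tests and the acceptance script are true acquisition
  plus a fixed 2-minute transfer delay. A constant delay keeps skew
  assertions exact; the 20-minute allowance dwarfs realistic jitter, so a
  stochastic delay would add noise without changing any flagging outcome
  as long as it stays well under the threshold margin (the fixture offsets
  keep at least a 5-minute margin on either side of 20).
- schedule times are rounded to whole seconds, and instance instants
  floored to whole seconds, because DA/TM headers are written at second
  precision; this keeps "window ⊆ true interval" containment exact instead
  of approximately true.

Deterministic UIDs are derived from (seed, exam, series, instance) under a
private UID root, so identical inputs give byte-stable fixtures.

What the generator does **not** emulate: realistic pixel content (payloads
are 16×16 grayscale ramps), modality-specific acquisition physics,
incomplete or inconsistent headers beyond what individual tests construct,
PACS-side throttling, and multi-day archives. Green tests therefore
demonstrate the pipeline's bookkeeping and analytics logic, not robustness
to the full messiness of production DICOM streams.

The corrupted-schedule generator emulates hand-entered operational records:
a fraction `error_rate` of entries get start/end shifts uniform on
±`max_shift_min` (entries are re-ordered if a shift inverts an interval).
Overlap emergence is probabilistic per draw, which is why tests and the
acceptance script aggregate over several corruption seeds.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| skew threshold | 20 | min | allowance for network transfer + extraction latency before a clock is deemed miscalibrated |
| extraction interval | 10 | min | polling cadence; an event-triggered mode exists for lower latency |
| representative mode | `first` | — | one image per series suffices for series-level metadata and bounds extraction cost |
| cleanup schedule | 23:59 | local time | nightly, after the working day |
| retention floor | 1440 | min | a series is never deleted within a day of receipt, whatever its extraction state |
| C-MOVE retries | 2 | — | transient PACS faults are common; 1+2 attempts bounds query effort |
| network delay (fixtures) | 2 | min | fixed, so skew expectations are exact |

## Numerical and semantic choices

- **Skew statistic.** The 20-minute rule could be applied per image or per
  scanner. Per-image flagging would mark a healthy scanner for one delayed
  image, so the scanner-level decision uses the **median** skew (the
  per-image exceedance count is still reported). Sign convention:
  skew = receipt − acquisition, so a fast clock yields negative skew.
- **Timestamp precedence.** Acquisition → Series → Content date/time, the
  order of closeness to the actual acquisition event. Date-only values
  parse to midnight with a low-precision flag and are excluded from skew
  medians — a midnight pseudo-time would inject up to ±24 h of noise.
- **Exam identity** is `AccessionNumber` with `StudyInstanceUID` fallback;
  scanner identity is `StationName` with `DeviceSerialNumber` fallback;
  window grouping by study is available as an option.
- **Overlap convention.** Touching windows (end = next start) do not
  overlap; only positive-length intersections are physically impossible.
- **Duplicate stores** are last-write-wins with an updated receipt time:
  C-MOVE retries resend instances, and resends must not inflate counts.
  The ingestion index is an append-only log; the reader collapses it to
  one record per SOP instance.
- **Progress formats** are newline-delimited key files written via
  temp-file + atomic rename — crash-safe without a database, and readable
  by eye during an incident. The metadata store is likewise a directory of
  JSON documents per profile collection: upsert = atomic overwrite, and a
  corrupted extraction state can be rebuilt exactly by listing each
  collection.
- **Missing identifiers** file under an `UNKNOWN` bucket instead of being
  rejected: real scanners emit incomplete headers, and a misfiled instance
  is recoverable where a rejected one is lost.
- **PHI handling.** The default exclusion list covers directly identifying
  attributes (names, birth date, addresses, physician, institution
  address); `PatientID` and `AccessionNumber` are retained by default
  because cohort workflows key on them, and the list is configurable for
  shared collections. PHI is enforced twice: at profile load (with a
  warning) and again at document extraction.
- **De-identification** keeps the whitelist plus the minimum attributes of
  a valid image object, remaps UIDs through a persistent map (so
  study/series linkage survives across files and runs), and preserves the
  pixel buffer bit-exact.

## Problem sizes

The test suite and acceptance script run fleets of 1–9 scanners with 1–4
exams each (tens to ~130 instances per scenario, a few hundred kilobytes of
generated DICOM in temporary storage), chosen so every scenario is
regenerated from code in seconds while still exercising multi-scanner,
multi-series, multi-instance structure, crash/resume schedules and the full
round trip.

## Known limitations

- No TCP DIMSE stack: the service objects are behaviourally faithful test
  doubles, not network endpoints.
- No sequence (SQ) elements, no compressed transfer syntaxes, no Structured
  Report parsing.
- Clock-skew detection assumes transfer delay well under the threshold; a
  congested network approaching the allowance would need a larger threshold
  or an explicit delay model.
- Utilization windows computed from one representative per series can
  under-cover an exam (a single-series exam collapses to a point); the
  `first_middle_last` or `all` representative modes tighten this at higher
  extraction cost.
- Pixel-level PHI (burned-in annotations) is out of scope for
  de-identification.
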