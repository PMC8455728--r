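# Synthetic scanner-fleet generator: per-scanner daily exam schedules with
# controllable clock offsets, materialized as small DICOM Part 10 instances.
# Together with the mock PACS this makes the whole pipeline testable with no
# clinical data.

#' Describe one scanner in a synthetic fleet
#'
#' @param scanner_id unique scanner identifier; written to `StationName` and
#'   `DeviceSerialNumber`.
#' @param modality DICOM modality code (`"MR"`, `"CT"`, `"DX"`, ...).
#' @param clock_offset_min signed clock miscalibration in minutes (scanner
#'   clock minus true time); `0` is a correctly calibrated scanner.
#' @param site_id site the scanner belongs to.
#' @return one-row data frame.
#' @export
#' @examples
#' scanner_spec("MR01", "MR", clock_offset_min = 60)
scanner_spec <- function(scanner_id, modality = "MR", clock_offset_min = 0,
                         site_id = "SITE1") {
  stopifnot(is.character(scanner_id), length(scanner_id) == 1L, nzchar(scanner_id),
            is.finite(clock_offset_min))
  data.frame(scanner_id = scanner_id, modality = modality,
             clock_offset_min = clock_offset_min, site_id = site_id,
             stringsAsFactors = FALSE)
}

.validate_fleet <- function(scanners) {
  stopifnot(is.data.frame(scanners),
            all(c("scanner_id", "modality", "clock_offset_min", "site_id") %in%
                  names(scanners)))
  if (anyDuplicated(scanners$scanner_id)) {
    stop("scanner_id values must be unique within a fleet")
  }
  if (!all(is.finite(scanners$clock_offset_min))) {
    stop("clock offsets must be finite")
  }
  invisible(scanners)
}

.BODY_PARTS <- c("CHEST", "ABDOMEN", "HEAD", "SPINE", "KNEE")

#' Generate a day of exam schedules for a scanner fleet
#'
#' Draws, per scanner, `exams_per_scanner` non-overlapping exams for one day:
#' the working day opens at `day_start`, exam durations and inter-exam gaps
#' are uniform within the given ranges (minutes). A scanner performs one exam
#' at a time, so intervals are pairwise disjoint within a scanner; scanners
#' run independently and may overlap each other.
#'
#' @param scanners fleet data frame (rows from [scanner_spec()]).
#' @param day a `Date` (or `"YYYY-MM-DD"` string).
#' @param exams_per_scanner exams to schedule per scanner (>= 0).
#' @param seed integer seed; fixes schedules, patients and (downstream) UIDs.
#' @param duration_range,gap_range uniform bounds, minutes.
#' @param day_start clock time the first exam may begin, `"HH:MM"`.
#' @return data frame of exams (`accession`, `empi`, `scanner_id`,
#'   `true_start`, `true_end`, `n_series`, `instances_per_series`,
#'   `body_part`) with the generation parameters attached as attribute
#'   `provenance`. Errors if the requested exams cannot fit in the day.
#' @export
generate_fleet_schedule <- function(scanners, day, exams_per_scanner, seed,
                                    duration_range = c(15, 45),
                                    gap_range = c(5, 30),
                                    day_start = "07:00") {
  .validate_fleet(scanners)
  stopifnot(exams_per_scanner >= 0, length(seed) == 1L)
  day <- as.Date(day)
  day_open <- as.POSIXct(paste(day, day_start), format = "%Y-%m-%d %H:%M", tz = "UTC")
  day_close <- as.POSIXct(paste(day + 1, "00:00"), format = "%Y-%m-%d %H:%M", tz = "UTC")

  empty <- data.frame(accession = character(0), empi = character(0),
                      scanner_id = character(0),
                      true_start = as.POSIXct(character(0), tz = "UTC"),
                      true_end = as.POSIXct(character(0), tz = "UTC"),
                      n_series = integer(0), instances_per_series = integer(0),
                      body_part = character(0), stringsAsFactors = FALSE)
  prov <- list(seed = seed, duration_range = duration_range,
               gap_range = gap_range, day_start = day_start, day = day)
  if (exams_per_scanner == 0L || nrow(scanners) == 0L) {
    attr(empty, "provenance") <- prov
    return(empty)
  }

  with_seed(seed, {
    n_total <- nrow(scanners) * exams_per_scanner
    pool <- sprintf("EMP%04d", seq_len(max(1L, ceiling(0.8 * n_total))))
    rows <- vector("list", n_total)
    k <- 0L
    for (si in seq_len(nrow(scanners))) {
      cursor <- day_open
      for (ei in seq_len(exams_per_scanner)) {
        gap <- if (ei == 1L) 0 else stats::runif(1, gap_range[1], gap_range[2])
        dur <- stats::runif(1, duration_range[1], duration_range[2])
        # whole seconds: header DA/TM values are written at second precision
        start <- round(cursor + 60 * gap, "secs")
        end <- round(start + 60 * dur, "secs")
        if (end > day_close) {
          stop(sprintf(
            "cannot pack %d exams for scanner %s within %s: exam %d would end after midnight",
            exams_per_scanner, scanners$scanner_id[si], format(day), ei))
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          accession = sprintf("ACC%d%04d", seed %% 100L, k),
          empi = sample(pool, 1L),
          scanner_id = scanners$scanner_id[si],
          true_start = start, true_end = end,
          n_series = sample(1:3, 1L),
          instances_per_series = sample(2:4, 1L),
          body_part = sample(.BODY_PARTS, 1L),
          stringsAsFactors = FALSE)
        cursor <- end
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "provenance") <- prov
    out
  })
}

#' Materialize a fleet schedule as DICOM Part 10 instances
#'
#' Writes one file per instance under `out_dir`. Instance acquisition
#' instants are spread evenly across `[true_start, true_end]` (first at the
#' start, last at the end, so min/max over an exam's instances recover the
#' true window), then shifted by the scanner's clock offset before being
#' written to the `StudyDate/Time`, `SeriesDate/Time` and
#' `AcquisitionDate/Time` headers — exactly what a miscalibrated scanner
#' clock does. UIDs are derived deterministically from the schedule's seed
#' under a private root, so fixtures are stable across runs. Instances carry
#' a small 16x16 grayscale ramp payload, identifying (synthetic) patient
#' attributes, and a pair of private tags, so de-identification and
#' PHI-stripping are exercisable.
#'
#' @param exams schedule from [generate_fleet_schedule()].
#' @param scanners the fleet the schedule was generated for.
#' @param out_dir writable output directory (created if missing).
#' @return manifest data frame, one row per written instance: `path`,
#'   identifiers, `scanner_id`, `true_time` (the un-shifted acquisition
#'   instant) and `header_time` (what the file claims).
#' @export
materialize_instances <- function(exams, scanners, out_dir) {
  .validate_fleet(scanners)
  unknown <- setdiff(exams$scanner_id, scanners$scanner_id)
  if (length(unknown)) {
    stop("schedule references unknown scanner_id: ", paste(unknown, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L) {
    stop("output directory not writable: ", out_dir)
  }
  prov <- attr(exams, "provenance")
  seed <- if (is.null(prov)) 0L else prov$seed

  ramp <- as.raw(rep(seq(0L, 255L, length.out = 16L), each = 16L))
  rows <- vector("list", sum(exams$n_series * exams$instances_per_series))
  k <- 0L
  for (xi in seq_len(nrow(exams))) {
    ex <- exams[xi, ]
    sc <- scanners[scanners$scanner_id == ex$scanner_id, ]
    offset <- 60 * sc$clock_offset_min
    study_uid <- paste(UID_ROOT, seed, xi, 0, 0, sep = ".")
    n_total <- ex$n_series * ex$instances_per_series
    instants <- if (n_total == 1L) ex$true_start else
      seq(ex$true_start, ex$true_end, length.out = n_total)
    # floor to whole seconds (header TM precision); endpoints stay exact
    instants <- as.POSIXct(floor(as.numeric(instants)), tz = "UTC",
                           origin = "1970-01-01")
    slot <- 0L
    for (se in seq_len(ex$n_series)) {
      series_uid <- paste(UID_ROOT, seed, xi, se, 0, sep = ".")
      series_true <- instants[slot + 1L]
      for (ii in seq_len(ex$instances_per_series)) {
        slot <- slot + 1L
        sop_uid <- paste(UID_ROOT, seed, xi, se, ii, sep = ".")
        true_t <- instants[slot]
        hdr_t <- true_t + offset
        ds <- list(
          SOPClassUID = SOP_SECONDARY_CAPTURE,
          SOPInstanceUID = sop_uid,
          StudyDate = format_da(ex$true_start + offset),
          StudyTime = format_tm(ex$true_start + offset),
          SeriesDate = format_da(series_true + offset),
          SeriesTime = format_tm(series_true + offset),
          AcquisitionDate = format_da(hdr_t),
          AcquisitionTime = format_tm(hdr_t),
          AccessionNumber = ex$accession,
          Modality = sc$modality,
          Manufacturer = "SYNTHETIC",
          InstitutionName = sc$site_id,
          InstitutionAddress = "1 Synthetic Way",
          ReferringPhysicianName = "DOE^JANE",
          StationName = sc$scanner_id,
          PatientName = paste0("SYNTH^", ex$empi),
          PatientID = ex$empi,
          PatientBirthDate = "19700101",
          BodyPartExamined = ex$body_part,
          DeviceSerialNumber = sc$scanner_id,
          StudyInstanceUID = study_uid,
          SeriesInstanceUID = series_uid,
          SeriesNumber = se,
          InstanceNumber = ii,
          ImageType = c("ORIGINAL", "PRIMARY"),
          SamplesPerPixel = 1L,
          PhotometricInterpretation = "MONOCHROME2",
          Rows = 16L, Columns = 16L,
          BitsAllocated = 8L, BitsStored = 8L, HighBit = 7L,
          PixelRepresentation = 0L,
          PixelData = ramp,
          `(0009,0010)` = "SYNTH PRIVATE",
          `(0009,1001)` = "fixture-marker"
        )
        path <- file.path(out_dir, sprintf("%s_%d_%d_%d.dcm",
                                           sanitize_identifier(ex$accession), xi, se, ii))
        write_dicom(ds, path, private_vrs = c(`(0009,0010)` = "LO",
                                              `(0009,1001)` = "LO"))
        k <- k + 1L
        rows[[k]] <- data.frame(
          path = path, sop_uid = sop_uid, series_uid = series_uid,
          study_uid = study_uid, patient_id = ex$empi, accession = ex$accession,
          scanner_id = ex$scanner_id, series_number = se, instance_number = ii,
          true_time = true_t, header_time = hdr_t, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- prov
  out
}

#' Corrupt a schedule the way hand-entered operational records drift
#'
#' Emulates a clinical data warehouse's human-entered exam times: a fraction
#' `error_rate` of entries get their recorded start/end perturbed by a
#' uniform shift, which can (and for comparison tests, should) create
#' physically impossible overlaps between exams on one scanner.
#'
#' @param exams true schedule from [generate_fleet_schedule()].
#' @param error_rate fraction of entries perturbed, in `[0, 1]`.
#' @param seed integer seed.
#' @param max_shift_min maximum absolute shift, minutes.
#' @return data frame (`accession`, `scanner_id`, `recorded_start`,
#'   `recorded_end`, `perturbed`).
#' @export
corrupt_schedule <- function(exams, error_rate, seed, max_shift_min = 60) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  with_seed(seed, {
    n <- nrow(exams)
    hit <- seq_len(n) %in% sample(n, round(error_rate * n))
    shift_s <- ifelse(hit, 60 * stats::runif(n, -max_shift_min, max_shift_min), 0)
    shift_e <- ifelse(hit, 60 * stats::runif(n, -max_shift_min, max_shift_min), 0)
    out <- data.frame(
      accession = exams$accession, scanner_id = exams$scanner_id,
      recorded_start = exams$true_start + shift_s,
      recorded_end = exams$true_end + shift_e,
      perturbed = hit, stringsAsFactors = FALSE)
    # keep each entry a valid interval; errors move it, never invert it
    flip <- out$recorded_end < out$recorded_start
    tmp <- out$recorded_start[flip]
    out$recorded_start[flip] <- out$recorded_end[flip]
    out$recorded_end[flip] <- tmp
    attr(out, "error_rate") <- error_rate
    out
  })
}
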