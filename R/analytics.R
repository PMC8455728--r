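# Application layer: scanner utilization from exam timestamps, clock-skew
# (miscalibration) detection, schedule-overlap comparison, PNG export and
# de-identification.

# Normalize metadata documents to the flat analytics frame:
# scanner_id, exam_key, instant, full_precision, receipt_time.
# Scanner identity: StationName, falling back to DeviceSerialNumber.
# Exam identity: AccessionNumber, falling back to StudyInstanceUID.
# Timestamp precedence: Acquisition -> Series -> Content date/time.
documents_to_frame <- function(docs, grouping = c("accession", "study")) {
  grouping <- match.arg(grouping)
  one <- function(x) if (is.null(x) || !length(x)) NA_character_ else as.character(x[[1]])
  rows <- lapply(docs, function(d) {
    v <- d$values
    scanner <- one(v$StationName)
    if (is.na(scanner) || !nzchar(scanner)) scanner <- one(v$DeviceSerialNumber)
    exam <- if (grouping == "accession") {
      e <- one(v$AccessionNumber)
      if (is.na(e) || !nzchar(e)) one(v$StudyInstanceUID) else e
    } else one(v$StudyInstanceUID)
    inst <- NA
    full <- FALSE
    for (pair in list(c("AcquisitionDate", "AcquisitionTime"),
                      c("SeriesDate", "SeriesTime"),
                      c("ContentDate", "ContentTime"))) {
      da <- one(v[[pair[1]]]); tm <- one(v[[pair[2]]])
      if (!is.na(da) && grepl("^[0-9]{8}$", da)) {
        p <- tryCatch(parse_dicom_datetime(da, if (is.na(tm)) "" else tm),
                      error = function(e) NULL)
        if (!is.null(p)) { inst <- p; full <- attr(p, "full_precision"); break }
      }
    }
    data.frame(series_uid = d$series_uid,
               scanner_id = if (is.na(scanner)) NA_character_ else scanner,
               exam_key = if (is.na(exam)) NA_character_ else exam,
               instant = if (identical(inst, NA)) as.POSIXct(NA) else as.POSIXct(inst),
               full_precision = full,
               receipt_time = if (is.null(d$receipt_time)) as.POSIXct(NA)
                 else parse_instant(d$receipt_time),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compute exam time windows from metadata documents
#'
#' Groups documents by (scanner, exam) and takes the min/max header
#' acquisition instant as the exam window. Exams are identified by
#' `AccessionNumber` (with `StudyInstanceUID` fallback) or, with
#' `grouping = "study"`, by study. Documents with no scanner identity or no
#' parseable timestamp are excluded and counted in the `excluded` attribute.
#'
#' @param docs metadata documents (e.g. [read_collection()]), whose profile
#'   must include scanner identity and timestamp attributes.
#' @param grouping `"accession"` (default) or `"study"`.
#' @return data frame of windows: `scanner_id`, `exam_key`, `start`, `end`,
#'   `duration_min`, `n_series`; attribute `excluded` counts dropped
#'   documents.
#' @export
compute_exam_windows <- function(docs, grouping = c("accession", "study")) {
  frame <- documents_to_frame(docs, grouping)
  bad <- is.na(frame$scanner_id) | is.na(frame$exam_key) | is.na(frame$instant)
  excluded <- sum(bad)
  frame <- frame[!bad, , drop = FALSE]
  if (!nrow(frame)) {
    out <- data.frame(scanner_id = character(0), exam_key = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      duration_min = numeric(0), n_series = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    return(out)
  }
  sp <- split(frame, paste(frame$scanner_id, frame$exam_key, sep = "\r"))
  rows <- lapply(sp, function(g) {
    data.frame(scanner_id = g$scanner_id[1], exam_key = g$exam_key[1],
               start = min(g$instant), end = max(g$instant),
               duration_min = as.numeric(difftime(max(g$instant), min(g$instant),
                                                  units = "mins")),
               n_series = length(unique(g$series_uid)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scanner_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Detect physically impossible exam overlaps
#'
#' A scanner performs one exam at a time, so two windows of one scanner
#' with a positive-length intersection indicate a recording error. Touching
#' endpoints (one exam ends exactly when the next starts) are not overlaps.
#'
#' @param windows window data frame for ONE scanner (`exam_key`, `start`,
#'   `end`; [compute_exam_windows()] output or a recorded schedule renamed
#'   to those columns).
#' @return data frame of overlapping pairs with the overlap length in
#'   minutes (zero rows if none).
#' @export
detect_overlaps <- function(windows) {
  n <- nrow(windows)
  out <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ov <- as.numeric(difftime(min(windows$end[i], windows$end[j]),
                                  max(windows$start[i], windows$start[j]),
                                  units = "mins"))
        if (ov > 0) {
          out[[length(out) + 1L]] <- data.frame(
            exam_key_1 = windows$exam_key[i], exam_key_2 = windows$exam_key[j],
            overlap_min = ov, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(exam_key_1 = character(0), exam_key_2 = character(0),
                      overlap_min = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Scanner utilization report for one day
#'
#' From one scanner's exam windows: exam durations, idle gaps between
#' consecutive windows, overlap pairs, and the busy fraction of the
#' observed span (first start to last end). When no windows overlap, the
#' durations and idle gaps partition the span exactly.
#'
#' @param windows windows of ONE scanner, one day.
#' @param day the day (`Date` or string), recorded in the report.
#' @return a `utilization_report`: list with `day`, `scanner_id`, `windows`
#'   (sorted by start), `exam_durations_min`, `idle_gaps_min`, `overlaps`,
#'   `busy_fraction`, `span_min`.
#' @export
utilization_report <- function(windows, day) {
  if (!nrow(windows)) {
    return(structure(list(day = as.Date(day), scanner_id = NA_character_,
                          windows = windows, exam_durations_min = numeric(0),
                          idle_gaps_min = numeric(0),
                          overlaps = detect_overlaps(windows),
                          busy_fraction = 0, span_min = 0),
                     class = "utilization_report"))
  }
  stopifnot(length(unique(windows$scanner_id)) == 1L)
  windows <- windows[order(windows$start), , drop = FALSE]
  durations <- as.numeric(difftime(windows$end, windows$start, units = "mins"))
  gaps <- if (nrow(windows) > 1L) {
    g <- as.numeric(difftime(windows$start[-1L],
                             windows$end[-nrow(windows)], units = "mins"))
    g[g > 0]
  } else numeric(0)
  span <- as.numeric(difftime(max(windows$end), min(windows$start), units = "mins"))
  structure(list(
    day = as.Date(day), scanner_id = windows$scanner_id[1], windows = windows,
    exam_durations_min = durations, idle_gaps_min = gaps,
    overlaps = detect_overlaps(windows),
    busy_fraction = if (span > 0) sum(durations) / span else 1,
    span_min = span), class = "utilization_report")
}

#' @export
print.utilization_report <- function(x, ...) {
  cat(sprintf("Scanner %s on %s: %d exams, busy %.1f%% of a %.0f-min span\n",
              x$scanner_id, format(x$day), nrow(x$windows),
              100 * x$busy_fraction, x$span_min))
  cat(sprintf("  exam durations (min): %s\n",
              paste(sprintf("%.1f", x$exam_durations_min), collapse = ", ")))
  cat(sprintf("  idle gaps (min): %s\n",
              paste(sprintf("%.1f", x$idle_gaps_min), collapse = ", ")))
  if (nrow(x$overlaps)) cat(sprintf("  WARNING: %d overlapping pair(s)\n",
                                    nrow(x$overlaps)))
  invisible(x)
}

#' Clock-skew report: find scanners with miscalibrated clocks
#'
#' For every document, the skew is the receipt time at the research store
#' minus the header acquisition instant; network transfer and extraction add
#' a small positive delay, while a clock set ahead by `o` minutes shifts the
#' skew by `-o`. Per scanner, the median skew is compared to the threshold:
#' a scanner is flagged iff |median skew| exceeds it, so a single delayed
#' image never flags a scanner. The default threshold is 20 minutes, the
#' allowance for network transfer plus metadata extraction. Date-only
#' (low-precision) timestamps are excluded; a scanner with no usable
#' timestamp is reported unassessable (`flagged = NA`).
#'
#' @param docs metadata documents whose profile includes scanner identity
#'   and acquisition timestamps (receipt time is stamped by the extractor).
#' @param threshold_min flagging threshold, minutes.
#' @return data frame per scanner: `scanner_id`, `n_instances`, `n_usable`,
#'   `median_skew_min`, `n_exceeding` (documents individually beyond the
#'   threshold), `flagged`; attribute `threshold_min`.
#' @export
clock_skew_report <- function(docs, threshold_min = 20) {
  frame <- documents_to_frame(docs)
  frame <- frame[!is.na(frame$scanner_id), , drop = FALSE]
  sp <- split(frame, frame$scanner_id)
  rows <- lapply(sp, function(g) {
    usable <- !is.na(g$instant) & g$full_precision & !is.na(g$receipt_time)
    skews <- as.numeric(difftime(g$receipt_time[usable], g$instant[usable],
                                 units = "mins"))
    if (!length(skews)) {
      return(data.frame(scanner_id = g$scanner_id[1], n_instances = nrow(g),
                        n_usable = 0L, median_skew_min = NA_real_,
                        n_exceeding = NA_integer_, flagged = NA,
                        stringsAsFactors = FALSE))
    }
    med <- stats::median(skews)
    data.frame(scanner_id = g$scanner_id[1], n_instances = nrow(g),
               n_usable = length(skews), median_skew_min = med,
               n_exceeding = sum(abs(skews) > threshold_min),
               flagged = abs(med) > threshold_min, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold_min") <- threshold_min
  out
}

#' Export a DICOM instance to 8-bit grayscale PNG
#'
#' Applies `WindowCenter`/`WindowWidth` when present, min-max scaling
#' otherwise; MONOCHROME1 images are inverted so air is dark either way.
#' The PNG carries pixels only — no DICOM header survives, which is why the
#' export is fit for sharing with ML pipelines.
#'
#' @param file DICOM instance path.
#' @param out output PNG path.
#' @return `out`, invisibly.
#' @export
dicom_to_png <- function(file, out) {
  ds <- read_dicom(file)
  if (is.null(ds$PixelData) || !length(ds$PixelData)) {
    stop("no decodable pixel data in ", file, " (transfer syntax ",
         attr(ds, "transfer_syntax"), ")")
  }
  rows <- ds$Rows; cols <- ds$Columns
  bits <- if (is.null(ds$BitsAllocated)) 8L else ds$BitsAllocated
  px <- if (bits == 8L) {
    as.numeric(as.integer(ds$PixelData))
  } else if (bits == 16L) {
    as.numeric(readBin(ds$PixelData, integer(), n = length(ds$PixelData) %/% 2L,
                       size = 2L, signed = FALSE, endian = "little"))
  } else stop("unsupported BitsAllocated: ", bits)
  px <- px[seq_len(rows * cols)]
  wc <- ds$WindowCenter[1]; ww <- ds$WindowWidth[1]
  if (!is.null(wc) && !is.null(ww) && is.finite(wc) && is.finite(ww) && ww > 0) {
    lo <- wc - ww / 2; hi <- wc + ww / 2
    px <- pmin(pmax(px, lo), hi)
    px <- (px - lo) / (hi - lo)
  } else {
    rng <- range(px)
    px <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
  }
  if (identical(toupper(ds$PhotometricInterpretation), "MONOCHROME1")) {
    px <- 1 - px
  }
  m <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(m, out)
  invisible(out)
}

# -- de-identification ------------------------------------------------------

# Attributes every de-identified instance keeps regardless of the whitelist:
# enough to remain a valid, renderable Part 10 image object.
.DEID_MANDATORY <- c("SOPClassUID", "SOPInstanceUID", "StudyInstanceUID",
                     "SeriesInstanceUID", "SamplesPerPixel",
                     "PhotometricInterpretation", "Rows", "Columns",
                     "BitsAllocated", "BitsStored", "HighBit",
                     "PixelRepresentation", "PixelData")
.DEID_REMAP_UIDS <- c("SOPInstanceUID", "StudyInstanceUID", "SeriesInstanceUID")

#' Open (or create) a persistent UID map for de-identification
#'
#' Maps original UIDs to replacement UIDs under the private root, stored as
#' JSON so the same study/series keeps the same replacement across files
#' and runs — linkage survives, the original UIDs do not leave.
#'
#' @param path JSON file path.
#' @return a `uid_map` handle.
#' @export
uid_map <- function(path) {
  map <- if (file.exists(path)) {
    unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else c(`__counter__` = "0")
  if (!"__counter__" %in% names(map)) map["__counter__"] <- "0"
  env <- new.env(parent = emptyenv())
  env$map <- map
  env$path <- path
  structure(env, class = "uid_map")
}

.remap_uid <- function(um, uid) {
  if (!is.null(unname(um$map[uid])) && !is.na(um$map[uid])) return(unname(um$map[uid]))
  counter <- as.integer(um$map[["__counter__"]]) + 1L
  new <- paste(UID_ROOT, "9", counter, sep = ".")
  um$map[uid] <- new
  um$map[["__counter__"]] <- as.character(counter)
  jsonlite::write_json(as.list(um$map), um$path, auto_unbox = TRUE)
  new
}

#' De-identify a DICOM instance
#'
#' Writes a new Part 10 file containing ONLY the whitelisted attributes,
#' freshly remapped UIDs (consistent through the persistent [uid_map()], so
#' study/series linkage survives), and the minimum attributes a valid image
#' object needs. Pixel data is preserved bit-exact. A whitelist naming a
#' PHI attribute is refused before anything is written.
#'
#' @param file input instance.
#' @param out output path.
#' @param keep attribute keywords to retain (non-empty; must not intersect
#'   the PHI list).
#' @param um a [uid_map()].
#' @param phi_exclusion PHI list the whitelist is checked against.
#' @return `out`, invisibly.
#' @export
deidentify <- function(file, out, keep, um,
                       phi_exclusion = default_phi_list()) {
  stopifnot(length(keep) > 0)
  banned <- intersect(keep, phi_exclusion)
  if (length(banned)) {
    stop("whitelist contains PHI attribute(s): ", paste(banned, collapse = ", "))
  }
  ds <- read_dicom(file)
  keep_all <- union(keep, .DEID_MANDATORY)
  new_ds <- ds[intersect(keep_all, names(ds))]
  for (u in intersect(.DEID_REMAP_UIDS, names(new_ds))) {
    new_ds[[u]] <- .remap_uid(um, new_ds[[u]])
  }
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write_dicom(new_ds, out)
  invisible(out)
}
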