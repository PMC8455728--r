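# Real-time path: a storage-class listener per configured source accepts
# C-STORE datasets, files them into a hierarchical store
# (patient/study/series/instance.dcm by default) and appends one record per
# instance to a durable ingestion index. Receipt time is assigned by the
# listener at store time, never read from headers.

.INDEX_FILE <- "ingestion_index.tsv"
.INDEX_COLS <- c("sop_uid", "series_uid", "study_uid", "patient_id", "accession",
                 "path", "receipt_time", "acquisition_date", "acquisition_time",
                 "series_date", "series_time", "station_name", "device_serial",
                 "modality", "body_part")

#' Configure one ingestion source
#'
#' One source corresponds to one PACS sending to one listener endpoint
#' (AE title + port) with its own storage root.
#'
#' @param name source name.
#' @param ae_title listener application entity title.
#' @param port listener port (must be unique across sources).
#' @param storage_root directory the source's instances are filed under.
#' @param folder_depth storage hierarchy: `"patient"`, `"patient/study"`, or
#'   the default `"patient/study/series"`.
#' @return a `source_config` list.
#' @export
source_config <- function(name, ae_title, port, storage_root,
                          folder_depth = c("patient/study/series",
                                           "patient/study", "patient")) {
  folder_depth <- match.arg(folder_depth)
  stopifnot(is.numeric(port), length(port) == 1L)
  structure(list(name = name, ae_title = ae_title, port = as.integer(port),
                 storage_root = storage_root, folder_depth = folder_depth),
            class = "source_config")
}

#' Resolve the storage path for an instance
#'
#' Pure function of the identifiers and the configured hierarchy depth.
#' Identifier characters outside `[A-Za-z0-9.-]` are replaced by underscore;
#' a missing patient or study identifier files the instance under an
#' `UNKNOWN` bucket rather than rejecting it (real scanners emit incomplete
#' headers), but an instance without a `SOPInstanceUID` cannot be filed.
#'
#' @param patient_id,study_uid,series_uid,sop_uid instance identifiers.
#' @param folder_depth hierarchy depth (see [source_config()]).
#' @return storage-relative path ending in `<sop_uid>.dcm`.
#' @export
#' @examples
#' resolve_storage_path("P1", "ST1", "SE1", "I1")
resolve_storage_path <- function(patient_id, study_uid, series_uid, sop_uid,
                                 folder_depth = "patient/study/series") {
  if (is.null(sop_uid) || is.na(sop_uid) || !nzchar(sop_uid)) {
    stop("cannot file an instance without a SOPInstanceUID")
  }
  bucket <- function(x) {
    if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x)) "UNKNOWN"
    else sanitize_identifier(x)
  }
  parts <- switch(folder_depth,
    "patient" = bucket(patient_id),
    "patient/study" = c(bucket(patient_id), bucket(study_uid)),
    "patient/study/series" = c(bucket(patient_id), bucket(study_uid), bucket(series_uid)),
    stop("unknown folder_depth: ", folder_depth))
  do.call(file.path, as.list(c(parts, paste0(sanitize_identifier(sop_uid), ".dcm"))))
}

.first_or_empty <- function(x) {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) "" else as.character(x[1])
}

#' Start an ingestion listener
#'
#' Returns an in-process storage service object for one source. Its
#' `$c_store(bytes, receipt_time)` handler accepts one DICOM instance as raw
#' Part 10 bytes (or a file path), files it under the source's storage root
#' and appends an index record stamped with the receipt time — by default
#' the wall clock; tests and simulations may inject a clock. A malformed
#' dataset is refused with a DIMSE-style failure status and leaves no
#' partial file. Re-storing a `SOPInstanceUID` overwrites the file and
#' supersedes the index record (last write wins).
#'
#' @param config a [source_config()].
#' @return listener object (list with `$config`, `$c_store`, `$received`).
#' @export
start_listener <- function(config) {
  stopifnot(inherits(config, "source_config"))
  dir.create(config$storage_root, recursive = TRUE, showWarnings = FALSE)
  index_path <- file.path(config$storage_root, .INDEX_FILE)
  if (!file.exists(index_path)) {
    cat(paste(.INDEX_COLS, collapse = "\t"), "\n", sep = "", file = index_path)
  }

  c_store <- function(bytes, receipt_time = Sys.time()) {
    src <- NULL
    if (is.character(bytes)) {
      src <- bytes
      bytes <- readBin(bytes, raw(), n = file.size(bytes))
    }
    tmp <- tempfile(fileext = ".dcm")
    writeBin(bytes, tmp)
    ds <- tryCatch(read_dicom(tmp, skip_pixels = TRUE), error = function(e) e)
    if (inherits(ds, "error")) {
      unlink(tmp)
      message("C-STORE refused (", config$name, "): ", conditionMessage(ds))
      return(list(status = 0xC000L, message = conditionMessage(ds)))
    }
    rel <- resolve_storage_path(.first_or_empty(ds$PatientID),
                                .first_or_empty(ds$StudyInstanceUID),
                                .first_or_empty(ds$SeriesInstanceUID),
                                .first_or_empty(ds$SOPInstanceUID),
                                config$folder_depth)
    dest <- file.path(config$storage_root, rel)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    ok <- file.copy(tmp, dest, overwrite = TRUE)
    unlink(tmp)
    if (!ok) return(list(status = 0xA700L, message = "storage write failed"))
    rec <- c(.first_or_empty(ds$SOPInstanceUID), .first_or_empty(ds$SeriesInstanceUID),
             .first_or_empty(ds$StudyInstanceUID), .first_or_empty(ds$PatientID),
             .first_or_empty(ds$AccessionNumber), rel,
             format_instant(receipt_time),
             .first_or_empty(ds$AcquisitionDate), .first_or_empty(ds$AcquisitionTime),
             .first_or_empty(ds$SeriesDate), .first_or_empty(ds$SeriesTime),
             .first_or_empty(ds$StationName), .first_or_empty(ds$DeviceSerialNumber),
             .first_or_empty(ds$Modality), .first_or_empty(ds$BodyPartExamined))
    cat(paste(rec, collapse = "\t"), "\n", sep = "", file = index_path, append = TRUE)
    list(status = 0x0000L, sop_uid = .first_or_empty(ds$SOPInstanceUID), path = rel)
  }

  structure(list(config = config, c_store = c_store, index_path = index_path),
            class = "dicom_listener")
}

#' Start several listeners, enforcing cross-source invariants
#'
#' Ports must be unique across sources (one listener endpoint per PACS) and
#' storage roots must be distinct.
#'
#' @param configs list of [source_config()] objects.
#' @return list of listener objects, named by source name.
#' @export
start_listeners <- function(configs) {
  ports <- vapply(configs, function(cf) cf$port, integer(1))
  roots <- vapply(configs, function(cf) cf$storage_root, character(1))
  if (anyDuplicated(ports)) stop("listener ports must be unique across sources")
  if (anyDuplicated(roots)) stop("storage roots must be distinct across sources")
  out <- lapply(configs, start_listener)
  names(out) <- vapply(configs, function(cf) cf$name, character(1))
  out
}

#' Read the ingestion index
#'
#' The index is an append-only log; a re-stored instance appends a new line,
#' and this reader collapses the log to its current view: one record per
#' `SOPInstanceUID`, keeping the latest.
#'
#' @param storage_root the source's storage root.
#' @return data frame of instance records (zero rows if nothing ingested),
#'   with `receipt_time` parsed to `POSIXct`.
#' @export
read_ingestion_index <- function(storage_root) {
  path <- file.path(storage_root, .INDEX_FILE)
  if (!file.exists(path)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(.INDEX_COLS)),
                                 .INDEX_COLS), stringsAsFactors = FALSE)
    df$receipt_time <- as.POSIXct(character(0), tz = "UTC")
    return(df)
  }
  df <- utils::read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(df)) df <- df[!duplicated(df$sop_uid, fromLast = TRUE), , drop = FALSE]
  df$receipt_time <- parse_instant(df$receipt_time)
  rownames(df) <- NULL
  df
}

#' Reconcile storage with the ingestion index after a crash
#'
#' A crash between writing an instance file and appending its index record
#' leaves an orphan file. This startup sweep walks the storage tree, parses
#' any `.dcm` file whose `SOPInstanceUID` is absent from the index, and
#' appends a record for it (receipt time taken from the file's modification
#' time, the best available bound).
#'
#' @param listener a listener object from [start_listener()].
#' @return number of orphan files reconciled.
#' @export
reconcile_index <- function(listener) {
  root <- listener$config$storage_root
  idx <- read_ingestion_index(root)
  files <- list.files(root, pattern = "\\.dcm$", recursive = TRUE, full.names = TRUE)
  n <- 0L
  for (f in files) {
    ds <- tryCatch(read_dicom(f, skip_pixels = TRUE), error = function(e) NULL)
    if (is.null(ds)) next
    sop <- .first_or_empty(ds$SOPInstanceUID)
    if (!sop %in% idx$sop_uid) {
      listener$c_store(f, receipt_time = file.mtime(f))
      n <- n + 1L
    }
  }
  n
}
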