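# Embedded mock PACS: an in-process query/retrieve service over a directory
# of Part 10 files. It answers Study-Root STUDY-level C-FIND on PatientID,
# AccessionNumber and StudyDate, and C-MOVE by pushing matching instances
# via C-STORE to a registered destination AE. A fault-injection mode fails
# every k-th C-MOVE so retry logic is testable. This is a service double
# with DIMSE semantics (statuses, AE registry), not a network endpoint.

# DIMSE-style status codes used by the mock.
DIMSE_SUCCESS <- 0x0000L
DIMSE_MOVE_DEST_UNKNOWN <- 0xA801L
DIMSE_UNABLE_TO_PROCESS <- 0xC000L

#' Serve a DICOM archive through an embedded mock PACS
#'
#' Scans `archive_dir` for Part 10 files, builds a study/instance index,
#' and returns a service object:
#'
#' * `$c_find(identifier)` — STUDY-level query; `identifier` is a named list
#'   of exact-match keys among `PatientID`, `AccessionNumber`, `StudyDate`,
#'   `StudyInstanceUID`. Returns a data frame of matching studies (always
#'   including `StudyInstanceUID`); zero matches is a success, not an error.
#' * `$c_move(identifier, dest_ae)` — sends every instance of every matching
#'   study to the destination's `c_store` handler; unknown destinations get
#'   a move-destination-unknown failure status.
#' * `$register_destination(ae_title, listener)` — adds a C-MOVE destination.
#'
#' @param archive_dir directory of `.dcm` files (recursively scanned).
#' @param fail_every_k if positive, every k-th C-MOVE call fails with a
#'   unable-to-process status before sending anything (fault injection for
#'   retry tests).
#' @param receipt_clock optional function `(instance index row) -> POSIXct`
#'   giving the receipt time stamped by the destination listener; default
#'   `NULL` lets the listener use its wall clock.
#' @return a `mock_pacs` service object.
#' @export
mock_pacs_serve <- function(archive_dir, fail_every_k = 0L, receipt_clock = NULL) {
  files <- list.files(archive_dir, pattern = "\\.dcm$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("archive contains no DICOM files: ", archive_dir)
  recs <- lapply(files, function(f) {
    ds <- read_dicom(f, skip_pixels = TRUE)
    data.frame(path = f,
               sop_uid = .first_or_empty(ds$SOPInstanceUID),
               series_uid = .first_or_empty(ds$SeriesInstanceUID),
               study_uid = .first_or_empty(ds$StudyInstanceUID),
               patient_id = .first_or_empty(ds$PatientID),
               accession = .first_or_empty(ds$AccessionNumber),
               study_date = .first_or_empty(ds$StudyDate),
               acq_date = .first_or_empty(ds$AcquisitionDate),
               acq_time = .first_or_empty(ds$AcquisitionTime),
               stringsAsFactors = FALSE)
  })
  index <- do.call(rbind, recs)

  state <- new.env(parent = emptyenv())
  state$destinations <- list()
  state$move_count <- 0L

  match_studies <- function(identifier) {
    keep <- rep(TRUE, nrow(index))
    keymap <- c(PatientID = "patient_id", AccessionNumber = "accession",
                StudyDate = "study_date", StudyInstanceUID = "study_uid")
    for (key in names(identifier)) {
      col <- keymap[[key]]
      if (is.null(col)) next  # unsupported keys are universal matches
      val <- identifier[[key]]
      if (is.null(val) || !nzchar(val)) next
      keep <- keep & index[[col]] == val
    }
    index[keep, , drop = FALSE]
  }

  c_find <- function(identifier) {
    hits <- match_studies(identifier)
    if (!nrow(hits)) {
      return(list(status = DIMSE_SUCCESS,
                  studies = data.frame(StudyInstanceUID = character(0),
                                       PatientID = character(0),
                                       AccessionNumber = character(0),
                                       StudyDate = character(0),
                                       n_instances = integer(0),
                                       stringsAsFactors = FALSE)))
    }
    sp <- split(hits, hits$study_uid)
    studies <- do.call(rbind, lapply(sp, function(h) {
      data.frame(StudyInstanceUID = h$study_uid[1], PatientID = h$patient_id[1],
                 AccessionNumber = h$accession[1], StudyDate = h$study_date[1],
                 n_instances = nrow(h), stringsAsFactors = FALSE)
    }))
    rownames(studies) <- NULL
    list(status = DIMSE_SUCCESS, studies = studies)
  }

  c_move <- function(identifier, dest_ae) {
    state$move_count <- state$move_count + 1L
    if (fail_every_k > 0L && state$move_count %% fail_every_k == 0L) {
      return(list(status = DIMSE_UNABLE_TO_PROCESS, completed = 0L, failed = 0L,
                  message = "injected fault"))
    }
    dest <- state$destinations[[dest_ae]]
    if (is.null(dest)) {
      return(list(status = DIMSE_MOVE_DEST_UNKNOWN, completed = 0L, failed = 0L,
                  message = paste("unknown move destination:", dest_ae)))
    }
    hits <- match_studies(identifier)
    completed <- 0L; failed <- 0L
    for (i in seq_len(nrow(hits))) {
      rt <- if (is.null(receipt_clock)) Sys.time() else receipt_clock(hits[i, ])
      res <- dest$c_store(readBin(hits$path[i], raw(), n = file.size(hits$path[i])),
                          receipt_time = rt)
      if (identical(res$status, DIMSE_SUCCESS)) completed <- completed + 1L
      else failed <- failed + 1L
    }
    list(status = if (failed == 0L) DIMSE_SUCCESS else DIMSE_UNABLE_TO_PROCESS,
         completed = completed, failed = failed)
  }

  register_destination <- function(ae_title, listener) {
    state$destinations[[ae_title]] <- listener
    invisible(ae_title)
  }

  structure(list(index = index, c_find = c_find, c_move = c_move,
                 register_destination = register_destination,
                 archive_dir = archive_dir),
            class = "mock_pacs")
}
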