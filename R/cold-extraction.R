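# On-demand path: parse a query CSV in one of four shapes, expand each row
# into a C-FIND-filtered set of per-study C-MOVEs, with retry, a failures
# CSV, and halt-and-resume progress persisted after every query.

.QUERY_SHAPES <- list(
  EMPI = c("EMPI"),
  EMPI_ACCESSION = c("EMPI", "Accession"),
  ACCESSION = c("Accession"),
  EMPI_STUDYDATE = c("EMPI", "StudyDate")
)

#' Parse an on-demand query CSV
#'
#' The CSV must carry a header row matching the declared shape: `EMPI`,
#' `{EMPI, Accession}`, `Accession`, or `{EMPI, StudyDate}`. Duplicate rows
#' are collapsed; malformed rows (empty fields, non-`YYYYMMDD` study dates)
#' are dropped with a warning naming their row numbers.
#'
#' @param file CSV path.
#' @param shape one of `"EMPI"`, `"EMPI_ACCESSION"`, `"ACCESSION"`,
#'   `"EMPI_STUDYDATE"`.
#' @return data frame of query specs (`shape`, `empi`, `accession`,
#'   `study_date`, `key`); zero rows for an empty file.
#' @export
parse_query_csv <- function(file, shape = names(.QUERY_SHAPES)) {
  shape <- match.arg(shape)
  expected <- .QUERY_SHAPES[[shape]]
  if (!file.exists(file)) stop("query CSV not found: ", file)
  df <- utils::read.csv(file, colClasses = "character", stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!identical(trimws(names(df)), expected)) {
    stop("query CSV header does not match shape ", shape,
         "; expected columns: ", paste(expected, collapse = ", "),
         " but found: ", paste(names(df), collapse = ", "))
  }
  if (!nrow(df)) return(.empty_query_specs(shape))
  df[] <- lapply(df, trimws)
  bad <- !stats::complete.cases(df) | apply(df == "", 1L, any)
  if ("StudyDate" %in% names(df)) {
    bad <- bad | !grepl("^[0-9]{8}$", df$StudyDate)
  }
  if (any(bad)) {
    warning("dropping malformed query rows: ", paste(which(bad), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  df <- unique(df)
  out <- data.frame(
    shape = rep(shape, nrow(df)),
    empi = if ("EMPI" %in% names(df)) df$EMPI else NA_character_,
    accession = if ("Accession" %in% names(df)) df$Accession else NA_character_,
    study_date = if ("StudyDate" %in% names(df)) df$StudyDate else NA_character_,
    stringsAsFactors = FALSE)
  out$key <- query_key(out)
  rownames(out) <- NULL
  out
}

.empty_query_specs <- function(shape) {
  data.frame(shape = character(0), empi = character(0), accession = character(0),
             study_date = character(0), key = character(0), stringsAsFactors = FALSE)
}

#' Stable key identifying one query spec
#' @param specs query spec data frame.
#' @return character vector of keys.
#' @export
query_key <- function(specs) {
  paste(specs$shape,
        ifelse(is.na(specs$empi), "", specs$empi),
        ifelse(is.na(specs$accession), "", specs$accession),
        ifelse(is.na(specs$study_date), "", specs$study_date),
        sep = "|")
}

#' Map a query spec to a STUDY-level C-FIND identifier
#'
#' EMPI maps to `PatientID` (all studies of the patient), accession to
#' `AccessionNumber`, and the `{EMPI, StudyDate}` shape to both keys.
#'
#' @param spec one-row query spec data frame.
#' @return named list of exact-match query keys.
#' @export
to_find_identifier <- function(spec) {
  stopifnot(nrow(spec) == 1L)
  switch(spec$shape,
    EMPI = list(PatientID = spec$empi),
    ACCESSION = list(AccessionNumber = spec$accession),
    EMPI_ACCESSION = list(PatientID = spec$empi, AccessionNumber = spec$accession),
    EMPI_STUDYDATE = list(PatientID = spec$empi, StudyDate = spec$study_date),
    stop("invalid query shape: ", spec$shape))
}

# -- retrieval progress: newline-delimited key files, atomic rename ---------

#' Load halt-and-resume retrieval progress
#' @param dir progress directory (created on first persist).
#' @return list with `completed` and `failed` key sets.
#' @export
load_progress <- function(dir) {
  list(completed = read_set_file(file.path(dir, "completed.keys")),
       failed = read_set_file(file.path(dir, "failed.keys")))
}

.persist_progress <- function(progress, dir) {
  atomic_write_lines(progress$completed, file.path(dir, "completed.keys"))
  atomic_write_lines(progress$failed, file.path(dir, "failed.keys"))
  invisible(progress)
}

#' Run a batch retrieval against a PACS
#'
#' For every query spec not already completed (or terminally failed) in the
#' persisted progress: run one C-FIND, then one C-MOVE per matching study to
#' `dest_ae`. A C-MOVE failure is retried up to `max_retries` times; terminal
#' failures are appended to `failures.csv` in the progress directory.
#' Progress is persisted after every spec, so a restart skips completed
#' specs exactly and each spec reaches the PACS at most `1 + max_retries`
#' times across any crash/restart sequence.
#'
#' @param specs query specs from [parse_query_csv()].
#' @param pacs a PACS service object (e.g. [mock_pacs_serve()]).
#' @param dest_ae destination AE title (must be registered with the PACS and
#'   backed by a running listener).
#' @param progress_dir directory for progress and failure files.
#' @param max_retries extra attempts per failed C-MOVE (default 2).
#' @param inter_query_delay seconds to sleep between specs (default 0;
#'   PACS-side throttling is the norm, so no client parallelism).
#' @param on_spec_complete optional callback `function(key)` invoked after a
#'   spec's progress is persisted; used by halt-and-resume tests to
#'   simulate crashes at spec boundaries.
#' @return report data frame: `key`, `status` (`completed`, `no_match`,
#'   `failed`), `n_studies`, `attempts`.
#' @export
run_batch_retrieval <- function(specs, pacs, dest_ae, progress_dir,
                                max_retries = 2L, inter_query_delay = 0,
                                on_spec_complete = NULL) {
  if (is.null(pacs) || !inherits(pacs, "mock_pacs")) {
    stop("PACS endpoint unreachable or invalid; progress left intact")
  }
  progress <- load_progress(progress_dir)
  report <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, , drop = FALSE]
    key <- spec$key
    if (key %in% progress$completed || key %in% progress$failed) next
    identifier <- to_find_identifier(spec)
    found <- pacs$c_find(identifier)
    studies <- found$studies
    attempts <- 0L
    spec_failed <- FALSE
    last_status <- DIMSE_SUCCESS
    for (s in seq_len(nrow(studies))) {
      move_id <- list(StudyInstanceUID = studies$StudyInstanceUID[s])
      ok <- FALSE
      for (try_n in seq_len(1L + max_retries)) {
        attempts <- attempts + 1L
        res <- pacs$c_move(move_id, dest_ae)
        last_status <- res$status
        if (identical(res$status, DIMSE_SUCCESS)) { ok <- TRUE; break }
      }
      if (!ok) { spec_failed <- TRUE; break }
    }
    status <- if (spec_failed) "failed"
      else if (nrow(studies) == 0L) "no_match" else "completed"
    if (spec_failed) {
      progress$failed <- union(progress$failed, key)
      fcsv <- file.path(progress_dir, "failures.csv")
      dir.create(progress_dir, recursive = TRUE, showWarnings = FALSE)
      line <- data.frame(key = key, attempts = attempts,
                         last_status = sprintf("0x%04X", last_status))
      utils::write.table(line, fcsv, sep = ",", row.names = FALSE,
                         col.names = !file.exists(fcsv), append = file.exists(fcsv),
                         quote = FALSE)
    } else {
      progress$completed <- union(progress$completed, key)
    }
    .persist_progress(progress, progress_dir)
    report[[key]] <- data.frame(key = key, status = status,
                                n_studies = nrow(studies), attempts = attempts,
                                stringsAsFactors = FALSE)
    if (!is.null(on_spec_complete)) on_spec_complete(key)
    if (inter_query_delay > 0) Sys.sleep(inter_query_delay)
  }
  out <- if (length(report)) do.call(rbind, report) else
    data.frame(key = character(0), status = character(0),
               n_studies = integer(0), attempts = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
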