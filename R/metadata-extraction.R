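# Polling metadata extractor: traverse the ingestion index, pick one
# representative instance per new series, extract profile-defined PHI-free
# attributes, and upsert one JSON document per (series, profile) into
# per-profile collections, with crash-safe progress.

#' Default PHI exclusion list
#'
#' Directly identifying attributes, modeled on the DICOM Basic
#' Confidentiality Profile. `PatientID` and `AccessionNumber` are retained
#' by default because cohort workflows key on them; pass a longer list to
#' drop them for shared collections.
#'
#' @return character vector of attribute keywords.
#' @export
default_phi_list <- function() {
  c("PatientName", "PatientBirthDate", "PatientAddress", "OtherPatientIDs",
    "ReferringPhysicianName", "InstitutionAddress")
}

#' Load extraction profiles from a directory
#'
#' One profile per `.txt` file: the filename (without extension) is the
#' profile/collection name; each non-blank line is one DICOM attribute
#' keyword; `#` starts a comment. Attributes on the PHI exclusion list are
#' removed with a warning; unknown keywords are kept with a warning
#' (extraction simply yields no value for them). New files are picked up
#' whenever this is called, so profiles can be added at run time without a
#' restart.
#'
#' @param dir profiles directory.
#' @param phi_exclusion PHI attribute keywords to strip from every profile.
#' @return list of profiles, each `list(name, attributes)`.
#' @export
load_profiles <- function(dir, phi_exclusion = default_phi_list()) {
  if (!dir.exists(dir)) stop("profiles directory does not exist: ", dir)
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  profiles <- lapply(files, function(f) {
    lines <- readLines(f, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    attrs <- lines[nzchar(lines)]
    phi <- intersect(attrs, phi_exclusion)
    if (length(phi)) {
      warning("profile ", basename(f), ": dropping PHI attributes: ",
              paste(phi, collapse = ", "))
      attrs <- setdiff(attrs, phi)
    }
    unknown <- attrs[!vapply(attrs, is_known_keyword, logical(1))]
    if (length(unknown)) {
      warning("profile ", basename(f), ": unknown attribute keywords kept: ",
              paste(unknown, collapse = ", "))
    }
    if (!length(attrs)) stop("profile ", basename(f), " has no attributes")
    list(name = tools::file_path_sans_ext(basename(f)), attributes = attrs)
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  if (anyDuplicated(names(profiles))) stop("profile names must be unique")
  profiles
}

#' Select representative instances of a series
#'
#' The default extracts metadata from only one image per series (the first);
#' `first_middle_last` and `all` widen that. Ordering is by `InstanceNumber`
#' with ties and missing numbers broken by lexicographic `SOPInstanceUID`.
#'
#' @param records data frame of instance records for ONE series (from
#'   [read_ingestion_index()] or a manifest); needs `sop_uid` and, if
#'   available, `instance_number`.
#' @param mode `"first"` (default), `"first_middle_last"`, or `"all"`.
#' @return subset of `records` (deduplicated for short series).
#' @export
select_representative <- function(records, mode = c("first", "first_middle_last", "all")) {
  mode <- match.arg(mode)
  if (!nrow(records)) stop("cannot select a representative of an empty series")
  inum <- if ("instance_number" %in% names(records)) {
    suppressWarnings(as.numeric(records$instance_number))
  } else rep(NA_real_, nrow(records))
  inum[is.na(inum)] <- Inf
  ord <- order(inum, records$sop_uid)
  records <- records[ord, , drop = FALSE]
  n <- nrow(records)
  idx <- switch(mode,
    first = 1L,
    first_middle_last = unique(c(1L, as.integer(ceiling(n / 2)), n)),
    all = seq_len(n))
  records[idx, , drop = FALSE]
}

#' Extract one metadata document from an instance file
#'
#' Reads the header (pixel data skipped), keeps the profile's attributes
#' that are present (absent attributes are omitted, not null-filled),
#' enforces the PHI exclusion list, and stamps the record's receipt time.
#' Multi-valued attributes are preserved as lists in order.
#'
#' @param file instance file path.
#' @param record the instance's index record (one row; needs `series_uid`,
#'   `receipt_time`).
#' @param profile a profile from [load_profiles()].
#' @param phi_exclusion PHI list enforced on output.
#' @return a metadata document: `list(series_uid, profile, receipt_time,
#'   values)`.
#' @export
extract_document <- function(file, record, profile,
                             phi_exclusion = default_phi_list()) {
  ds <- read_dicom(file, skip_pixels = TRUE)
  wanted <- setdiff(profile$attributes, phi_exclusion)
  values <- ds[intersect(wanted, names(ds))]
  list(series_uid = record$series_uid[1],
       profile = profile$name,
       receipt_time = format_instant(record$receipt_time[1]),
       values = values)
}

# -- file-backed document store --------------------------------------------

#' Open a document store
#'
#' Collections are directories named by profile; documents are one JSON
#' file per series, so an upsert is an atomic overwrite and document counts
#' are exactly the distinct series counts.
#'
#' @param root store root directory (created if missing).
#' @return a `doc_store` handle.
#' @export
doc_store <- function(root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  structure(list(root = root), class = "doc_store")
}

#' Upsert a metadata document
#' @param store a [doc_store()].
#' @param doc document from [extract_document()].
#' @return invisibly, the document's path.
#' @export
upsert_document <- function(store, doc) {
  dir <- file.path(store$root, sanitize_identifier(doc$profile))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(sanitize_identifier(doc$series_uid), ".json"))
  tmp <- paste0(path, ".tmp.", Sys.getpid())
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' Read all documents of a collection
#' @param store a [doc_store()].
#' @param profile collection (profile) name.
#' @return list of documents (empty if the collection does not exist).
#' @export
read_collection <- function(store, profile) {
  dir <- file.path(store$root, sanitize_identifier(profile))
  if (!dir.exists(dir)) return(list())
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  lapply(files, function(f) jsonlite::read_json(f, simplifyVector = FALSE))
}

# -- extraction state & cycle ----------------------------------------------

#' Extractor configuration defaults
#'
#' The extractor polls every 10 minutes by default; it can instead be
#' triggered per arrival (`mode = "event"`). One representative image per
#' series is extracted by default.
#'
#' @param interval_minutes polling interval.
#' @param trigger `"interval"` or `"event"`.
#' @param representative see [select_representative()].
#' @return configuration list.
#' @export
extraction_config <- function(interval_minutes = 10, trigger = c("interval", "event"),
                              representative = "first") {
  list(interval_minutes = interval_minutes, trigger = match.arg(trigger),
       representative = representative)
}

#' Run one metadata-extraction cycle
#'
#' Processes exactly the series present in the ingestion index but not yet
#' marked extracted for each profile. Documents are upserted (so a crash
#' between a document write and the state persist merely re-writes the same
#' document on the next cycle), state is persisted at the end of the cycle,
#' and an immediate re-run is a no-op. An unparseable instance is skipped
#' and its series left pending for retry.
#'
#' @param storage_root ingestion storage root (index + files).
#' @param profiles profiles from [load_profiles()].
#' @param store a [doc_store()].
#' @param state_dir directory holding per-profile extracted-series sets.
#' @param config an [extraction_config()].
#' @param phi_exclusion PHI list enforced on documents.
#' @param on_document_written optional callback `function(series_uid,
#'   profile)` run after each upsert; crash-simulation seam for tests.
#' @return list: updated `state`, `written` (document count this cycle),
#'   `skipped` (unparseable instances).
#' @export
run_extraction_cycle <- function(storage_root, profiles, store, state_dir,
                                 config = extraction_config(),
                                 phi_exclusion = default_phi_list(),
                                 on_document_written = NULL) {
  index <- read_ingestion_index(storage_root)
  state <- load_state(state_dir)
  written <- 0L
  skipped <- 0L
  series_ids <- unique(index$series_uid)
  by_series <- split(index, index$series_uid)
  for (profile in profiles) {
    done <- state$extracted[[profile$name]]
    todo <- setdiff(series_ids, done)
    for (sid in todo) {
      recs <- by_series[[sid]]
      reps <- select_representative(recs, config$representative)
      values <- list()
      doc <- NULL
      ok <- TRUE
      for (ri in seq_len(nrow(reps))) {
        f <- file.path(storage_root, reps$path[ri])
        d <- tryCatch(
          extract_document(f, reps[ri, , drop = FALSE], profile, phi_exclusion),
          error = function(e) e)
        if (inherits(d, "error")) {
          message("skipping unparseable instance in series ", sid, ": ",
                  conditionMessage(d))
          ok <- FALSE
          break
        }
        if (is.null(doc)) doc <- d
        # union of representative headers, first instance wins per attribute
        values <- c(values, d$values[setdiff(names(d$values), names(values))])
      }
      if (!ok) { skipped <- skipped + 1L; next }
      doc$values <- values
      upsert_document(store, doc)
      written <- written + 1L
      state$extracted[[profile$name]] <- union(state$extracted[[profile$name]], sid)
      if (!is.null(on_document_written)) on_document_written(sid, profile$name)
    }
  }
  persist_state(state, state_dir)
  list(state = state, written = written, skipped = skipped)
}

#' Filter a cohort from a metadata collection
#'
#' Returns the series whose documents satisfy ALL predicates. Matching is
#' exact and case-insensitive (DICOM code strings); a predicate may give a
#' set of admissible values; a multi-valued document attribute matches if
#' any of its values does. Predicates on attributes the profile does not
#' extract are an error — they would otherwise silently select nothing.
#'
#' @param docs documents from [read_collection()].
#' @param predicates named list: attribute keyword -> value or vector.
#' @param profile the collection's profile (for predicate validation).
#' @return character vector of matching `series_uid`s.
#' @export
filter_cohort <- function(docs, predicates, profile) {
  if (!length(predicates)) {
    return(vapply(docs, function(d) d$series_uid, character(1)))
  }
  missing_attr <- setdiff(names(predicates), profile$attributes)
  if (length(missing_attr)) {
    stop("predicate on attribute(s) absent from profile '", profile$name,
         "': ", paste(missing_attr, collapse = ", "))
  }
  keep <- vapply(docs, function(d) {
    all(vapply(names(predicates), function(a) {
      v <- d$values[[a]]
      if (is.null(v)) return(FALSE)
      any(toupper(unlist(v)) %in% toupper(unlist(predicates[[a]])))
    }, logical(1)))
  }, logical(1))
  vapply(docs[keep], function(d) d$series_uid, character(1))
}
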