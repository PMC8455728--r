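# Storage lifecycle: persisted extraction/deletion state as newline-
# delimited series-UID sets, and the nightly cleanup that deletes only
# series whose metadata is extracted for every active profile, respecting
# consumer holds and a retention floor.

#' Load extractor/cleanup state
#'
#' State lives in a directory of newline-delimited series-UID set files:
#' `extracted-<profile>.keys` per profile and `deleted.keys`. A missing
#' directory or file yields the empty state (cold start). A file that is
#' not a flat list of UIDs is an error instructing a rebuild from the
#' document store (see [rebuild_state_from_store()]).
#'
#' @param dir state directory.
#' @return list: `extracted` (named list profile -> series set), `deleted`
#'   (series set).
#' @export
load_state <- function(dir) {
  state <- list(extracted = list(), deleted = character(0))
  if (!dir.exists(dir)) return(state)
  for (f in list.files(dir, pattern = "^extracted-.*\\.keys$", full.names = TRUE)) {
    profile <- sub("^extracted-(.*)\\.keys$", "\\1", basename(f))
    keys <- read_set_file(f)
    if (any(grepl("[\t ]", keys))) {
      stop("corrupt state file ", f,
           "; rebuild the extracted sets from the document store with ",
           "rebuild_state_from_store()")
    }
    state$extracted[[profile]] <- keys
  }
  state$deleted <- read_set_file(file.path(dir, "deleted.keys"))
  state
}

#' Persist extractor/cleanup state
#'
#' Write-then-atomic-rename per set file, so a crash never leaves a
#' half-written state; `load_state(persist_state(s)) == s`.
#'
#' @param state state list (see [load_state()]).
#' @param dir state directory (created if missing).
#' @return `state`, invisibly.
#' @export
persist_state <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (profile in names(state$extracted)) {
    atomic_write_lines(sort(state$extracted[[profile]]),
                       file.path(dir, paste0("extracted-", profile, ".keys")))
  }
  atomic_write_lines(sort(state$deleted), file.path(dir, "deleted.keys"))
  invisible(state)
}

#' Rebuild extraction state from the document store
#'
#' After state-file corruption, the extracted set per profile is exactly the
#' set of series with a document in that profile's collection.
#'
#' @param store a [doc_store()].
#' @param profiles profiles whose collections to scan.
#' @return a state list (empty `deleted` set).
#' @export
rebuild_state_from_store <- function(store, profiles) {
  extracted <- lapply(profiles, function(p) {
    vapply(read_collection(store, p$name), function(d) d$series_uid, character(1))
  })
  names(extracted) <- vapply(profiles, `[[`, character(1), "name")
  list(extracted = extracted, deleted = character(0))
}

#' Delete images whose metadata is extracted
#'
#' The nightly cleanup (scheduled at 23:59 by default in deployments; this
#' function is the one-shot core). A series is deleted iff it is (a) marked
#' extracted for ALL active profiles, (b) not held by a registered consumer,
#' and (c) past the retention floor since receipt. Empty parent directories
#' are pruned; the deleted set is persisted so an immediate re-run deletes
#' nothing; a failure on one series is logged and the rest proceed.
#'
#' @param storage_root ingestion storage root.
#' @param state_dir state directory ([load_state()]/[persist_state()]).
#' @param profiles active profiles; a series must be extracted for all.
#' @param holds series UIDs in use by ML/processing workflows, never deleted.
#' @param now current instant (injectable for tests/schedulers).
#' @param retention_min minimum age since receipt, minutes (default one day).
#' @return report data frame: `series_uid`, `n_files`, `action`
#'   (`deleted`, `kept_pending`, `kept_hold`, `kept_young`, `error`).
#' @export
clear_storage <- function(storage_root, state_dir, profiles,
                          holds = character(0), now = Sys.time(),
                          retention_min = 1440) {
  state <- load_state(state_dir)
  index <- read_ingestion_index(storage_root)
  if (!nrow(index)) {
    return(data.frame(series_uid = character(0), n_files = integer(0),
                      action = character(0), stringsAsFactors = FALSE))
  }
  profile_names <- vapply(profiles, `[[`, character(1), "name")
  by_series <- split(index, index$series_uid)
  live <- setdiff(names(by_series), state$deleted)
  rows <- lapply(live, function(sid) {
    recs <- by_series[[sid]]
    extracted_all <- length(profile_names) > 0L &&
      all(vapply(profile_names,
                 function(p) sid %in% state$extracted[[p]], logical(1)))
    action <- if (!extracted_all) "kept_pending"
      else if (sid %in% holds) "kept_hold"
      else if (as.numeric(difftime(now, max(recs$receipt_time), units = "mins")) <
               retention_min) "kept_young"
      else "deleted"
    if (action == "deleted") {
      paths <- file.path(storage_root, recs$path)
      ok <- tryCatch({ unlink(paths); !any(file.exists(paths)) },
                     error = function(e) FALSE)
      if (!ok) {
        message("failed to delete series ", sid, "; continuing")
        action <- "error"
      } else {
        for (d in unique(dirname(paths))) .prune_empty_dirs(d, storage_root)
      }
    }
    data.frame(series_uid = sid, n_files = nrow(recs), action = action,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  state$deleted <- union(state$deleted,
                         report$series_uid[report$action == "deleted"])
  persist_state(state, state_dir)
  report
}

.prune_empty_dirs <- function(dir, stop_at) {
  dir <- normalizePath(dir, mustWork = FALSE)
  stop_at <- normalizePath(stop_at, mustWork = FALSE)
  while (nzchar(dir) && dir != stop_at && dir.exists(dir) &&
         length(list.files(dir, all.files = TRUE, no.. = TRUE)) == 0L) {
    unlink(dir, recursive = TRUE)
    dir <- dirname(dir)
  }
}

#' Default cleanup schedule
#'
#' Deployments run [clear_storage()] nightly; this records the default
#' trigger time.
#'
#' @return list with `at` (`"23:59"` local time).
#' @export
cleanup_schedule <- function() list(at = "23:59")
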