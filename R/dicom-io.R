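# DICOM Part 10 file I/O: Explicit VR Little Endian, no sequence (SQ)
# support — the attributes this framework handles are all top-level simple
# VRs. Datasets are plain named lists: names are dictionary keywords or
# "(gggg,eeee)" hex keys for private/unknown tags; PixelData is a raw vector;
# multi-valued attributes are vectors collapsed with backslash on write.

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                 "PN", "SH", "ST", "TM", "UI", "UT")

.encode_value <- function(vr, value) {
  if (vr %in% c("OB", "OW", "UN")) {
    # UN round trip: a re-serialized unknown element may carry a decoded
    # string rather than raw bytes
    v <- if (is.character(value)) charToRaw(paste(value, collapse = "\\"))
         else as.raw(value)
    if (length(v) %% 2L == 1L) v <- c(v, as.raw(0L))
    return(v)
  }
  if (vr == "US") {
    return(writeBin(as.integer(value), raw(), size = 2L, endian = "little"))
  }
  if (vr == "UL") {
    return(writeBin(as.integer(value), raw(), size = 4L, endian = "little"))
  }
  if (vr %in% .STRING_VRS) {
    s <- if (vr == "DS") {
      paste(vapply(value, function(x)
        if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE) else as.character(x),
        character(1)), collapse = "\\")
    } else {
      paste(as.character(value), collapse = "\\")
    }
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      b <- c(b, pad)
    }
    return(b)
  }
  stop("cannot encode VR ", vr)
}

.encode_element <- function(group, element, vr, value) {
  body <- .encode_value(vr, value)
  head <- c(
    writeBin(as.integer(group), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(element), raw(), size = 2L, endian = "little"),
    charToRaw(vr)
  )
  if (vr %in% .LONG_VRS) {
    c(head, as.raw(c(0L, 0L)),
      writeBin(length(body), raw(), size = 4L, endian = "little"), body)
  } else {
    if (length(body) > 65534L) stop("value too long for short-form VR ", vr)
    c(head, writeBin(length(body), raw(), size = 2L, endian = "little"), body)
  }
}

#' Write a DICOM Part 10 file
#'
#' Serializes a named-list dataset as Explicit VR Little Endian with a
#' standard 128-byte preamble and file meta information group. The file meta
#' group (media storage SOP class/instance UID, transfer syntax) is derived
#' from the dataset; `SOPClassUID` and `SOPInstanceUID` must be present.
#'
#' @param dataset named list of attribute values. Names are dictionary
#'   keywords (e.g. `"PatientID"`) or `"(gggg,eeee)"` hex keys for private
#'   tags; `PixelData`, if present, is a raw vector.
#' @param path output file path.
#' @param private_vrs optional named character vector giving the VR for hex
#'   tag keys (default `"LO"` treated as unknown-but-string; unlisted hex
#'   keys are written as `UN`).
#' @return `path`, invisibly.
#' @export
write_dicom <- function(dataset, path, private_vrs = NULL) {
  for (req in c("SOPClassUID", "SOPInstanceUID")) {
    if (is.null(dataset[[req]])) stop("dataset lacks required attribute ", req)
  }
  keys <- names(dataset)
  tags <- lapply(keys, dicom_tag)
  groups <- vapply(tags, `[[`, numeric(1), "group")
  elements <- vapply(tags, `[[`, numeric(1), "element")
  if (any(groups == 2L)) stop("file meta elements are generated, not supplied")
  vrs <- vapply(seq_along(keys), function(i) {
    vr <- tags[[i]]$vr
    if (vr == "UN" && !is.null(private_vrs) && keys[i] %in% names(private_vrs)) {
      vr <- unname(private_vrs[keys[i]])
    }
    vr
  }, character(1))

  ord <- order(groups, elements)
  body <- raw(0)
  for (i in ord) {
    body <- c(body, .encode_element(groups[i], elements[i], vrs[i], dataset[[keys[i]]]))
  }

  meta_elems <- c(
    .encode_element(2L, 1L, "OB", as.raw(c(0L, 1L))),
    .encode_element(2L, 2L, "UI", dataset$SOPClassUID),
    .encode_element(2L, 3L, "UI", dataset$SOPInstanceUID),
    .encode_element(2L, 16L, "UI", TS_EXPLICIT_VR_LE),
    .encode_element(2L, 18L, "UI", paste0(UID_ROOT, ".0.1")),
    .encode_element(2L, 19L, "SH", "DICOMFLOW_01")
  )
  meta <- c(.encode_element(2L, 0L, "UL", length(meta_elems)), meta_elems)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

.decode_value <- function(vr, bytes) {
  if (vr %in% c("OB", "OW", "UN")) return(bytes)
  if (vr == "US") return(readBin(bytes, integer(), n = length(bytes) %/% 2L,
                                 size = 2L, signed = FALSE, endian = "little"))
  if (vr == "UL") return(readBin(bytes, integer(), n = length(bytes) %/% 4L,
                                 size = 4L, endian = "little"))
  s <- rawToChar(bytes[bytes != as.raw(0L)])
  s <- sub("[ ]+$", "", s)
  parts <- if (nzchar(s)) strsplit(s, "\\", fixed = TRUE)[[1]] else s
  parts <- trimws(parts)
  if (vr == "IS") return(as.integer(parts))
  if (vr == "DS") return(as.numeric(parts))
  parts
}

#' Read a DICOM Part 10 file
#'
#' Parses the file meta group and an Explicit VR Little Endian dataset into
#' a named list (see [write_dicom()] for the representation). Only
#' uncompressed Explicit VR Little Endian datasets are supported; any other
#' transfer syntax is an error naming the UID found.
#'
#' @param path file to read.
#' @param skip_pixels if `TRUE`, the PixelData element is skipped (header-only
#'   parse, as used by the metadata extractor).
#' @return named list of attribute values with attribute
#'   `transfer_syntax`.
#' @export
read_dicom <- function(path, skip_pixels = FALSE) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM Part 10 file: ", path)
  }
  pos <- 133L
  n <- length(bytes)
  out <- list()
  ts <- NULL
  in_meta <- TRUE
  meta_end <- Inf
  while (pos + 7L <= n + 1L && pos <= n) {
    if (in_meta && pos >= meta_end) {
      in_meta <- FALSE
      if (!identical(ts, TS_EXPLICIT_VR_LE)) {
        stop("unsupported transfer syntax: ", if (is.null(ts)) "<missing>" else ts)
      }
    }
    group <- readBin(bytes[pos:(pos + 1L)], integer(), size = 2L,
                     signed = FALSE, endian = "little")
    element <- readBin(bytes[(pos + 2L):(pos + 3L)], integer(), size = 2L,
                       signed = FALSE, endian = "little")
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("implicit VR or corrupt element at offset ", pos - 1L, " in ", path)
    }
    if (vr %in% .LONG_VRS) {
      len <- readBin(bytes[(pos + 8L):(pos + 11L)], integer(), size = 4L,
                     endian = "little")
      val_start <- pos + 12L
    } else {
      len <- readBin(bytes[(pos + 6L):(pos + 7L)], integer(), size = 2L,
                     signed = FALSE, endian = "little")
      val_start <- pos + 8L
    }
    if (vr == "SQ") stop("sequence elements are not supported (", path, ")")
    if (len < 0L || val_start + len - 1L > n) {
      stop("element length overruns file at offset ", pos - 1L, " in ", path)
    }
    key <- .keyword_for_tag(group, element)
    if (group == 2L && element == 0L) {
      gl <- .decode_value("UL", bytes[val_start:(val_start + len - 1L)])
      meta_end <- val_start + len + gl
    } else if (!(skip_pixels && key == "PixelData")) {
      val <- if (len == 0L) {
        if (vr %in% c("OB", "OW", "UN")) raw(0) else ""
      } else {
        .decode_value(vr, bytes[val_start:(val_start + len - 1L)])
      }
      if (group == 2L) {
        if (element == 16L) ts <- val
      } else {
        out[[key]] <- val
      }
    }
    pos <- val_start + len
  }
  if (is.infinite(meta_end) && !identical(ts, TS_EXPLICIT_VR_LE)) {
    stop("unsupported transfer syntax: ", if (is.null(ts)) "<missing>" else ts)
  }
  attr(out, "transfer_syntax") <- ts
  out
}
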