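# DICOM DA/TM value handling. All instants are POSIXct in UTC; the scanner
# clock offset and receipt clock live in the same frame, so arithmetic on
# them is exact.

#' Parse a DICOM date/time pair into an instant
#'
#' Combines a DA (`YYYYMMDD`) and TM (`HHMMSS` with optional fractional
#' seconds, or empty) value into a UTC instant. A missing or empty time
#' yields midnight with the precision flag lowered — such instants are
#' excluded from clock-skew statistics.
#'
#' @param da DICOM DA string.
#' @param tm DICOM TM string; `""`, `NA` or `NULL` means time unknown.
#' @return `POSIXct` instant with attribute `full_precision` (logical).
#' @export
parse_dicom_datetime <- function(da, tm = "") {
  if (is.null(da) || length(da) != 1L || is.na(da) || !grepl("^[0-9]{8}$", da)) {
    stop("unparseable DICOM DA value: ", deparse(substitute(da)), " = ",
         if (is.null(da)) "NULL" else da)
  }
  if (is.null(tm) || length(tm) == 0L || is.na(tm)) tm <- ""
  full <- nzchar(tm)
  frac <- 0
  if (full) {
    if (!grepl("^[0-9]{2}([0-9]{2}([0-9]{2}(\\.[0-9]{1,6})?)?)?$", tm)) {
      stop("unparseable DICOM TM value: ", tm)
    }
    hms <- sub("\\..*$", "", tm)
    base <- paste0(hms, strrep("0", 6L - nchar(hms)))
    if (grepl("\\.", tm)) frac <- as.numeric(paste0("0.", sub("^.*\\.", "", tm)))
  } else {
    base <- "000000"
  }
  inst <- as.POSIXct(paste0(da, base), format = "%Y%m%d%H%M%S", tz = "UTC") + frac
  if (is.na(inst)) stop("invalid DICOM date/time: ", da, " ", tm)
  attr(inst, "full_precision") <- full
  inst
}

# Format an instant as DA / TM (whole seconds).
format_da <- function(instant) format(instant, "%Y%m%d", tz = "UTC")
format_tm <- function(instant) format(instant, "%H%M%S", tz = "UTC")

# Parse ISO-8601-ish timestamp stored in index/documents back to POSIXct UTC.
parse_instant <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}
format_instant <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
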