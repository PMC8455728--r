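# Minimal DICOM data dictionary: the attributes this framework reads or
# writes. Keywords follow the standard; tags outside this table are carried
# as "(gggg,eeee)" hex keys so private elements survive a round trip.

.dicom_dict_raw <- c(
  # keyword,                       group, element, vr
  "FileMetaInformationGroupLength", "0002", "0000", "UL",
  "FileMetaInformationVersion",     "0002", "0001", "OB",
  "MediaStorageSOPClassUID",        "0002", "0002", "UI",
  "MediaStorageSOPInstanceUID",     "0002", "0003", "UI",
  "TransferSyntaxUID",              "0002", "0010", "UI",
  "ImplementationClassUID",         "0002", "0012", "UI",
  "ImplementationVersionName",      "0002", "0013", "SH",
  "SpecificCharacterSet",           "0008", "0005", "CS",
  "ImageType",                      "0008", "0008", "CS",
  "SOPClassUID",                    "0008", "0016", "UI",
  "SOPInstanceUID",                 "0008", "0018", "UI",
  "StudyDate",                      "0008", "0020", "DA",
  "SeriesDate",                     "0008", "0021", "DA",
  "AcquisitionDate",                "0008", "0022", "DA",
  "ContentDate",                    "0008", "0023", "DA",
  "StudyTime",                      "0008", "0030", "TM",
  "SeriesTime",                     "0008", "0031", "TM",
  "AcquisitionTime",                "0008", "0032", "TM",
  "ContentTime",                    "0008", "0033", "TM",
  "AccessionNumber",                "0008", "0050", "SH",
  "Modality",                       "0008", "0060", "CS",
  "Manufacturer",                   "0008", "0070", "LO",
  "InstitutionName",                "0008", "0080", "LO",
  "InstitutionAddress",             "0008", "0081", "ST",
  "ReferringPhysicianName",         "0008", "0090", "PN",
  "StationName",                    "0008", "1010", "SH",
  "StudyDescription",               "0008", "1030", "LO",
  "SeriesDescription",              "0008", "103E", "LO",
  "PatientName",                    "0010", "0010", "PN",
  "PatientID",                      "0010", "0020", "LO",
  "PatientBirthDate",               "0010", "0030", "DA",
  "PatientSex",                     "0010", "0040", "CS",
  "OtherPatientIDs",                "0010", "1000", "LO",
  "PatientAddress",                 "0010", "1040", "LO",
  "BodyPartExamined",               "0018", "0015", "CS",
  "DeviceSerialNumber",             "0018", "1000", "LO",
  "SoftwareVersions",               "0018", "1020", "LO",
  "ProtocolName",                   "0018", "1030", "LO",
  "StudyInstanceUID",               "0020", "000D", "UI",
  "SeriesInstanceUID",              "0020", "000E", "UI",
  "StudyID",                        "0020", "0010", "SH",
  "SeriesNumber",                   "0020", "0011", "IS",
  "InstanceNumber",                 "0020", "0013", "IS",
  "SamplesPerPixel",                "0028", "0002", "US",
  "PhotometricInterpretation",      "0028", "0004", "CS",
  "Rows",                           "0028", "0010", "US",
  "Columns",                        "0028", "0011", "US",
  "BitsAllocated",                  "0028", "0100", "US",
  "BitsStored",                     "0028", "0101", "US",
  "HighBit",                        "0028", "0102", "US",
  "PixelRepresentation",            "0028", "0103", "US",
  "WindowCenter",                   "0028", "1050", "DS",
  "WindowWidth",                    "0028", "1051", "DS",
  "RescaleIntercept",               "0028", "1052", "DS",
  "RescaleSlope",                   "0028", "1053", "DS",
  "PixelData",                      "7FE0", "0010", "OW"
)

.dicom_dict <- local({
  m <- matrix(.dicom_dict_raw, ncol = 4, byrow = TRUE)
  data.frame(
    keyword = m[, 1],
    group = strtoi(m[, 2], 16L),
    element = strtoi(m[, 3], 16L),
    vr = m[, 4],
    stringsAsFactors = FALSE
  )
})

# Transfer syntax and SOP class UIDs used by the generator.
TS_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
# Private UID root for deterministically generated fixture UIDs.
UID_ROOT <- "1.2.826.0.1.3680043.10.1457"

#' Look up a DICOM attribute keyword
#'
#' @param keyword attribute keyword, or a `"(gggg,eeee)"` hex tag key.
#' @return list with `group`, `element`, `vr` (VR is `"UN"` for hex keys not
#'   in the dictionary).
#' @keywords internal
dicom_tag <- function(keyword) {
  i <- match(keyword, .dicom_dict$keyword)
  if (!is.na(i)) {
    return(list(group = .dicom_dict$group[i], element = .dicom_dict$element[i],
                vr = .dicom_dict$vr[i]))
  }
  m <- regmatches(keyword, regexec("^\\(([0-9A-Fa-f]{4}),([0-9A-Fa-f]{4})\\)$", keyword))[[1]]
  if (length(m) == 3L) {
    return(list(group = strtoi(m[2], 16L), element = strtoi(m[3], 16L), vr = "UN"))
  }
  stop("unknown DICOM attribute keyword: ", keyword)
}

#' Is a keyword known to the dictionary (or a valid hex tag key)?
#' @keywords internal
is_known_keyword <- function(keyword) {
  keyword %in% .dicom_dict$keyword |
    grepl("^\\([0-9A-Fa-f]{4},[0-9A-Fa-f]{4}\\)$", keyword)
}

.keyword_for_tag <- function(group, element) {
  i <- which(.dicom_dict$group == group & .dicom_dict$element == element)
  if (length(i) == 1L) .dicom_dict$keyword[i]
  else sprintf("(%04X,%04X)", group, element)
}
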