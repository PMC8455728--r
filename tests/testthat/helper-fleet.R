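# Fixture builders: small synthetic fleets, in-memory ingestion, and a
# pydicom-based independent oracle for the Part 10 writer.

demo_scanners <- function(offsets = c(MR01 = 0, MR02 = 60), modality = "MR") {
  do.call(rbind, Map(function(id, off) scanner_spec(id, modality, off),
                     names(offsets), unname(offsets)))
}

# The nine-scanner miscalibration fixture: offsets in minutes; with the
# 2-minute transfer delay, scanners beyond the 20-minute rule are exactly
# those with |offset| > 20.
skew_fleet_offsets <- c(SC1 = 0, SC2 = 5, SC3 = 25, SC4 = -60, SC5 = 300,
                        SC6 = 12, SC7 = -1440, SC8 = 18, SC9 = 45)

build_fleet <- function(scanners = demo_scanners(), exams_per_scanner = 2,
                        seed = 1, day = "2020-01-15") {
  exams <- generate_fleet_schedule(scanners, day, exams_per_scanner, seed)
  arch <- tempfile("arch")
  manifest <- materialize_instances(exams, scanners, arch)
  list(scanners = scanners, exams = exams, arch = arch, manifest = manifest,
       day = as.Date(day))
}

# Store every manifest instance directly on a fresh listener, stamping
# receipt = true acquisition + a fixed network delay (minutes).
ingest_fleet <- function(fleet, delay_min = 2,
                         folder_depth = "patient/study/series") {
  root <- tempfile("store")
  lst <- start_listener(source_config("rt", "RESEARCH", 11112, root, folder_depth))
  for (i in seq_len(nrow(fleet$manifest))) {
    res <- lst$c_store(fleet$manifest$path[i],
                       receipt_time = fleet$manifest$true_time[i] + 60 * delay_min)
    stopifnot(identical(res$status, 0x0000L))
  }
  list(root = root, listener = lst)
}

# A mock PACS over the fleet archive whose C-MOVEs stamp receipt times as
# true acquisition + a fixed delay (the network model).
fleet_pacs <- function(fleet, delay_min = 2, fail_every_k = 0L) {
  clock <- function(row) {
    fleet$manifest$true_time[match(row$sop_uid, fleet$manifest$sop_uid)] +
      60 * delay_min
  }
  mock_pacs_serve(fleet$arch, fail_every_k = fail_every_k, receipt_clock = clock)
}

# Operational profile covering scanner identity, exam identity and
# timestamps — what the analytics layer needs.
ops_profile_dir <- function(attrs = c("Modality", "StationName",
                                      "DeviceSerialNumber", "AccessionNumber",
                                      "StudyInstanceUID", "BodyPartExamined",
                                      "AcquisitionDate", "AcquisitionTime",
                                      "SeriesDate", "SeriesTime", "ImageType"),
                            name = "ops") {
  dir <- tempfile("profiles")
  dir.create(dir)
  writeLines(attrs, file.path(dir, paste0(name, ".txt")))
  dir
}

# Ingest + extract in one go; returns everything downstream tests need.
extracted_fleet <- function(fleet = build_fleet(), delay_min = 2) {
  ing <- ingest_fleet(fleet, delay_min)
  pdir <- ops_profile_dir()
  profs <- load_profiles(pdir)
  store <- doc_store(tempfile("docs"))
  sdir <- tempfile("state")
  res <- run_extraction_cycle(ing$root, profs, store, sdir)
  c(fleet, ing, list(profiles = profs, profile_dir = pdir, store = store,
                     state_dir = sdir, cycle = res,
                     docs = read_collection(store, "ops")))
}

# Independent oracle: parse a Part 10 file with pydicom and return selected
# attributes as a list.
pydicom_dump <- function(path) {
  script <- paste(
    "import sys, json, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "arr = ds.pixel_array",
    "out = {",
    "  'TransferSyntaxUID': str(ds.file_meta.TransferSyntaxUID),",
    "  'SOPInstanceUID': str(ds.SOPInstanceUID),",
    "  'PatientID': str(ds.get('PatientID', '')),",
    "  'AccessionNumber': str(ds.get('AccessionNumber', '')),",
    "  'Modality': str(ds.get('Modality', '')),",
    "  'AcquisitionDate': str(ds.get('AcquisitionDate', '')),",
    "  'AcquisitionTime': str(ds.get('AcquisitionTime', '')),",
    "  'ImageType': [str(x) for x in ds.get('ImageType', [])],",
    "  'InstanceNumber': int(ds.get('InstanceNumber', -1)),",
    "  'Rows': int(ds.Rows), 'Columns': int(ds.Columns),",
    "  'pix_min': int(arr.min()), 'pix_max': int(arr.max()),",
    "  'private_creator': str(ds[0x0009, 0x0010].value) if (0x0009, 0x0010) in ds else ''",
    "}",
    "print(json.dumps(out))",
    sep = "\n")
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  out <- system2("python", c(f, shQuote(path)), stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# MD5 digest of a raw vector (pixel-buffer comparisons).
digest_raw <- function(x) {
  f <- tempfile()
  writeBin(x, f)
  unname(tools::md5sum(f))
}

# Brute-force pairwise interval disjointness check (the oracle for the
# scheduler's one-exam-at-a-time invariant).
intervals_disjoint <- function(starts, ends) {
  n <- length(starts)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (max(as.numeric(starts[i]), as.numeric(starts[j])) <
          min(as.numeric(ends[i]), as.numeric(ends[j]))) return(FALSE)
    }
  }
  TRUE
}

# Build one metadata document directly (for analytics unit tests that do
# not need the full pipeline).
make_doc <- function(series_uid, scanner = "MR01", accession = "ACC1",
                     da = "20200115", tm = "080000", receipt = NULL, ...) {
  values <- list(StationName = scanner, AccessionNumber = accession,
                 AcquisitionDate = da, AcquisitionTime = tm, ...)
  list(series_uid = series_uid, profile = "ops",
       receipt_time = if (is.null(receipt)) NULL else receipt,
       values = values)
}
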