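# Analytics: exam windows, utilization arithmetic, overlap detection,
# clock-skew flagging, PNG export and de-identification.

ts_doc <- function(sid, tm, scanner = "MR01", accession = "ACC1",
                   receipt = NULL) {
  make_doc(sid, scanner = scanner, accession = accession, tm = tm,
           receipt = receipt)
}

test_that("exam windows are the min/max header instants per exam", {
  docs <- list(ts_doc("s1", "080000"), ts_doc("s2", "081000"),
               ts_doc("s3", "082500"))
  w <- compute_exam_windows(docs)
  expect_identical(nrow(w), 1L)
  expect_identical(format(w$start, "%H:%M:%S", tz = "UTC"), "08:00:00")
  expect_identical(format(w$end, "%H:%M:%S", tz = "UTC"), "08:25:00")
  expect_equal(w$duration_min, 25)
  expect_identical(w$n_series, 3L)

  single <- compute_exam_windows(list(ts_doc("s1", "090000")))
  expect_equal(single$duration_min, 0)  # degenerate exam: zero-length window
})

test_that("documents without scanner identity or timestamps are excluded and counted", {
  docs <- list(
    ts_doc("s1", "080000"),
    list(series_uid = "s2", profile = "ops", receipt_time = NULL,
         values = list(AccessionNumber = "ACC1", AcquisitionDate = "20200115",
                       AcquisitionTime = "081000")),  # no scanner identity
    list(series_uid = "s3", profile = "ops", receipt_time = NULL,
         values = list(StationName = "MR01", AccessionNumber = "ACC1")))  # no timestamp
  w <- compute_exam_windows(docs)
  expect_identical(attr(w, "excluded"), 2L)
  expect_identical(w$n_series, 1L)
})

test_that("timestamp fallback order is acquisition, series, content", {
  d <- list(series_uid = "s1", profile = "ops", receipt_time = NULL,
            values = list(StationName = "MR01", AccessionNumber = "ACC1",
                          SeriesDate = "20200115", SeriesTime = "091500"))
  w <- compute_exam_windows(list(d))
  expect_identical(format(w$start, "%H:%M:%S", tz = "UTC"), "09:15:00")
})

test_that("computed windows sit inside the true intervals shifted by the clock offset", {
  ef <- extracted_fleet(build_fleet(demo_scanners(c(MR01 = 0, MR02 = 60)),
                                    exams_per_scanner = 2, seed = 16))
  w <- compute_exam_windows(ef$docs)
  off <- ef$scanners$clock_offset_min[match(w$scanner_id, ef$scanners$scanner_id)]
  for (i in seq_len(nrow(w))) {
    ex <- ef$exams[ef$exams$accession == w$exam_key[i], ]
    expect_true(w$start[i] >= ex$true_start + 60 * off[i] &&
                w$end[i] <= ex$true_end + 60 * off[i],
                info = w$exam_key[i])
  }
})

test_that("utilization metrics partition the observed span", {
  mk <- function(s, e, key) data.frame(
    scanner_id = "MR01", exam_key = key,
    start = as.POSIXct(paste("2020-01-15", s), tz = "UTC"),
    end = as.POSIXct(paste("2020-01-15", e), tz = "UTC"),
    stringsAsFactors = FALSE)
  w <- rbind(mk("08:00:00", "08:25:00", "A"), mk("09:00:00", "09:30:00", "B"))
  rep <- utilization_report(w, "2020-01-15")
  expect_equal(rep$idle_gaps_min, 35)
  expect_equal(rep$exam_durations_min, c(25, 30))
  expect_equal(rep$busy_fraction, (25 + 30) / 90)
  expect_equal(rep$span_min, 90)
  expect_identical(nrow(rep$overlaps), 0L)

  one <- utilization_report(mk("08:00:00", "08:45:00", "A"), "2020-01-15")
  expect_identical(one$idle_gaps_min, numeric(0))
  expect_equal(one$busy_fraction, 1)

  none <- utilization_report(w[0, ], "2020-01-15")
  expect_equal(none$busy_fraction, 0)
})

test_that("conservation identity holds exactly on seeded synthetic days", {
  for (seed in c(21, 22, 23)) {
    ef <- extracted_fleet(build_fleet(demo_scanners(c(MR01 = 0)),
                                      exams_per_scanner = 3, seed = seed))
    w <- compute_exam_windows(ef$docs)
    rep <- utilization_report(w, ef$day)
    expect_identical(nrow(rep$overlaps), 0L, info = paste("seed", seed))
    expect_equal(sum(rep$exam_durations_min) + sum(rep$idle_gaps_min),
                 rep$span_min, tolerance = 1e-9, info = paste("seed", seed))
  }
})

test_that("overlap detection finds corrupted schedules, not touching windows", {
  mk <- function(s, e, key) data.frame(
    scanner_id = "MR01", exam_key = key,
    start = as.POSIXct(paste("2020-01-15", s), tz = "UTC"),
    end = as.POSIXct(paste("2020-01-15", e), tz = "UTC"),
    stringsAsFactors = FALSE)
  touching <- rbind(mk("08:00:00", "08:30:00", "A"), mk("08:30:00", "09:00:00", "B"))
  expect_identical(nrow(detect_overlaps(touching)), 0L)

  forced <- rbind(mk("08:00:00", "08:40:00", "A"), mk("08:30:00", "09:00:00", "B"))
  ov <- detect_overlaps(forced)
  expect_identical(nrow(ov), 1L)
  expect_equal(ov$overlap_min, 10)

  # corrupted-schedule emulation eventually produces overlaps; clean never
  sc <- demo_scanners(c(MR01 = 0))
  ex <- generate_fleet_schedule(sc, "2020-01-15", 5, seed = 24)
  clean <- data.frame(scanner_id = ex$scanner_id, exam_key = ex$accession,
                      start = ex$true_start, end = ex$true_end,
                      stringsAsFactors = FALSE)
  expect_identical(nrow(detect_overlaps(clean)), 0L)
  found <- FALSE
  for (cseed in 1:10) {
    cdw <- corrupt_schedule(ex, error_rate = 0.5, seed = cseed)
    rec <- data.frame(scanner_id = cdw$scanner_id, exam_key = cdw$accession,
                      start = cdw$recorded_start, end = cdw$recorded_end,
                      stringsAsFactors = FALSE)
    if (nrow(detect_overlaps(rec)) > 0L) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("clock-skew medians flag miscalibrated scanners, not delayed images", {
  base <- as.POSIXct("2020-01-15 08:00:00", tz = "UTC")
  mkdocs <- function(scanner, offset_min, delay_min = 2, n = 5) {
    lapply(seq_len(n), function(i) {
      truth <- base + 300 * i
      hdr <- truth + 60 * offset_min
      ts_doc(paste0(scanner, "-s", i), format(hdr, "%H%M%S"), scanner = scanner,
             receipt = format(truth + 60 * delay_min, "%Y-%m-%dT%H:%M:%S"))
    })
  }
  calibrated <- clock_skew_report(mkdocs("OK", 0))
  expect_equal(calibrated$median_skew_min, 2)
  expect_false(calibrated$flagged)

  ahead <- clock_skew_report(mkdocs("AHEAD", 60))
  expect_equal(ahead$median_skew_min, -58)
  expect_true(ahead$flagged)

  # one straggler image does not flag a healthy scanner
  docs <- mkdocs("OK", 0)
  docs[[1]]$receipt_time <- format(base + 3600, "%Y-%m-%dT%H:%M:%S")
  robust <- clock_skew_report(docs)
  expect_false(robust$flagged)
  expect_identical(robust$n_exceeding, 1L)

  # no usable timestamps: unassessable, not flagged
  bare <- list(list(series_uid = "s1", profile = "ops", receipt_time = NULL,
                    values = list(StationName = "MUTE")))
  mute <- clock_skew_report(bare)
  expect_true(is.na(mute$flagged))
})

test_that("the nine-scanner fleet flags exactly the |offset| > 20 min scanners", {
  sc <- demo_scanners(skew_fleet_offsets)
  fleet <- build_fleet(sc, exams_per_scanner = 1, seed = 17)
  ef <- extracted_fleet(fleet)
  skew <- clock_skew_report(ef$docs)
  truth <- names(skew_fleet_offsets)[abs(skew_fleet_offsets) > 20]
  expect_setequal(skew$scanner_id[which(skew$flagged)], truth)
  expect_identical(sum(skew$flagged), 5L)
  # medians recover delay - offset exactly
  est <- skew$median_skew_min[match(names(skew_fleet_offsets), skew$scanner_id)]
  expect_equal(est, 2 - unname(skew_fleet_offsets), tolerance = 1e-9)
})

test_that("PNG export scales min-max to the full 8-bit range and inverts MONOCHROME1", {
  fleet <- build_fleet(demo_scanners(c(MR01 = 0)), 1, seed = 18)
  f <- fleet$manifest$path[1]
  out <- tempfile(fileext = ".png")
  dicom_to_png(f, out)
  img <- png::readPNG(out)
  expect_equal(min(img), 0)
  expect_equal(max(img), 1)

  ds <- read_dicom(f)
  ds$PhotometricInterpretation <- "MONOCHROME1"
  ds <- ds[setdiff(names(ds), c("(0009,0010)", "(0009,1001)"))]
  inv_f <- tempfile(fileext = ".dcm")
  write_dicom(ds, inv_f)
  inv_out <- tempfile(fileext = ".png")
  dicom_to_png(inv_f, inv_out)
  inv <- png::readPNG(inv_out)
  expect_equal(inv, 1 - img, tolerance = 1 / 255)

  nopix <- ds[setdiff(names(ds), "PixelData")]
  nopix_f <- tempfile(fileext = ".dcm")
  write_dicom(nopix, nopix_f)
  expect_error(dicom_to_png(nopix_f, tempfile()), "pixel data")
})

test_that("de-identification keeps only the whitelist and preserves pixels and linkage", {
  fleet <- build_fleet(demo_scanners(c(MR01 = 0)), 1, seed = 19)
  same_series <- fleet$manifest[fleet$manifest$series_uid ==
                                fleet$manifest$series_uid[1], ]
  um <- uid_map(tempfile(fileext = ".json"))
  keep <- c("Modality", "BodyPartExamined")
  outs <- vapply(seq_len(nrow(same_series)), function(i) {
    o <- tempfile(fileext = ".dcm")
    deidentify(same_series$path[i], o, keep, um)
    o
  }, character(1))
  mandatory <- c("SOPClassUID", "SOPInstanceUID", "StudyInstanceUID",
                 "SeriesInstanceUID", "SamplesPerPixel",
                 "PhotometricInterpretation", "Rows", "Columns", "BitsAllocated",
                 "BitsStored", "HighBit", "PixelRepresentation", "PixelData")
  d1 <- read_dicom(outs[1])
  expect_true(all(names(d1) %in% c(keep, mandatory)))  # whitelist contract
  expect_false(any(default_phi_list() %in% names(d1)))
  # pixel digest preserved
  orig <- read_dicom(same_series$path[1])
  expect_identical(d1$PixelData, orig$PixelData)
  # UIDs remapped but consistent across the series
  d2 <- read_dicom(outs[2])
  expect_false(d1$SOPInstanceUID == orig$SOPInstanceUID)
  expect_identical(d1$SeriesInstanceUID, d2$SeriesInstanceUID)
  expect_false(d1$SOPInstanceUID == d2$SOPInstanceUID)
  # a PHI whitelist is refused before any write
  expect_error(deidentify(same_series$path[1], tempfile(), c("PatientName"), um),
               "PHI")
})
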