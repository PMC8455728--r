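# Metadata extractor: profile loading, representative selection, document
# extraction, idempotent cycles with crash recovery, datetime parsing and
# cohort filtering.

test_that("profiles load from text files, stripping PHI and keeping unknowns", {
  dir <- tempfile("profiles"); dir.create(dir)
  writeLines(c("Modality", "StationName", "# a comment",
               "AcquisitionDate  # trailing comment", "AcquisitionTime"),
             file.path(dir, "mri_ops.txt"))
  profs <- load_profiles(dir)
  expect_named(profs, "mri_ops")
  expect_identical(profs$mri_ops$attributes,
                   c("Modality", "StationName", "AcquisitionDate", "AcquisitionTime"))

  dir2 <- tempfile("profiles"); dir.create(dir2)
  writeLines(c("PatientName", "Modality"), file.path(dir2, "leaky.txt"))
  expect_warning(profs <- load_profiles(dir2), "dropping PHI.*PatientName")
  expect_identical(profs$leaky$attributes, "Modality")

  dir3 <- tempfile("profiles"); dir.create(dir3)
  writeLines(c("Modality", "NotARealKeyword"), file.path(dir3, "odd.txt"))
  expect_warning(profs <- load_profiles(dir3), "unknown attribute")
  expect_true("NotARealKeyword" %in% profs$odd$attributes)

  empty <- tempfile("noprofiles"); dir.create(empty)
  expect_identical(length(load_profiles(empty)), 0L)
})

test_that("representative selection orders by InstanceNumber with sop tie-break", {
  recs <- data.frame(sop_uid = c("c", "a", "b"), instance_number = c(3, 1, 2),
                     stringsAsFactors = FALSE)
  expect_identical(select_representative(recs, "first")$sop_uid, "a")

  ten <- data.frame(sop_uid = sprintf("s%02d", 1:10), instance_number = 1:10)
  expect_identical(nrow(select_representative(ten, "first")), 1L)
  fml <- select_representative(ten, "first_middle_last")
  expect_identical(fml$instance_number, c(1L, 5L, 10L))
  expect_identical(nrow(select_representative(ten, "all")), 10L)

  two <- data.frame(sop_uid = c("a", "b"), instance_number = c(1, 2))
  expect_identical(nrow(select_representative(two, "first_middle_last")), 2L)

  nonum <- data.frame(sop_uid = c("z", "y", "x"), instance_number = NA_real_)
  expect_identical(select_representative(nonum, "first")$sop_uid, "x")
  expect_error(select_representative(nonum[0, ], "first"), "empty series")
})

test_that("documents carry present attributes only, with lists for VM>1 and no PHI", {
  f <- tempfile(fileext = ".dcm")
  write_dicom(list(SOPClassUID = "1.2", SOPInstanceUID = "1.3",
                   SeriesInstanceUID = "1.4", Modality = "MR",
                   StationName = "SCAN01", PatientName = "DOE^JOHN",
                   ImageType = c("ORIGINAL", "PRIMARY")), f)
  record <- data.frame(series_uid = "1.4",
                       receipt_time = as.POSIXct("2020-01-15 08:02:00", tz = "UTC"))
  profile <- list(name = "ops",
                  attributes = c("Modality", "StationName", "AcquisitionDate",
                                 "AcquisitionTime", "ImageType", "PatientName"))
  doc <- extract_document(f, record, profile)
  expect_setequal(names(doc$values), c("Modality", "StationName", "ImageType"))
  expect_identical(doc$values$ImageType, c("ORIGINAL", "PRIMARY"))
  expect_false("PatientName" %in% names(doc$values))  # PHI enforced at extraction
  expect_identical(doc$receipt_time, "2020-01-15T08:02:00")
})

test_that("DICOM date/time pairs parse with precision tracking", {
  t1 <- parse_dicom_datetime("20200101", "120000")
  expect_identical(format(t1, "%Y-%m-%d %H:%M:%S", tz = "UTC"), "2020-01-01 12:00:00")
  expect_true(attr(t1, "full_precision"))

  t2 <- parse_dicom_datetime("20200101", "120000.123456")
  expect_equal(as.numeric(t2) - as.numeric(t1), 0.123456, tolerance = 1e-6)

  t3 <- parse_dicom_datetime("20200101", "")
  expect_identical(format(t3, "%H:%M:%S", tz = "UTC"), "00:00:00")
  expect_false(attr(t3, "full_precision"))

  expect_error(parse_dicom_datetime("2020-01-01", "120000"), "DA value")
  expect_error(parse_dicom_datetime("20200101", "12:00"), "TM value")
})

test_that("an extraction cycle is idempotent and exactly covers new series", {
  ef <- extracted_fleet(build_fleet(seed = 7))
  n_series <- length(unique(ef$manifest$series_uid))
  expect_identical(ef$cycle$written, n_series)
  expect_identical(length(ef$docs), n_series)
  again <- run_extraction_cycle(ef$root, ef$profiles, ef$store, ef$state_dir)
  expect_identical(again$written, 0L)
  # one document per (series, profile)
  sids <- vapply(ef$docs, function(d) d$series_uid, character(1))
  expect_false(anyDuplicated(sids) > 0L)
})

test_that("a crash between document write and state persist is harmless", {
  fleet <- build_fleet(seed = 8)
  ing <- ingest_fleet(fleet)
  profs <- load_profiles(ops_profile_dir())
  store <- doc_store(tempfile("docs"))
  sdir <- tempfile("state")
  # crash after the 2nd document, before any state persists
  n <- 0L
  expect_error(
    run_extraction_cycle(ing$root, profs, store, sdir,
                         on_document_written = function(sid, p) {
                           n <<- n + 1L
                           if (n == 2L) stop("simulated crash")
                         }),
    "simulated crash")
  expect_identical(length(load_state(sdir)$extracted$ops), 0L)
  # restart: upsert makes the duplicate writes harmless
  res <- run_extraction_cycle(ing$root, profs, store, sdir)
  n_series <- length(unique(fleet$manifest$series_uid))
  expect_identical(res$written, n_series)
  expect_identical(length(read_collection(store, "ops")), n_series)
  expect_setequal(load_state(sdir)$extracted$ops, unique(fleet$manifest$series_uid))
})

test_that("a profile added between cycles is back-filled without restart", {
  ef <- extracted_fleet(build_fleet(seed = 9))
  writeLines(c("Modality", "BodyPartExamined"),
             file.path(ef$profile_dir, "bodyparts.txt"))
  profs2 <- load_profiles(ef$profile_dir)
  expect_setequal(names(profs2), c("ops", "bodyparts"))
  res <- run_extraction_cycle(ef$root, profs2, ef$store, ef$state_dir)
  n_series <- length(unique(ef$manifest$series_uid))
  expect_identical(res$written, n_series)  # only the new profile back-fills
  expect_identical(length(read_collection(ef$store, "bodyparts")), n_series)
  expect_identical(length(read_collection(ef$store, "ops")), n_series)
})

test_that("an unparseable instance leaves its series pending for retry", {
  fleet <- build_fleet(demo_scanners(c(MR01 = 0)), 1, seed = 10)
  ing <- ingest_fleet(fleet)
  idx <- read_ingestion_index(ing$root)
  # corrupt the representative (lowest InstanceNumber) of one series
  sid <- idx$series_uid[1]
  victim <- idx$path[idx$series_uid == sid][1]
  writeBin(as.raw(0:99), file.path(ing$root, victim))
  profs <- load_profiles(ops_profile_dir())
  store <- doc_store(tempfile("docs"))
  sdir <- tempfile("state")
  res <- suppressMessages(
    run_extraction_cycle(ing$root, profs, store, sdir))
  expect_identical(res$skipped, 1L)
  expect_false(sid %in% load_state(sdir)$extracted$ops)
})

test_that("every stored document is PHI-free", {
  ef <- extracted_fleet(build_fleet(seed = 11))
  phi <- default_phi_list()
  for (d in ef$docs) {
    expect_identical(intersect(names(d$values), phi), character(0))
  }
})

test_that("cohort filters apply conjunctive, case-insensitive predicates", {
  profile <- list(name = "ops", attributes = c("Modality", "BodyPartExamined"))
  mods <- c(rep("DX", 6), rep("CR", 2), rep("MR", 2))
  docs <- lapply(seq_along(mods), function(i) {
    list(series_uid = paste0("s", i), profile = "ops",
         values = list(Modality = mods[i],
                       BodyPartExamined = if (i %% 2) "CHEST" else "ABDOMEN"))
  })
  # brute-force oracle over the fixture
  expect_identical(length(filter_cohort(docs, list(Modality = c("DX", "CR")),
                                        profile)), 8L)
  expect_identical(length(filter_cohort(docs, list(), profile)), 10L)
  both <- filter_cohort(docs, list(Modality = "mr", BodyPartExamined = "CHEST"),
                        profile)
  truth <- sum(mods == "MR" & seq_along(mods) %% 2 == 1)
  expect_identical(length(both), truth)
  expect_error(filter_cohort(docs, list(Manufacturer = "X"), profile),
               "absent from profile")
})
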