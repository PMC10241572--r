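test_that("a phantom-written series round-trips bit-identically", {
  g <- generate_phantom_volume("focal", phantom_spec(), seed = 7, patient_id = "FOC0007")
  d <- withr::local_tempdir()
  write_dicom_series(g$volume, d)
  v2 <- read_dicom_series(d)
  expect_equal(v2$patient_id, "FOC0007")
  expect_equal(v2$rescale_slope, 1)
  expect_equal(v2$rescale_intercept, -1024)
  expect_equal(v2$slice_positions, g$volume$slice_positions)
  expect_equal(v2$pixel_spacing, g$volume$pixel_spacing)
  for (i in seq_along(v2$slices))
    expect_true(all(v2$slices[[i]] == g$volume$slices[[i]]))
})

test_that("slices are ordered by scan-axis position regardless of file order", {
  d <- withr::local_tempdir()
  # three single-slice files with shuffled positions; constant pixel values
  # tag each slice so the sort is observable
  for (i in seq_along(pos <- c(12, 6, 9))) {
    v <- ct_volume("SORT", list(matrix(100L * i, 8, 8)),
                   slice_positions = pos[i])
    tmp <- file.path(d, sprintf("sub%d", i))
    write_dicom_series(v, tmp)
    file.copy(file.path(tmp, "slice_0001.dcm"),
              file.path(d, sprintf("f%d.dcm", i)))
    unlink(tmp, recursive = TRUE)
  }
  v2 <- read_dicom_series(d)
  expect_equal(v2$slice_positions, c(6, 9, 12))
  expect_equal(vapply(v2$slices, function(s) s[1, 1], 0), c(200, 300, 100))
})

test_that("duplicated positions and mixed series are rejected", {
  d <- withr::local_tempdir()
  for (i in 1:2) {
    v <- ct_volume("DUP", list(matrix(i, 8, 8)), slice_positions = 5)
    tmp <- file.path(d, sprintf("sub%d", i))
    write_dicom_series(v, tmp)
    file.copy(file.path(tmp, "slice_0001.dcm"),
              file.path(d, sprintf("f%d.dcm", i)))
    unlink(tmp, recursive = TRUE)
  }
  expect_error(read_dicom_series(d), "duplicated")

  d2 <- withr::local_tempdir()
  for (pid in c("A", "B")) {
    v <- ct_volume(pid, list(matrix(1, 8, 8)), slice_positions = 5)
    tmp <- file.path(d2, pid)
    write_dicom_series(v, tmp)
    file.copy(file.path(tmp, "slice_0001.dcm"),
              file.path(d2, sprintf("%s.dcm", pid)))
    unlink(tmp, recursive = TRUE)
  }
  expect_error(read_dicom_series(d2), "multiple DICOM series")
})

test_that("inconsistent slice shapes within a series are rejected", {
  d <- withr::local_tempdir()
  specs <- list(list(sz = 8, pos = 1), list(sz = 10, pos = 2))
  for (i in seq_along(specs)) {
    v <- ct_volume("SHAPE", list(matrix(1, specs[[i]]$sz, specs[[i]]$sz)),
                   slice_positions = specs[[i]]$pos)
    tmp <- file.path(d, sprintf("sub%d", i))
    write_dicom_series(v, tmp)
    file.copy(file.path(tmp, "slice_0001.dcm"),
              file.path(d, sprintf("f%d.dcm", i)))
    unlink(tmp, recursive = TRUE)
  }
  expect_error(read_dicom_series(d), "shapes")
})

test_that("written files conform to what an independent DICOM reader expects", {
  # pydicom, from the pre-installed scientific Python stack, is the oracle
  v <- noise_volume(n = 2, size = 16, pid = "ORACLE", seed = 3)
  d <- withr::local_tempdir()
  paths <- write_dicom_series(v, d)
  script <- sprintf(paste0(
    "import pydicom\n",
    "ds = pydicom.dcmread(r'%s')\n",
    "print(ds.PatientID, ds.Rows, ds.Columns, ds.RescaleIntercept,\n",
    "      float(ds.ImagePositionPatient[2]), int(ds.pixel_array.sum()))\n"),
    paths[1])
  f <- withr::local_tempfile(fileext = ".py")
  writeLines(script, f)
  out <- system2("python", f, stdout = TRUE)
  parts <- strsplit(out[length(out)], " +")[[1]]
  expect_equal(parts[1], "ORACLE")
  expect_equal(as.integer(parts[2:3]), c(16L, 16L))
  expect_equal(as.numeric(parts[4]), -1024)
  expect_equal(as.numeric(parts[5]), v$slice_positions[1])
  expect_equal(as.numeric(parts[6]), sum(v$slices[[1]]))
})
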