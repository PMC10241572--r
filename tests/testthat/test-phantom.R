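test_that("phantom generation is bit-reproducible", {
  g1 <- generate_phantom_volume("tubular", phantom_spec(), seed = 12, patient_id = "T")
  g2 <- generate_phantom_volume("tubular", phantom_spec(), seed = 12, patient_id = "T")
  expect_identical(g1$volume$slices, g2$volume$slices)
  expect_identical(g1$annotations, g2$annotations)
  g3 <- generate_phantom_volume("tubular", phantom_spec(), seed = 13, patient_id = "T")
  expect_false(identical(g1$volume$slices, g3$volume$slices))
})

test_that("tubular lesions drift monotonically along one direction", {
  for (seed in 1:10) {
    g <- generate_phantom_volume("tubular", phantom_spec(), seed = seed)
    proj <- g$lesion_centres %*% g$drift_direction
    expect_true(all(diff(proj) > 0))
    steps <- sqrt(rowSums(diff(g$lesion_centres)^2))
    expect_equal(steps, rep(3, 4))      # default drift 3 px per slice
  }
})

test_that("focal lesions stay centred on the middle position without consistent drift", {
  g <- generate_phantom_volume("focal", phantom_spec(), seed = 4)
  mid <- (nrow(g$lesion_centres) + 1) / 2
  offs <- sweep(g$lesion_centres, 2, g$lesion_centres[mid, ])
  d <- sqrt(rowSums(offs^2))
  expect_equal(d[mid], 0)
  expect_equal(d[-mid], rep(3, 4))      # displaced by drift_px from the middle
})

test_that("the middle slice is drawn from the class-shared sampler", {
  # structurally: the middle-slice lesion sits at the shared centre for both
  # classes, so the middle-slice construction cannot encode the class
  for (seed in c(3, 9)) {
    gt <- generate_phantom_volume("tubular", phantom_spec(), seed = seed)
    midt <- (nrow(gt$lesion_centres) + 1) / 2
    # tubular drift is symmetric about the shared middle position
    expect_equal(gt$lesion_centres[midt, ], colMeans(gt$lesion_centres))
  }
  # and the shared sampler places both classes' middle centres inside the
  # same safe region, with the same marginal law: compare empirical means
  mids <- function(cls) t(vapply(1:40, function(s)
    generate_phantom_volume(cls, phantom_spec(), seed = 1000 + s)$lesion_centres[3, ],
    numeric(2)))
  mt <- mids("tubular"); mf <- mids("focal")
  expect_lt(abs(mean(mt) - mean(mf)), 6)
})

test_that("annotation boxes contain the lesion with the configured margin", {
  spec <- phantom_spec()
  g <- generate_phantom_volume("tubular", spec, seed = 6)
  for (j in seq_along(g$annotations)) {
    ann <- g$annotations[[j]]
    c_rc <- g$lesion_centres[j, ]
    b <- ann$box                    # (x0, y0, w, h), 0-based
    expect_lte(b[1] + 1, c_rc[2] - 4)          # box starts left of the lesion
    expect_gte(b[1] + b[3], c_rc[2] + 4)
    expect_lte(b[2] + 1, c_rc[1] - 4)
    expect_gte(b[2] + b[4], c_rc[1] + 4)
    validate_annotation(ann, g$volume)
  }
})

test_that("lesion voxels are brighter than background by the configured contrast", {
  spec <- phantom_spec(noise_sd_hu = 0.0001)
  g <- generate_phantom_volume("tubular", spec, seed = 2)
  ann <- g$annotations[[3]]                     # middle lesion slice
  hu <- hu_slice(g$volume, ann$slice_index + 1)
  expect_equal(sort(unique(as.vector(round(hu)))), c(30, 90))
})

test_that("a cohort writes readable series and a stable manifest", {
  d <- withr::local_tempdir()
  co <- generate_cohort(2, phantom_spec(), seed = 5, out_dir = d)
  expect_equal(nrow(co$manifest), 2 * 2 * 5)    # patients x classes x lesion slices
  expect_setequal(unique(co$manifest$label), c("tubular", "focal"))
  expect_length(unique(co$manifest$patient_id), 4)
  # files on disk round-trip through the DICOM reader
  pid <- co$manifest$patient_id[1]
  v <- read_dicom_series(file.path(d, pid))
  expect_identical(lapply(v$slices, as.integer),
                   lapply(co$volumes[[pid]]$slices, as.integer))
  anns <- read_annotation_table(file.path(d, "annotations.csv"),
                                allowed_labels = c("tubular", "focal"))
  expect_length(anns, nrow(co$manifest))
  co2 <- generate_cohort(2, phantom_spec(), seed = 5)
  expect_identical(co$manifest, co2$manifest)
})

test_that("middle-slice crop intensities are indistinguishable between classes", {
  # the class signal must live only in cross-slice structure: the mean
  # intensity of the middle-slice crop cannot separate the classes
  crop_mean <- function(cls, seed) {
    g <- generate_phantom_volume(cls, phantom_spec(), seed = seed)
    mid <- (length(g$annotations) + 1) %/% 2
    ann <- g$annotations[[mid]]
    hu <- hu_slice(g$volume, ann$slice_index + 1)
    b <- ann$box
    mean(hu[(b[2] + 1):(b[2] + b[4]), (b[1] + 1):(b[1] + b[3])])
  }
  mt <- vapply(1:200, function(s) crop_mean("tubular", 5000 + s), 0)
  mf <- vapply(1:200, function(s) crop_mean("focal", 7000 + s), 0)
  ks <- suppressWarnings(stats::ks.test(mt, mf))
  expect_gt(ks$p.value, 0.01)
})

test_that("volumes too small for the lesion are refused", {
  expect_error(generate_phantom_volume("tubular", phantom_spec(height = 30, width = 30)),
               "cannot fit")
})
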