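# The synthetic multi-organ phantom generator.

test_that("forced presence with zero jitter yields every configured class", {
  org <- phantom_organs_small(64L)
  org$presence <- 1
  org$jitter <- 0
  org$rjitter <- 0
  spec <- phantom_spec(canvas = 64L, organs = org, noise_sd = 0,
                       ramp = 0, bg = 0.1)
  sl <- generate_slice(spec, seed = 1)
  expect_setequal(setdiff(unique(as.vector(sl$mask)), 0L), org$class)

  # noiseless, flat background: piecewise-constant image whose distinct
  # values are the configured intensities plus the background (the mirrored
  # pair shares one intensity by design)
  expect_equal(length(unique(as.vector(sl$image))),
               length(unique(org$intensity)) + 1L)
})

test_that("ellipse pixel area approximates pi * a * b", {
  # semi-axes (a, b) = (10, 5): radius = sqrt(50), aspect = sqrt(2)
  org <- data.frame(class = 1L, name = "e", lateral = "",
                    cy = 32, cx = 32, radius = sqrt(50), aspect = sqrt(2),
                    jitter = 0, rjitter = 0, intensity = 0.8, presence = 1)
  spec <- phantom_spec(canvas = 64L, organs = org, noise_sd = 0, ramp = 0)
  sl <- generate_slice(spec, seed = 2)
  area <- sum(sl$mask == 1L)
  expect_lt(abs(area - pi * 10 * 5) / (pi * 10 * 5), 0.05)
})

test_that("organs that cannot fit the canvas are rejected at spec validation", {
  org <- data.frame(class = 1L, name = "too_big", lateral = "",
                    cy = 16, cx = 16, radius = 20, aspect = 1,
                    jitter = 0, rjitter = 0, intensity = 0.5, presence = 1)
  expect_error(phantom_spec(canvas = 32L, organs = org), "cannot fit")
})

test_that("same seed regenerates byte-identical datasets", {
  spec <- phantom_spec(canvas = 32L, organs = phantom_organs_small(32L),
                       n_patients = 2L, slices_per_patient = 2L, seed = 4L)
  d1 <- tempfile(); d2 <- tempfile()
  generate_dataset(spec, d1)
  generate_dataset(spec, d2)
  for (f in list.files(file.path(d1, "masks"))) {
    b1 <- readBin(file.path(d1, "masks", f), "raw", 1e6)
    b2 <- readBin(file.path(d2, "masks", f), "raw", 1e6)
    expect_identical(b1, b2)
  }
  m <- read.csv(file.path(d1, "manifest.csv"))
  expect_equal(nrow(m), 4L)
  unlink(c(d1, d2), recursive = TRUE)

  # n_patients x slices_per_patient manifest records
  spec10 <- phantom_spec(canvas = 32L, organs = phantom_organs_small(32L),
                         n_patients = 10L, slices_per_patient = 4L, seed = 5L)
  ds <- phantom_dataset(spec10)
  expect_equal(dim(ds$images)[4], 40L)
  expect_equal(length(ds$patient_id), 40L)
})

test_that("presence frequencies follow the configured probabilities", {
  org <- phantom_organs_small(32L)
  org$presence[4] <- 0.5
  spec <- phantom_spec(canvas = 32L, organs = org, noise_sd = 0)
  n <- 400L
  hits <- 0L
  for (i in seq_len(n)) {
    sl <- generate_slice(spec, seed = 1000L + i)
    hits <- hits + as.integer(any(sl$mask == 4L))
  }
  sd3 <- 3 * sqrt(0.5 * 0.5 / n)
  expect_lt(abs(hits / n - 0.5), sd3)
})

test_that("masks contain only declared labels and images stay in [0, 1]", {
  spec <- phantom_spec(canvas = 64L, organs = default_phantom_organs(64L),
                       n_patients = 1L, slices_per_patient = 4L, seed = 6L)
  ds <- phantom_dataset(spec)
  expect_true(all(ds$masks %in% c(0L, spec$organs$class)))
  expect_true(all(is.finite(ds$images)))
  expect_true(all(ds$images >= 0 & ds$images <= 1))
})

test_that("small organ classes occupy a small share of the foreground", {
  # the size spectrum must preserve the small-organ difficulty regime:
  # every organ whose radius is at most 0.45 of the largest (eyes,
  # submandibular glands, thyroid in the default population) averages
  # under 5% of foreground pixels
  spec <- phantom_spec(canvas = 128L, organs = default_phantom_organs(128L),
                       n_patients = 1L, slices_per_patient = 20L, seed = 7L)
  org <- spec$organs
  small_cls <- org$class[org$radius <= 0.45 * max(org$radius)]
  expect_gte(length(small_cls), 3L)
  ds <- phantom_dataset(spec)
  fg <- sum(ds$masks != 0L)
  for (cls in small_cls) {
    expect_lt(sum(ds$masks == cls) / fg, 0.05)
  }
})
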