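test_that("phantom region means match their nominal temperatures", {
  spec <- phantom_spec(foot_temp = 36.9, seed = 71,
                       hotspot = hotspot_spec("disk", 1.5, delta_T = 2.5))
  ph <- make_phantom(spec)
  expect_equal(mean(ph$thermogram$temps[ph$hotspot_mask]), 39.4, tolerance = 0.1)
  expect_equal(mean(ph$thermogram$temps[ph$feet_mask & !ph$hotspot_mask]), 36.9,
               tolerance = 0.1)
  expect_true(all(ph$hotspot_mask[ph$hotspot_mask] & ph$feet_mask[ph$hotspot_mask]))
  expect_false(any(ph$left_mask & ph$right_mask))
})

test_that("a noiseless phantom is two-valued outside the transition band", {
  ph <- make_phantom(phantom_spec(seed = 72, noise_sigma = 0, foot_temp = 34))
  band <- dilate_mask(ph$feet_mask, se_diamond(4)) & !ph$feet_mask
  vals <- unique(as.vector(ph$thermogram$temps[!band]))
  expect_setequal(vals, c(18, 34))
})

test_that("phantoms are deterministic in the seed", {
  a <- make_phantom(phantom_spec(seed = 73))
  b <- make_phantom(phantom_spec(seed = 73))
  c <- make_phantom(phantom_spec(seed = 74))
  expect_identical(a$thermogram$temps, b$thermogram$temps)
  expect_false(identical(a$thermogram$temps, c$thermogram$temps))
})

test_that("phantom temperatures stay in range and noise within bounds", {
  for (s in 75:79) {
    spec <- phantom_spec(seed = s, foot_temp = stats::runif(1, 33, 37),
                         hotspot = hotspot_spec("disk", 1.5, 3))
    ph <- make_phantom(spec)
    quiet <- make_phantom(utils::modifyList(spec, list(noise_sigma = 0)))
    expect_true(all(ph$thermogram$temps >= -20 & ph$thermogram$temps <= 120))
    expect_lt(max(abs(ph$thermogram$temps - quiet$thermogram$temps)), 5 * 0.1)
  }
})

test_that("invalid hotspot placements are rejected", {
  expect_error(make_phantom(phantom_spec(
    hotspot = hotspot_spec("disk", 1.5, 2.5, center = c(5, 5)))), "inside")
  expect_error(phantom_spec(background_temp = 40, foot_temp = 35), "colder")
  expect_error(hotspot_spec("blob"), "arg")
})

test_that("shape rasterization matches the stated geometry", {
  dims <- c(60, 60)
  disk <- shape_mask("disk", 1.5, c(30, 30), 0.25, dims)   # radius 3 px
  expect_lt(abs(sum(disk) - pi * 9) / (pi * 9), 0.15)

  rect <- shape_mask("rectangle", 2, c(30, 30), 0.25, dims)
  ij <- which(rect, arr.ind = TRUE)
  expect_identical(diff(range(ij[, "col"])) + 1L, 8L)      # length 8 px
  expect_identical(diff(range(ij[, "row"])) + 1L, 4L)      # 2:1 aspect
  expect_identical(sum(rect), 32L)

  ring <- shape_mask("half-ring", 2, c(30, 30), 0.25, dims)
  annulus <- shape_mask("disk", 2, c(30, 30), 0.25, dims) &
    !shape_mask("disk", 1, c(30, 30), 0.25, dims)
  expect_true(all(annulus[ring]))                          # subset of annulus
  expect_false(any(ring[31:60, ]))                         # lower half removed
  expect_error(shape_mask("star", 1, c(30, 30), 0.25, dims), "arg")
})

test_that("detect_otsu recovers the planted elevation across seeds", {
  for (dT in c(2.2, 2.5, 3.0)) {
    err <- vapply(1:20, function(s) {
      ph <- hot_phantom(seed = 3000 + s, delta_T = dT,
                        foot_temp = stats::runif(1, 34, 37))
      res <- detect_otsu(ph$thermogram, segment_feet(ph$thermogram))
      abs(res$mu_d - dT)
    }, 0)
    expect_lt(max(err), 0.15)
  }
})

test_that("the fixture suite writes eight images with round-tripping manifest", {
  out <- file.path(tempdir(), "thermofoot-fixtures")
  unlink(out, recursive = TRUE)
  files <- make_fixture_suite(out)
  csvs <- list.files(out, pattern = "\\.csv$")
  expect_identical(length(csvs), 8L)
  expect_true(file.exists(file.path(out, "manifest.json")))

  specs <- read_fixture_manifest(file.path(out, "manifest.json"))
  expect_identical(length(specs), 8L)
  again <- thermofoot:::fixture_specs(20170L)
  for (i in 1:8) expect_equal(specs[[i]], again[[i]], tolerance = 0)

  # the healthy fixture classifies as no-ulcer
  tg <- read_thermogram(file.path(out, "image01.csv"))
  res <- detect_otsu(tg, segment_feet(tg))
  expect_identical(res$decision, "no-ulcer")
  unlink(out, recursive = TRUE)
})
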