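test_that("structuring elements enforce origin and symmetry", {
  se <- se_diamond(1)
  expect_identical(nrow(se$offsets), 5L)
  expect_true(any(se$offsets[, 1] == 0 & se$offsets[, 2] == 0))
  expect_error(structuring_element(matrix(c(1L, 0L), 1)), "origin")
  expect_error(structuring_element(matrix(c(0L, 0L, 1L, 0L), 2, byrow = TRUE)),
               "symmetric")
})

test_that("border clearing removes exactly the border-connected components", {
  m <- matrix(FALSE, 6, 6); m[1, 3] <- TRUE; m[2, 3] <- TRUE
  expect_false(any(clear_border(m)))

  m <- matrix(FALSE, 8, 8)
  m[3:5, 3:5] <- TRUE                  # interior block
  m[7:8, 1:2] <- TRUE                  # touches two borders
  out <- clear_border(m)
  expect_identical(sum(out), 9L)
  expect_true(all(out[3:5, 3:5]))

  set.seed(8)
  for (i in 1:25) {
    m <- random_mask(9, 11, p = stats::runif(1, 0.2, 0.6))
    out <- clear_border(m)
    expect_identical(out, brute_clear_border(m))
    expect_true(all(m[out]))                             # anti-extensive
    expect_false(any(out & thermofoot:::border_mask(9, 11)))
    expect_identical(clear_border(out), out)             # idempotent
  }
})

test_that("diamond erosion follows the neighborhood definition", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_false(any(erode_mask(m)))

  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  out <- erode_mask(m)
  expect_identical(which(out), which(matrix(FALSE, 5, 5) | {
    x <- matrix(FALSE, 5, 5); x[3, 3] <- TRUE; x
  }))

  # out-of-bounds counts as background: a full mask erodes at the frame
  full <- matrix(TRUE, 4, 6)
  expect_identical(sum(erode_mask(full)), 2L * 4L)

  set.seed(9)
  for (i in 1:20) {
    m <- random_mask(8, 8)
    out <- erode_mask(m)
    expect_true(all(m[out]))                             # anti-extensive
    expect_true(all(out[erode_mask(out)]))               # monotone under repetition
  }
})

test_that("hole filling closes interior background and is idempotent", {
  ring <- matrix(TRUE, 5, 5); ring[2:4, 2:4] <- FALSE   # 5x5 donut
  expect_true(all(fill_holes(ring)))

  no_holes <- matrix(FALSE, 6, 6); no_holes[2:3, 2:5] <- TRUE
  expect_identical(fill_holes(no_holes), no_holes)

  set.seed(10)
  for (i in 1:20) {
    m <- random_mask(8, 10)
    out <- fill_holes(m)
    expect_true(all(out[m]))                             # extensive
    expect_identical(fill_holes(out), out)               # idempotent
  }
})

test_that("hole filling uses 4-connectivity for background", {
  # ring with one corner missing: the interior background can escape only
  # diagonally, which 4-connectivity forbids, so the pocket counts as a hole
  m <- matrix(FALSE, 5, 5)
  m[2, 2:4] <- TRUE; m[4, 2:4] <- TRUE; m[3, c(2, 4)] <- TRUE
  m[2, 2] <- FALSE                       # open a diagonal corner
  filled <- fill_holes(m)
  expect_true(filled[3, 3])
  expect_false(filled[2, 2])             # the corner itself stays background
})

test_that("connected-component labelling distinguishes 4- and 8-connectivity", {
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(max(label_components(m, 8)), 1L)
  expect_identical(max(label_components(m, 4)), 2L)
})

test_that("smooth_mask applies clearing, erosion and filling in order", {
  expect_false(any(smooth_mask(matrix(FALSE, 6, 6))))

  # border blob removed, interior block eroded then hole-filled
  m <- matrix(FALSE, 10, 10)
  m[1:3, 6:9] <- TRUE                    # border-touching
  m[4:9, 2:7] <- TRUE; m[6, 4] <- FALSE  # interior block with a pinhole
  out <- smooth_mask(m)
  expect_false(any(out[1:3, 8:9]))
  expect_identical(out, fill_holes(erode_mask(clear_border(m))))
})

test_that("mask PNG export round-trips", {
  set.seed(12)
  m <- random_mask(7, 9)
  f <- tempfile(fileext = ".png")
  write_mask_png(m, f)
  expect_identical(read_mask_png(f), m)
})
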