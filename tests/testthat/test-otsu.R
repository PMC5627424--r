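test_that("gray histograms count pixels and normalize to probabilities", {
  q <- quantize(thermogram(matrix(c(20, 20, 30, 30), 2, byrow = TRUE)), 256)
  h <- gray_histogram(q)
  expect_identical(h$n[1], 2L)
  expect_identical(h$n[256], 2L)
  expect_equal(h$p[1], 0.5)
  expect_identical(h$N, 4L)

  top <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  h2 <- gray_histogram(q, mask = top)
  expect_identical(h2$N, 2L)
  expect_equal(h2$p[1], 1)

  set.seed(2)
  q3 <- quantize(thermogram(matrix(stats::runif(64, 20, 40), 8)), 64)
  h3 <- gray_histogram(q3)
  expect_equal(sum(h3$p), 1, tolerance = 1e-12)
  expect_identical(sum(h3$n), 64L)
  expect_error(gray_histogram(q3, mask = matrix(FALSE, 8, 8)), "degenerate")
})

test_that("evaluate_split reproduces the direct two-group decomposition", {
  h <- histogram_from_counts(c(5, 5, 0, 0, 0, 0, 3, 7))
  s <- evaluate_split(h, 1)
  b <- brute_split(c(5, 5, 0, 0, 0, 0, 3, 7), 1)
  for (f in c("w1", "w2", "u1", "u2", "uT", "sigmaW_sq", "sigmaB_sq")) {
    expect_equal(s[[f]], b[[f]], tolerance = 1e-12, label = f)
  }
  # point masses at the scale ends
  pm <- histogram_from_counts(c(3, rep(0, 254), 9))
  s2 <- evaluate_split(pm, 100)
  expect_equal(s2$w1, 0.25)
  expect_equal(s2$u1, 0)
  expect_equal(s2$u2, 255)
  expect_error(evaluate_split(h, -1), "valid range")
  expect_error(evaluate_split(h, 7), "valid range")
})

test_that("variance decomposition identity holds for every threshold", {
  set.seed(4)
  for (i in 1:40) {
    n <- random_counts(sample(8:64, 1))
    h <- histogram_from_counts(n)
    i_lev <- 0:(h$L - 1)
    total_var <- sum((i_lev - sum(i_lev * h$p))^2 * h$p)
    for (t in 0:(h$L - 2)) {
      s <- evaluate_split(h, t)
      expect_equal(s$sigmaW_sq + s$sigmaB_sq, total_var, tolerance = 1e-9)
      expect_equal(s$w1 + s$w2, 1, tolerance = 1e-12)
      expect_equal(s$uT, s$w1 * s$u1 + s$w2 * s$u2, tolerance = 1e-9)
    }
  }
})

test_that("otsu_threshold matches exhaustive search and the min-sigmaW dual", {
  set.seed(5)
  for (i in 1:200) {
    n <- random_counts(sample(8:64, 1))
    h <- histogram_from_counts(n)
    s <- otsu_threshold(h)
    # achieves the exhaustive-search optimum (ties between distinct splits
    # can fall either way at machine precision, so compare the objective)
    b <- brute_split(n, brute_otsu(n))
    expect_true(s$t == brute_otsu(n) ||
                  abs(s$sigmaB_sq - b$sigmaB_sq) < 1e-12 * max(1, b$sigmaB_sq))
    sW <- vapply(0:(h$L - 2), function(t) evaluate_split(h, t)$sigmaW_sq, 0)
    expect_equal(s$sigmaW_sq, min(sW), tolerance = 1e-9)
    # scale invariance of the selected threshold
    expect_identical(otsu_threshold(histogram_from_counts(7 * n))$t, s$t)
  }
})

test_that("plateaus break ties at the smallest threshold", {
  n <- rep(0, 256); n[11] <- 40; n[201] <- 60   # mass at levels 10 and 200
  s <- otsu_threshold(histogram_from_counts(n))
  expect_identical(s$t, 10L)
  expect_equal(s$t_norm, 10 / 255)
})

test_that("the threshold separates two well-separated lobes", {
  set.seed(6)
  for (i in 1:10) {
    lo <- pmin(pmax(round(stats::rnorm(300, 40, 8)), 0), 255)
    hi <- pmin(pmax(round(stats::rnorm(200, 200, 10)), 0), 255)
    s <- otsu_threshold(histogram_from_counts(tabulate(c(lo, hi) + 1, 256)))
    expect_gte(s$t, max(lo))     # every low-lobe sample is background
    expect_lt(s$t, min(hi))      # every high-lobe sample is foreground
  }
  expect_error(otsu_threshold(histogram_from_counts(c(0, 5, 0, 0))), "degenerate")
})

test_that("binarize labels the warm side as foreground", {
  q <- quantize(thermogram(matrix(c(20, 20, 30, 30), 2, byrow = TRUE)), 256)
  expect_identical(binarize(q, 100), matrix(c(FALSE, TRUE, FALSE, TRUE), 2))
  expect_identical(sum(binarize(q, 254L)), 2L)   # only max-level pixels
  # Otsu split exactly recovers two populations on a two-valued image
  h <- gray_histogram(q)
  m <- binarize(q, otsu_threshold(h)$t)
  expect_identical(m, q$levels == 255L)
})
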