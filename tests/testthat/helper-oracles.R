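# Independent oracles: deliberately naive implementations used only to check
# the package's vectorized code paths.

# Between/within-region variances of a two-group split computed directly from
# the counts, one level at a time.
brute_split <- function(counts, t) {
  L <- length(counts)
  i <- 0:(L - 1)
  N <- sum(counts)
  g1 <- i <= t
  n1 <- sum(counts[g1]); n2 <- N - n1
  w1 <- n1 / N; w2 <- n2 / N
  u1 <- if (n1 > 0) sum(i[g1] * counts[g1]) / n1 else 0
  u2 <- if (n2 > 0) sum(i[!g1] * counts[!g1]) / n2 else 0
  uT <- sum(i * counts) / N
  v1 <- if (n1 > 0) sum((i[g1] - u1)^2 * counts[g1]) / n1 else 0
  v2 <- if (n2 > 0) sum((i[!g1] - u2)^2 * counts[!g1]) / n2 else 0
  sB <- if (n1 > 0 && n2 > 0) w1 * (u1 - uT)^2 + w2 * (u2 - uT)^2 else 0
  list(w1 = w1, w2 = w2, u1 = u1, u2 = u2, uT = uT,
       sigmaW_sq = w1 * v1 + w2 * v2, sigmaB_sq = sB)
}

# Exhaustive-search threshold: argmax of sigmaB over all t, first tie wins.
brute_otsu <- function(counts) {
  L <- length(counts)
  sB <- vapply(0:(L - 2), function(t) brute_split(counts, t)$sigmaB_sq, 0)
  which.max(sB) - 1L
}

# Queue-based flood fill from the border, pixel by pixel (8-connectivity),
# for checking clear_border.
brute_clear_border <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  queue <- which(mask & thermofoot:::border_mask(nr, nc))
  seen[queue] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    r <- ((p - 1) %% nr) + 1; c <- ((p - 1) %/% nr) + 1
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          mask[rr, cc] && !seen[rr, cc]) {
        seen[rr, cc] <- TRUE
        queue <- c(queue, (cc - 1) * nr + rr)
      }
    }
  }
  mask & !seen
}

random_mask <- function(nr, nc, p = 0.4) matrix(stats::runif(nr * nc) < p, nr, nc)

random_counts <- function(L, max_count = 20) {
  n <- stats::rpois(L, lambda = 2) * sample(0:1, L, replace = TRUE, prob = c(0.4, 0.6))
  if (sum(n > 0) < 2) n[sample(L, 2)] <- c(5, 7)
  n
}

# Standard hotspot phantom used across detector tests.
hot_phantom <- function(seed, delta_T = 2.5, foot_temp = 36, shape = "disk",
                        size_cm = 1.5, side = "right", ...) {
  hs <- if (delta_T > 0) hotspot_spec(shape, size_cm, delta_T, side) else NULL
  make_phantom(phantom_spec(foot_temp = foot_temp, hotspot = hs, seed = seed, ...))
}

overlap_frac <- function(found, truth) sum(found & truth) / sum(truth)
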