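#' Gray-level histogram
#'
#' Counts pixels at each gray level `i` in `0..L-1` and normalizes to
#' probabilities `p_i = n_i / N`, where `n_i` is the number of pixels at level
#' `i` and `N` the number of counted pixels. With a mask only masked-in pixels
#' are counted.
#'
#' @param q a `quantized_image` from [quantize()].
#' @param mask optional logical matrix; must select at least 2 pixels.
#' @return Object of class `gray_histogram`: list with counts `n` (length
#'   `L`), probabilities `p`, total `N` and level count `L`.
#' @export
gray_histogram <- function(q, mask = NULL) {
  stopifnot(inherits(q, "quantized_image"))
  lev <- q$levels
  if (!is.null(mask)) {
    check_mask(mask, dim(lev))
    lev <- lev[mask]
    if (length(lev) < 2L) {
      stop("degenerate input: mask selects fewer than 2 pixels", call. = FALSE)
    }
  }
  n <- tabulate(as.vector(lev) + 1L, nbins = q$L)
  N <- sum(n)
  structure(list(n = n, p = n / N, N = N, L = q$L), class = "gray_histogram")
}

#' Build a gray histogram directly from level counts
#'
#' Convenience constructor for threshold-selection work that starts from
#' counts rather than an image: `n[i]` is the number of pixels at level
#' `i - 1`.
#'
#' @param n non-negative counts, one per gray level.
#' @return a `gray_histogram`.
#' @export
histogram_from_counts <- function(n) {
  n <- as.numeric(n)
  stopifnot(length(n) >= 2L, all(n >= 0), sum(n) > 0)
  structure(list(n = n, p = n / sum(n), N = sum(n), L = length(n)),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("<gray_histogram> L = %d, N = %d, %d occupied levels\n",
              x$L, x$N, sum(x$n > 0)))
  invisible(x)
}

#' Evaluate a two-region histogram split
#'
#' Splits the gray scale at threshold `t` into region 1 (levels `0..t`) and
#' region 2 (levels `t+1..L-1`) and computes the classical Otsu quantities:
#' region probability masses \eqn{w_1, w_2}, region means
#' \eqn{u_k = \sum_i i\,p_i / w_k}, total mean \eqn{u_T = w_1 u_1 + w_2 u_2},
#' region variances \eqn{\sigma_k^2 = \sum_i (i - u_k)^2 p_i / w_k}, the
#' within-region variance \eqn{\sigma_W^2 = w_1\sigma_1^2 + w_2\sigma_2^2}
#' and the between-region variance
#' \eqn{\sigma_B^2 = w_1(u_1-u_T)^2 + w_2(u_2-u_T)^2}.
#'
#' For every threshold \eqn{\sigma_W^2 + \sigma_B^2} equals the total
#' gray-level variance, so maximizing \eqn{\sigma_B^2} and minimizing
#' \eqn{\sigma_W^2} select the same threshold. An empty region contributes
#' mean and variance 0, which forces \eqn{\sigma_B^2 = 0} there, so such
#' thresholds can never win the search.
#'
#' @param h a `gray_histogram`.
#' @param t candidate threshold level, `0 <= t <= L-2`.
#' @return Object of class `otsu_split` with fields `t`, `t_norm` (`t/(L-1)`),
#'   `w1`, `w2`, `u1`, `u2`, `uT`, `sigma1_sq`, `sigma2_sq`, `sigmaW_sq`,
#'   `sigmaB_sq`.
#' @export
evaluate_split <- function(h, t) {
  stopifnot(inherits(h, "gray_histogram"))
  t <- as.integer(t)
  if (is.na(t) || t < 0L || t > h$L - 2L) {
    stop(sprintf("threshold t = %s outside the valid range [0, %d]",
                 as.character(t), h$L - 2L), call. = FALSE)
  }
  i <- 0:(h$L - 1L)
  p <- h$p
  lo <- i <= t
  w1 <- sum(p[lo]); w2 <- sum(p[!lo])
  u1 <- if (w1 > 0) sum(i[lo] * p[lo]) / w1 else 0
  u2 <- if (w2 > 0) sum(i[!lo] * p[!lo]) / w2 else 0
  uT <- w1 * u1 + w2 * u2
  s1 <- if (w1 > 0) sum((i[lo] - u1)^2 * p[lo]) / w1 else 0
  s2 <- if (w2 > 0) sum((i[!lo] - u2)^2 * p[!lo]) / w2 else 0
  sB <- if (w1 > 0 && w2 > 0) w1 * (u1 - uT)^2 + w2 * (u2 - uT)^2 else 0
  structure(list(t = t, t_norm = t / (h$L - 1L), w1 = w1, w2 = w2,
                 u1 = u1, u2 = u2, uT = uT,
                 sigma1_sq = s1, sigma2_sq = s2,
                 sigmaW_sq = w1 * s1 + w2 * s2, sigmaB_sq = sB),
            class = "otsu_split")
}

#' @export
print.otsu_split <- function(x, ...) {
  cat(sprintf(paste0("<otsu_split> t = %d (t/(L-1) = %.4f)\n",
                     "  w = (%.4f, %.4f), u = (%.2f, %.2f), uT = %.2f\n",
                     "  sigmaB^2 = %.4f, sigmaW^2 = %.4f\n"),
              x$t, x$t_norm, x$w1, x$w2, x$u1, x$u2, x$uT,
              x$sigmaB_sq, x$sigmaW_sq))
  invisible(x)
}

#' Otsu threshold selection
#'
#' Selects the threshold `t` in `0..L-2` that maximizes the between-region
#' variance \eqn{\sigma_B^2(t)} (equivalently minimizes the within-region
#' variance). Plateau ties are broken deterministically by the smallest `t`.
#'
#' @param h a `gray_histogram` with at least two occupied levels.
#' @return the winning [evaluate_split()] result (class `otsu_split`).
#' @examples
#' h <- histogram_from_counts(c(5, 5, 0, 0, 0, 0, 3, 7))
#' otsu_threshold(h)$t
#' @export
otsu_threshold <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  if (sum(h$n > 0) < 2L) {
    stop("degenerate input: histogram has fewer than 2 occupied levels", call. = FALSE)
  }
  i <- 0:(h$L - 1L)
  p <- h$p
  w1 <- cumsum(p)
  m1 <- cumsum(i * p)
  uT <- m1[h$L]
  w2 <- 1 - w1
  # sigmaB(t) = w1*(u1-uT)^2 + w2*(u2-uT)^2 = (uT*w1 - m1)^2 / (w1*w2)
  num <- (uT * w1 - m1)^2
  den <- w1 * w2
  sB <- ifelse(den > 0, num / den, 0)
  sB <- sB[seq_len(h$L - 1L)]            # candidate t in 0..L-2
  t_best <- which.max(sB) - 1L           # first maximum: smallest t on plateaus
  evaluate_split(h, t_best)
}

#' Binarize a quantized image at a threshold
#'
#' Foreground (the warm object) is every pixel with level strictly greater
#' than `t`; background is everything at or below.
#'
#' @param q a `quantized_image`.
#' @param t threshold level.
#' @return logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(q, t) {
  stopifnot(inherits(q, "quantized_image"))
  t <- as.integer(t)
  if (is.na(t)) stop("`t` must be an integer level", call. = FALSE)
  q$levels > t
}
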