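#' Reference mean temperatures from a published smartphone-thermography trial
#'
#' Per-image mean temperatures for eight plantar test thermograms (one
#' unheated, seven with a heated object applied to the skin) acquired with a
#' FLIR ONE smartphone camera: the feet (background) mean `mu_n`, the
#' suspected-region (foreground) mean `mu_h`, the printed mean difference
#' `mu_d` from the second-stage Otsu technique, the camera's own spot
#' measurement of the difference, and the contralateral point-to-point mean
#' difference. Bundled so the decision arithmetic can be validated against
#' published numbers without any image data.
#'
#' @return data frame with columns `image`, `mu_n`, `mu_h`, `mu_d_printed`,
#'   `camera_diff`, `p2p_diff` (all temperatures in degrees C).
#' @export
reference_measurements <- function() {
  data.frame(
    image        = 1:8,
    mu_n         = c(33.2, 36.9, 35.5, 35.3, 36.2, 36.3, 36.2, 34.8),
    mu_h         = c(35.0, 39.4, 38.0, 37.8, 38.4, 38.5, 38.6, 37.0),
    mu_d_printed = c(1.8, 2.5, 2.5, 2.5, 2.2, 2.2, 2.4, 2.2),
    camera_diff  = c(1.7, 2.4, 2.4, 2.5, 2.3, 2.2, 2.5, 2.3),
    p2p_diff     = c(0, 2.4, 2.5, 2.6, 2.2, 2.3, 2.6, 2.3)
  )
}

#' Classify a mean temperature difference against the hyperthermia threshold
#'
#' The clinical rule: a region whose mean temperature exceeds the surrounding
#' (or contralateral) tissue mean by at least `delta` = 2.2 degrees C is
#' hyperthermic, an early indicator of ulceration. Comparison happens after
#' rounding the difference to one decimal, the precision at which such
#' measurements are reported, so a difference printing as 2.2 counts as
#' suspect.
#'
#' @param mu_h suspected-region mean temperature(s), degrees C.
#' @param mu_n reference (feet) mean temperature(s), degrees C.
#' @param delta decision threshold in degrees C (default 2.2).
#' @return data frame with columns `mu_n`, `mu_h`, `mu_d` (= `mu_h - mu_n`)
#'   and logical `suspected`.
#' @examples
#' classify_mean_difference(c(35.0, 39.4), c(33.2, 36.9))
#' @export
classify_mean_difference <- function(mu_h, mu_n, delta = 2.2) {
  stopifnot(length(mu_h) == length(mu_n), delta > 0)
  mu_d <- mu_h - mu_n
  data.frame(mu_n = mu_n, mu_h = mu_h, mu_d = mu_d,
             suspected = round(mu_d, 1L) >= delta)
}

#' Hyperthermia detection by second-stage Otsu mean difference
#'
#' Re-runs Otsu thresholding on the foot pixels only: the feet now play the
#' role of the background and any warmer region (a possible ulcer site) the
#' foreground. The decision combines two reported criteria:
#' \enumerate{
#'   \item the mean difference `mu_d = mu_h - mu_n` between the suspected
#'     region and the rest of the feet must reach `delta` (2.2 degrees C)
#'     after rounding to one decimal, and
#'   \item a one-sided Welch two-sample t-test must find the two pixel
#'     populations statistically different (`p < alpha`). The null shift of
#'     the test defaults to 0 (are the means different?); set `null_shift =
#'     delta` to instead test whether the difference exceeds the threshold
#'     itself.
#' }
#' A guard completes the decision: the suspected (warm) class must cover at
#' most half of the feet. A lesion is a localized warm minority; when the
#' histogram split instead isolates a small cool tail (e.g. shaded or
#' poorly-segmented boundary pixels), the "warm" class is nearly the whole
#' foot surface and the mean difference, however large, does not indicate
#' hyperthermia. All criteria are reported separately for auditability.
#'
#' @param tg a [thermogram()].
#' @param feet logical feet mask, e.g. from [segment_feet()].
#' @param delta hyperthermia threshold in degrees C (default 2.2).
#' @param alpha significance level of the t-test (default 0.05).
#' @param L gray-level count for the second-stage histogram (default 256;
#'   the scale is stretched over the foot-pixel temperature range).
#' @param null_shift null-hypothesis difference of the Welch test (degrees C).
#' @return Object of class `otsu_detection`: list with `mu_n`, `mu_h`, `mu_d`,
#'   `t_stat`, `df`, `p_value`, `decision` (`"ulcer-suspected"` or
#'   `"no-ulcer"`), `region_mask` (logical, subset of `feet`), the
#'   second-stage `split`, pixel counts `n_h`/`n_n`, and the parameters used.
#' @examples
#' ph <- make_phantom(phantom_spec(foot_temp = 36.9,
#'   hotspot = hotspot_spec(delta_T = 2.5), seed = 7))
#' detect_otsu(ph$thermogram, segment_feet(ph$thermogram))
#' @export
detect_otsu <- function(tg, feet, delta = 2.2, alpha = 0.05, L = 256L,
                        null_shift = 0) {
  stopifnot(is_thermogram(tg), delta > 0, alpha > 0, alpha < 1)
  check_mask(feet, dim(tg$temps), "feet")
  if (!any(feet)) stop("degenerate input: empty feet mask", call. = FALSE)
  q <- quantize(tg, L, mask = feet)        # errors if feet are single-temperature
  s <- otsu_threshold(gray_histogram(q, feet))
  region <- binarize(q, s$t) & feet
  th <- tg$temps[region]
  tn <- tg$temps[feet & !region]
  mu_h <- mean(th); mu_n <- mean(tn)
  mu_d <- mu_h - mu_n
  tt <- tryCatch(
    stats::t.test(th, tn, alternative = "greater", mu = null_shift,
                  var.equal = FALSE),
    error = function(e) NULL)
  p_value <- if (is.null(tt)) NA_real_ else unname(tt$p.value)
  mean_rule <- round(mu_d, 1L) >= delta
  test_rule <- !is.na(p_value) && p_value < alpha
  # a lesion is a warm minority of the foot surface; a "warm" class covering
  # most of the feet means the split isolated a cool tail instead
  minority_rule <- length(th) <= length(tn)
  structure(list(
    mu_n = mu_n, mu_h = mu_h, mu_d = mu_d,
    t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
    p_value = p_value,
    mean_rule = mean_rule, test_rule = test_rule, minority_rule = minority_rule,
    decision = if (mean_rule && test_rule && minority_rule) "ulcer-suspected" else "no-ulcer",
    region_mask = region, split = s,
    n_h = length(th), n_n = length(tn),
    delta = delta, alpha = alpha, null_shift = null_shift), class = "otsu_detection")
}

#' @export
print.otsu_detection <- function(x, ...) {
  cat(sprintf(paste0("<otsu_detection> %s\n",
                     "  mu_n = %.1f degC (n = %d), mu_h = %.1f degC (n = %d)\n",
                     "  mu_d = %.1f degC (threshold %.1f), Welch t = %.2f, p = %.3g\n"),
              x$decision, x$mu_n, x$n_n, x$mu_h, x$n_h,
              x$mu_d, x$delta, x$t_stat, x$p_value))
  invisible(x)
}

#' Tabular summary of a detection result
#'
#' @param x an `otsu_detection` or `p2p_detection` object.
#' @param ... unused.
#' @return one-row data frame of the scalar fields.
#' @export
as.data.frame.otsu_detection <- function(x, ...) {
  data.frame(method = "otsu", mu_n = x$mu_n, mu_h = x$mu_h, mu_d = x$mu_d,
             t_stat = x$t_stat, p_value = x$p_value,
             n_h = x$n_h, n_n = x$n_n, decision = x$decision)
}

# Bounding box of a mask, as a list (r1, r2, c1, c2); NULL if empty.
mask_bbox <- function(mask) {
  if (!any(mask)) return(NULL)
  ij <- which(mask, arr.ind = TRUE)
  list(r1 = min(ij[, 1L]), r2 = max(ij[, 1L]),
       c1 = min(ij[, 2L]), c2 = max(ij[, 2L]))
}

#' Serialize a detection result to a JSON report
#'
#' Temperatures are printed to one decimal, the reporting precision of the
#' underlying measurements; the suspected region is summarized by its
#' bounding box (1-based, inclusive).
#'
#' @param x an `otsu_detection` or `p2p_detection`.
#' @param path destination `.json` file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  rep <- if (inherits(x, "otsu_detection")) {
    list(schema = "thermofoot-report/1", method = "otsu",
         mu_n = round(x$mu_n, 1L), mu_h = round(x$mu_h, 1L),
         mu_d = round(x$mu_d, 1L),
         t_stat = round(x$t_stat, 3L), p_value = x$p_value,
         delta = x$delta, alpha = x$alpha,
         decision = x$decision, region_bbox = mask_bbox(x$region_mask))
  } else if (inherits(x, "p2p_detection")) {
    list(schema = "thermofoot-report/1", method = "p2p",
         mean_diff = round(x$mean_diff, 1L),
         mean_diff_overlap = round(x$mean_diff_overlap, 2L),
         n_hyper = sum(x$hyper_mask), delta = x$delta,
         decision = x$decision, region_bbox = mask_bbox(x$hyper_mask_full),
         transform = x$transform[c("dx", "dy", "theta")],
         registration_converged = x$converged)
  } else stop("unsupported report object", call. = FALSE)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
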