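#' Segment the plantar feet from a cold background
#'
#' First-stage segmentation: with the acquisition protocol (feet in front of a
#' cold homogeneous backdrop) the gray-level histogram is bimodal, so a global
#' Otsu threshold separates the warm feet from the background. The raw binary
#' image is then cleaned by [smooth_mask()] (border clearing, diamond erosion,
#' hole filling).
#'
#' @param tg a [thermogram()].
#' @param L gray-level count for the histogram (default 256).
#' @param min_frac minimum fraction of the frame the feet must cover; a
#'   smoothed mask below this is a segmentation failure (e.g. an image with
#'   no feet, where thresholding splits sensor noise), surfaced as an error
#'   because the downstream statistics would be meaningless.
#' @return logical feet mask (same shape as `tg`), with the first-stage
#'   `otsu_split` attached as attribute `"split"`.
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 1))
#' feet <- segment_feet(ph$thermogram)
#' mean(feet[ph$feet_mask])   # recall of the true foot area
#' @export
segment_feet <- function(tg, L = 256L, min_frac = 0.005) {
  stopifnot(is_thermogram(tg))
  q <- quantize(tg, L)                     # errors on a constant image
  s <- otsu_threshold(gray_histogram(q))
  feet <- smooth_mask(binarize(q, s$t))
  if (sum(feet) < min_frac * length(feet)) {
    stop("segmentation produced an empty or implausibly small feet mask: no interior warm object found",
         call. = FALSE)
  }
  attr(feet, "split") <- s
  feet
}
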