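# 3x3 Sobel gradients via shifted matrices; border handled by edge
# replication so gradients at the frame are finite and unbiased.
sobel_gradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  pad[1L, ] <- pad[2L, ]; pad[nr + 2L, ] <- pad[nr + 1L, ]
  pad[, 1L] <- pad[, 2L]; pad[, nc + 2L] <- pad[, nc + 1L]
  at <- function(dr, dc) pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
  gx <- (at(-1L, 1L) + 2 * at(0L, 1L) + at(1L, 1L)) -
        (at(-1L, -1L) + 2 * at(0L, -1L) + at(1L, -1L))
  gy <- (at(1L, -1L) + 2 * at(1L, 0L) + at(1L, 1L)) -
        (at(-1L, -1L) + 2 * at(-1L, 0L) + at(-1L, 1L))
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

#' Sobel edge detection with automatic threshold
#'
#' Computes the gradient magnitude from the two 3x3 Sobel kernels, selects an
#' automatic threshold by running Otsu selection on the magnitude histogram
#' (within `mask` if given), marks pixels above it as edges, and dilates the
#' edge set by one pixel to buffer sub-pixel boundary uncertainty. A
#' constant region yields no edges.
#'
#' @param tg a [thermogram()] or numeric matrix.
#' @param mask optional logical matrix restricting both the histogram and the
#'   reported edges.
#' @param dilate dilation radius applied to the edge set (default 1).
#' @param L gray-level count for the magnitude histogram.
#' @return logical edge mask.
#' @examples
#' step <- thermogram(matrix(rep(c(30, 30, 35, 35), each = 4), 4))
#' which(sobel_edges(step), arr.ind = TRUE)
#' @export
sobel_edges <- function(tg, mask = NULL, dilate = 1L, L = 256L) {
  m <- if (is_thermogram(tg)) tg$temps else tg
  stopifnot(is.matrix(m), is.numeric(m))
  if (!is.null(mask)) check_mask(mask, dim(m))
  mag <- sobel_gradients(m)$magnitude
  sel <- if (is.null(mask)) rep(TRUE, length(mag)) else as.vector(mask)
  vals <- mag[sel]
  rng <- range(vals)
  if (rng[2L] - rng[1L] < 1e-12) {
    return(matrix(FALSE, nrow(m), ncol(m)))       # flat field: no edges
  }
  lev <- as.integer(round((mag - rng[1L]) / (rng[2L] - rng[1L]) * (L - 1L)))
  lev[lev < 0L] <- 0L; lev[lev > L - 1L] <- L - 1L
  h <- histogram_from_counts(tabulate(lev[sel] + 1L, nbins = L))
  thr <- otsu_threshold(h)$t
  edges <- matrix(lev > thr, nrow(m), ncol(m))
  if (!is.null(mask)) edges <- edges & mask
  if (dilate > 0L) edges <- dilate_mask(edges, se_diamond(as.integer(dilate)))
  edges
}

# Silhouette contour band: Sobel edges of the binary mask itself (the "foot
# contours"), dilated by `dilate`. Used by the point-to-point pipeline to
# excise the foot outline, where any residual misregistration meets the
# steepest temperature gradients.
silhouette_edges <- function(mask, dilate = 1L) {
  mag <- sobel_gradients(mask * 1)$magnitude
  edges <- mag > 1e-9
  if (dilate > 0L) edges <- dilate_mask(edges, se_diamond(as.integer(dilate)))
  edges
}
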