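#' Structuring elements for binary morphology
#'
#' A structuring element is the set of (row, col) offsets defining a
#' neighborhood; it must contain the origin and be point-symmetric.
#' `se_diamond(1)` is the 4-neighbor cross ("a single pixel distance from the
#' origin to the points of the diamond"), the element used by the foot
#' smoothing chain.
#'
#' @param offsets integer matrix with columns `dr`, `dc`.
#' @return object of class `structuring_element`.
#' @export
structuring_element <- function(offsets) {
  offsets <- matrix(as.integer(offsets), ncol = 2L,
                    dimnames = list(NULL, c("dr", "dc")))
  key <- function(m) paste(m[, 1L], m[, 2L])
  if (!any(offsets[, 1L] == 0L & offsets[, 2L] == 0L)) {
    stop("structuring element must contain the origin (0,0)", call. = FALSE)
  }
  if (!setequal(key(offsets), key(-offsets))) {
    stop("structuring element must be symmetric under negation", call. = FALSE)
  }
  structure(list(offsets = offsets), class = "structuring_element")
}

#' @rdname structuring_element
#' @param radius L1 radius of the diamond.
#' @export
se_diamond <- function(radius = 1L) {
  radius <- as.integer(radius)
  stopifnot(radius >= 0L)
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g <- g[abs(g$dr) + abs(g$dc) <= radius, , drop = FALSE]
  structuring_element(as.matrix(g))
}

# Shift a logical matrix by (dr, dc), padding with `fill`.
shift_mask <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (dr > nr - 1L || dr < 1L - nr || dc > nc - 1L || dc < 1L - nc) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

#' Binary erosion and dilation
#'
#' `erode_mask()`: a pixel survives iff every structuring-element offset from
#' it lands on a `TRUE` pixel; positions outside the image count as `FALSE`,
#' so foreground touching the border is eroded from outside as well.
#' `dilate_mask()` is the dual (union of shifted copies).
#'
#' @param mask logical matrix.
#' @param se a [structuring_element()] (default: diamond of radius 1).
#' @return logical matrix of the same shape.
#' @export
erode_mask <- function(mask, se = se_diamond(1L)) {
  check_mask(mask, dim(mask)); stopifnot(inherits(se, "structuring_element"))
  out <- mask
  for (k in seq_len(nrow(se$offsets))) {
    dr <- se$offsets[k, 1L]; dc <- se$offsets[k, 2L]
    if (dr == 0L && dc == 0L) next
    # pixel p survives only if mask[p + (dr,dc)] is TRUE
    out <- out & shift_mask(mask, -dr, -dc, fill = FALSE)
  }
  out
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, se = se_diamond(1L)) {
  check_mask(mask, dim(mask)); stopifnot(inherits(se, "structuring_element"))
  out <- mask
  for (k in seq_len(nrow(se$offsets))) {
    dr <- se$offsets[k, 1L]; dc <- se$offsets[k, 2L]
    if (dr == 0L && dc == 0L) next
    out <- out | shift_mask(mask, dr, dc, fill = FALSE)
  }
  out
}

# Geodesic flood fill: grow `seeds` inside `domain` until stable.
# connectivity 4 or 8.
flood_from <- function(domain, seeds, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  reach <- seeds & domain
  if (!any(reach)) return(reach)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  repeat {
    grown <- reach
    for (o in offs) grown <- grown | shift_mask(reach, o[1L], o[2L])
    grown <- grown & domain
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

border_mask <- function(nr, nc) {
  b <- matrix(FALSE, nr, nc)
  b[1L, ] <- TRUE; b[nr, ] <- TRUE; b[, 1L] <- TRUE; b[, nc] <- TRUE
  b
}

#' Remove components connected to the image border
#'
#' Every 8-connected foreground component containing at least one border pixel
#' is deleted; interior components are untouched. This suppresses warm objects
#' that protrude into the frame (hands, legs, radiators) which would otherwise
#' contaminate the foot segmentation.
#'
#' @param mask logical matrix.
#' @return logical matrix, subset of `mask`.
#' @export
clear_border <- function(mask) {
  check_mask(mask, dim(mask))
  mask & !flood_from(mask, border_mask(nrow(mask), ncol(mask)), 8L)
}

#' Fill interior holes of a binary mask
#'
#' Background pixels whose 4-connected component does not reach the image
#' border are turned to foreground. Idempotent and extensive.
#'
#' @param mask logical matrix.
#' @return logical matrix, superset of `mask`.
#' @export
fill_holes <- function(mask) {
  check_mask(mask, dim(mask))
  bg <- !mask
  outside <- flood_from(bg, border_mask(nrow(mask), ncol(mask)), 4L)
  mask | (bg & !outside)
}

#' Smooth a segmentation mask
#'
#' The post-segmentation cleanup chain, in fixed order: [clear_border()] (drop
#' anything touching the frame), [erode_mask()] with a radius-1 diamond
#' (shave ragged single-pixel fringes), then [fill_holes()] (close interior
#' gaps left by cooler skin patches).
#'
#' @param mask logical matrix (raw foreground from thresholding).
#' @param se structuring element for the erosion step.
#' @return smoothed logical matrix.
#' @export
smooth_mask <- function(mask, se = se_diamond(1L)) {
  fill_holes(erode_mask(clear_border(mask), se))
}

#' Label connected components
#'
#' Utility used for component counting in reports and tests.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, components numbered from 1 in
#'   raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8L) {
  check_mask(mask, dim(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[which(remaining)[1L]] <- TRUE
    comp <- flood_from(remaining, seed, connectivity)
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  lab
}

#' Export a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path destination `.png` file.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  check_mask(mask, dim(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a 0/255 PNG back into a logical mask
#'
#' @param path a `.png` written by [write_mask_png()].
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}
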