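#' Quantize a thermogram to discrete gray levels
#'
#' Otsu threshold selection operates on a discrete gray-level histogram, while
#' radiometric cameras report continuous temperatures. `quantize()` maps
#' temperatures linearly onto integer levels `0..L-1`:
#' \deqn{\mathrm{level} = \mathrm{round}\left(\frac{T - t_{min}}{t_{max}-t_{min}}(L-1)\right)}
#' with `t_min`/`t_max` the extrema of the quantized pixels. The map is
#' monotone, and [dequantize()] recovers every in-range temperature to within
#' one step, `(t_max - t_min)/(L-1)`.
#'
#' When `mask` is supplied the gray scale is stretched over the masked pixels
#' only (the usual second-stage setting, where only foot pixels matter);
#' temperatures outside the masked range are clamped to the scale ends.
#'
#' @param tg a [thermogram()].
#' @param L number of gray levels (default 256, the conventional 8-bit Otsu
#'   setting).
#' @param mask optional logical matrix selecting the pixels that define the
#'   temperature range.
#' @return An object of class `quantized_image`: list with integer matrix
#'   `levels`, level count `L`, and the anchor temperatures `t_min`, `t_max`.
#' @examples
#' tg <- thermogram(matrix(c(20, 25, 30, 30), 2))
#' quantize(tg, 256)$levels
#' @export
quantize <- function(tg, L = 256L, mask = NULL) {
  stopifnot(is_thermogram(tg))
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("`L` must be an integer >= 2", call. = FALSE)
  x <- tg$temps
  if (!is.null(mask)) {
    check_mask(mask, dim(x))
    if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
    rng <- range(x[mask])
  } else {
    rng <- range(x)
  }
  if (rng[1L] == rng[2L]) {
    stop("degenerate input: all (masked) temperatures are identical; gray-level histogram undefined",
         call. = FALSE)
  }
  lev <- round((x - rng[1L]) / (rng[2L] - rng[1L]) * (L - 1))
  lev[lev < 0] <- 0
  lev[lev > L - 1L] <- L - 1L
  storage.mode(lev) <- "integer"
  structure(list(levels = lev, L = L, t_min = rng[1L], t_max = rng[2L]),
            class = "quantized_image")
}

#' Map gray levels back to temperatures
#'
#' @param q a `quantized_image` from [quantize()].
#' @return numeric matrix of temperatures (degrees C).
#' @export
dequantize <- function(q) {
  stopifnot(inherits(q, "quantized_image"))
  q$t_min + q$levels / (q$L - 1) * (q$t_max - q$t_min)
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image> %d x %d px, L = %d over [%.2f, %.2f] degC\n",
              nrow(x$levels), ncol(x$levels), x$L, x$t_min, x$t_max))
  invisible(x)
}

# Shared validation for logical mask arguments.
check_mask <- function(mask, dims, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  }
  if (!identical(dim(mask), as.integer(dims))) {
    stop(sprintf("`%s` dimensions (%d x %d) do not match the image (%d x %d)",
                 arg, nrow(mask), ncol(mask), dims[1L], dims[2L]), call. = FALSE)
  }
  invisible(TRUE)
}
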