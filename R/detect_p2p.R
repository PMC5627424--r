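#' Split a thermogram into a contralateral foot pair
#'
#' Cuts the image into two equal halves down the vertical midline (for an odd
#' width the middle column is dropped) and mirrors the right half about its
#' vertical axis, so that with well-centred feet the left foot and the
#' flipped right foot occupy corresponding pixels. The left foot is the
#' reference.
#'
#' @param tg a [thermogram()].
#' @param feet logical feet mask, e.g. from [segment_feet()].
#' @return Object of class `foot_pair`: list with thermogram-shaped matrices
#'   `left`, `right_flipped` (temperatures) and masks `left_mask`,
#'   `right_mask` (the right-half mask, mirrored), plus `full_width` and
#'   `right_cols` (the original column indices of the right half, in flipped
#'   order) for mapping results back to the full frame.
#' @export
split_and_flip <- function(tg, feet) {
  stopifnot(is_thermogram(tg))
  check_mask(feet, dim(tg$temps), "feet")
  W <- ncol(tg$temps)
  half <- W %/% 2L
  left_cols <- seq_len(half)
  right_cols <- (W - half + 1L):W
  if (!any(feet[, left_cols]) || !any(feet[, right_cols])) {
    stop("cannot form a contralateral pair: feet pixels missing in one image half",
         call. = FALSE)
  }
  flip <- rev(seq_along(right_cols))
  structure(list(
    left = tg$temps[, left_cols, drop = FALSE],
    right_flipped = tg$temps[, right_cols[flip], drop = FALSE],
    left_mask = feet[, left_cols, drop = FALSE],
    right_mask = feet[, right_cols[flip], drop = FALSE],
    full_width = W, right_cols = right_cols[flip]), class = "foot_pair")
}

#' @export
print.foot_pair <- function(x, ...) {
  cat(sprintf("<foot_pair> halves %d x %d px (full width %d), feet px L/R: %d/%d\n",
              nrow(x$left), ncol(x$left), x$full_width,
              sum(x$left_mask), sum(x$right_mask)))
  invisible(x)
}

#' Hyperthermia detection by contralateral point-to-point difference
#'
#' Implements the asymmetry criterion: a skin region more than `delta`
#' (2.2 degrees C) warmer than the mirror-corresponding region on the other
#' foot is hyperthermic. Pipeline: [split_and_flip()]; [register()] the
#' flipped right half onto the left (intensity-based rigid registration);
#' absolute pixelwise difference over the overlap of both foot masks;
#' removal of the Sobel contour band of either foot (residual misregistration
#' meets the steepest gradients exactly there and would otherwise read as
#' false hyperthermia); thresholding at `delta`.
#'
#' The reported `mean_diff` averages the absolute difference over the
#' detected pixels and is 0 when nothing exceeds the threshold;
#' `mean_diff_overlap` (the mean over the whole foot overlap) is also
#' reported.
#'
#' @param tg a [thermogram()].
#' @param feet logical feet mask, e.g. from [segment_feet()].
#' @param delta hyperthermia threshold in degrees C (default 2.2).
#' @param edge_dilate dilation of the excluded contour band, pixels.
#' @param reference `"left"` (default) or `"right"`: which foot serves as the
#'   fixed reference frame.
#' @param ... passed to [register()].
#' @return Object of class `p2p_detection`: `diff_map` (signed left minus
#'   registered right, degrees C, `NA` outside the valid overlap),
#'   `hyper_mask` (half-frame), `hyper_mask_full` (both feet, full frame),
#'   `edge_mask`, `valid_mask`, `mean_diff`, `mean_diff_overlap`,
#'   `decision`, `transform`, `converged`, `delta`.
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 11,
#'   hotspot = hotspot_spec(delta_T = 3, foot = "right")))
#' res <- detect_p2p(ph$thermogram, segment_feet(ph$thermogram))
#' res$mean_diff
#' @export
detect_p2p <- function(tg, feet, delta = 2.2, edge_dilate = 1L,
                       reference = c("left", "right"), ...) {
  reference <- match.arg(reference)
  stopifnot(delta > 0)
  fp <- split_and_flip(tg, feet)
  if (reference == "left") {
    fixed <- fp$left; fixed_mask <- fp$left_mask
    moving <- fp$right_flipped; moving_mask <- fp$right_mask
  } else {
    fixed <- fp$right_flipped; fixed_mask <- fp$right_mask
    moving <- fp$left; moving_mask <- fp$left_mask
  }
  reg <- register(moving, fixed, moving_mask, fixed_mask, ...)
  diff_map <- fixed - reg$registered                 # NA where moving invalid
  valid <- fixed_mask & reg$registered_mask & !is.na(diff_map)
  edge_mask <- silhouette_edges(fixed_mask, edge_dilate) |
    silhouette_edges(reg$registered_mask, edge_dilate)
  eligible <- valid & !edge_mask
  hyper <- eligible & !is.na(diff_map) & abs(diff_map) > delta
  mean_diff <- if (any(hyper)) mean(abs(diff_map)[hyper]) else 0
  mean_diff_overlap <- if (any(eligible)) mean(abs(diff_map)[eligible]) else NA_real_
  diff_map[!valid] <- NA_real_

  # Map detections back to the full frame: the half-frame pixel itself plus
  # the mirror-corresponding source pixel on the other foot (the asymmetry is
  # direction-agnostic, so both sites are displayed).
  full <- matrix(FALSE, nrow(tg$temps), ncol(tg$temps))
  if (any(hyper)) {
    idx <- which(hyper)
    nr <- nrow(fixed)
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    fixed_cols <- if (reference == "left") seq_len(ncol(fp$left)) else fp$right_cols
    full[cbind(rr, fixed_cols[cc])] <- TRUE
    centre <- c((nr + 1) / 2, (ncol(fixed) + 1) / 2)
    src <- map_coords(reg$transform, rr, cc, centre)
    sr <- round(src$r); sc <- round(src$c)
    ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= ncol(fixed)
    moving_cols <- if (reference == "left") fp$right_cols else seq_len(ncol(fp$left))
    full[cbind(sr[ok], moving_cols[sc[ok]])] <- TRUE
  }

  structure(list(
    diff_map = diff_map, hyper_mask = hyper, hyper_mask_full = full,
    edge_mask = edge_mask, valid_mask = valid,
    mean_diff = mean_diff, mean_diff_overlap = mean_diff_overlap,
    decision = if (any(hyper)) "ulcer-suspected" else "no-ulcer",
    transform = reg$transform, converged = reg$converged,
    reference = reference, delta = delta, pair = fp), class = "p2p_detection")
}

#' @export
print.p2p_detection <- function(x, ...) {
  cat(sprintf(paste0("<p2p_detection> %s (reference: %s foot)\n",
                     "  hyper pixels: %d, mean difference over them: %.1f degC ",
                     "(threshold %.1f)\n",
                     "  mean |difference| over foot overlap: %.2f degC\n"),
              x$decision, x$reference, sum(x$hyper_mask), x$mean_diff,
              x$delta, x$mean_diff_overlap))
  print(x$transform)
  invisible(x)
}

#' @rdname as.data.frame.otsu_detection
#' @export
as.data.frame.p2p_detection <- function(x, ...) {
  data.frame(method = "p2p", mean_diff = x$mean_diff,
             mean_diff_overlap = x$mean_diff_overlap,
             n_hyper = sum(x$hyper_mask),
             dx = x$transform$dx, dy = x$transform$dy,
             theta_deg = x$transform$theta * 180 / pi,
             converged = x$converged, decision = x$decision)
}
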