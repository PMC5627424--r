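#' Rigid transforms for intensity-based registration
#'
#' A rigid transform maps a pixel position `p = (col, row)` in the fixed frame
#' to the source position in the moving image:
#' `T(p) = R(theta) (p - c) + c + (dx, dy)`, with `c` the image centre,
#' `theta` a counter-clockwise rotation in radians and `(dx, dy)` a
#' translation in pixels (x = column, y = row). Registration searches for the
#' transform whose resampled moving image best matches the fixed image.
#'
#' @param dx,dy translation in pixels.
#' @param theta rotation in radians (|theta| <= pi/4).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, theta = 0) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(theta),
            abs(theta) <= pi / 4)
  structure(list(dx = dx, dy = dy, theta = theta), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx = %.3f px, dy = %.3f px, theta = %.3f deg\n",
              x$dx, x$dy, x$theta * 180 / pi))
  invisible(x)
}

#' Invert a rigid transform
#'
#' @param tf a [rigid_transform()].
#' @return the inverse transform.
#' @export
invert_rigid <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  ct <- cos(-tf$theta); st <- sin(-tf$theta)
  # inverse: p -> R(-theta) (p - c - d) + c
  rigid_transform(dx = -(ct * tf$dx - st * tf$dy),
                  dy = -(st * tf$dx + ct * tf$dy),
                  theta = -tf$theta)
}

# Map fixed-frame coordinates (row r, col c vectors) through tf to source
# coordinates in the moving frame. centre = c(row, col).
map_coords <- function(tf, r, c, centre) {
  ct <- cos(tf$theta); st <- sin(tf$theta)
  x <- c - centre[2L]; y <- r - centre[1L]
  list(r = st * x + ct * y + centre[1L] + tf$dy,
       c = ct * x - st * y + centre[2L] + tf$dx)
}

# Bilinear sampling of matrix `img` at fractional (r, c); NA outside.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- img[cbind(r0, c0)];         v01 <- img[cbind(r0, c0 + 1L)]
  v10 <- img[cbind(r0 + 1L, c0)];    v11 <- img[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
    fr * ((1 - fc) * v10 + fc * v11)
  out
}

#' Resample an image through a rigid transform
#'
#' Bilinear resampling of `img` onto its own grid through `tf`
#' (fixed-frame pixel `p` receives `img(T(p))`). Pixels whose source falls
#' outside the image are `NA`.
#'
#' @param img numeric matrix or [thermogram()].
#' @param tf a [rigid_transform()].
#' @return numeric matrix with `NA` at invalid pixels.
#' @export
apply_transform <- function(img, tf) {
  if (is_thermogram(img)) img <- img$temps
  stopifnot(is.matrix(img), inherits(tf, "rigid_transform"))
  nr <- nrow(img); nc <- ncol(img)
  centre <- c((nr + 1) / 2, (nc + 1) / 2)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  src <- map_coords(tf, g$r, g$c, centre)
  matrix(bilinear_sample(img, src$r, src$c), nr, nc)
}

# MSE objective for registration, evaluated over the (dilated) fixed foot
# mask using the actual sampled temperatures. Samples that land on the
# moving image's cold background pay the full squared difference, so
# transforms that slide the foot off its counterpart cannot look good by
# shrinking the scored overlap; only samples falling outside the image frame
# are dropped, with a floor on the remaining coverage.
reg_objective <- function(par, moving, fixed_vals, rr, cc, centre) {
  tf <- list(dx = par[1L], dy = par[2L], theta = par[3L] * pi / 180)
  src <- map_coords(tf, rr, cc, centre)
  v <- bilinear_sample(moving, src$r, src$c)
  ok <- !is.na(v)
  if (sum(ok) < 0.5 * length(rr)) return(Inf)
  mean((fixed_vals[ok] - v[ok])^2)
}

#' Intensity-based rigid registration
#'
#' Aligns `moving` onto `fixed` by minimizing the mean squared temperature
#' difference over the fixed foot mask (plus a 2-px collar); samples landing
#' on the moving image's cold background pay the full squared difference, so
#' the optimum cannot cheat by shrinking the scored overlap. The optimizer is a coarse
#' grid search over translations (within `trans_range` pixels) and rotations
#' (within `angle_range` degrees), followed by Nelder-Mead refinement of the
#' best cell. This plain search is robust for the intended use - two
#' mirror-matched plantar feet that are already roughly aligned - and needs
#' no derivatives.
#'
#' @param moving,fixed [thermogram()]s (or numeric matrices) of equal shape.
#' @param moving_mask,fixed_mask logical masks of the objects to align.
#' @param trans_range,trans_step coarse search extent and step for `dx`, `dy`
#'   (pixels).
#' @param angle_range,angle_step coarse search extent and step for the
#'   rotation (degrees).
#' @param max_eval_px at most this many fixed-mask pixels enter the coarse
#'   objective (subsampled deterministically); refinement always uses all.
#' @return list with `transform` (a [rigid_transform()]), `registered`
#'   (resampled moving image, `NA` outside), `registered_mask` (logical),
#'   `mse` (final objective), and `converged` (`FALSE` when no transform
#'   improved on the identity, in which case the identity is returned).
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 3))
#' fp <- split_and_flip(ph$thermogram, ph$feet_mask)
#' reg <- register(fp$right_flipped, fp$left, fp$right_mask, fp$left_mask)
#' reg$transform
#' @export
register <- function(moving, fixed, moving_mask, fixed_mask,
                     trans_range = 8, trans_step = 2,
                     angle_range = 10, angle_step = 2,
                     max_eval_px = 2000L) {
  if (is_thermogram(moving)) moving <- moving$temps
  if (is_thermogram(fixed)) fixed <- fixed$temps
  stopifnot(is.matrix(moving), is.matrix(fixed),
            identical(dim(moving), dim(fixed)))
  check_mask(moving_mask, dim(moving), "moving_mask")
  check_mask(fixed_mask, dim(fixed), "fixed_mask")
  if (!any(moving_mask) || !any(fixed_mask)) {
    stop("degenerate input: registration masks must be non-empty", call. = FALSE)
  }
  nr <- nrow(fixed); nc <- ncol(fixed)
  centre <- c((nr + 1) / 2, (nc + 1) / 2)
  # score over the fixed mask plus a 2-px collar, so the foot outline
  # contributes alignment signal from both sides
  eval_mask <- dilate_mask(fixed_mask, se_diamond(2L))
  idx <- which(eval_mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  sub <- if (length(idx) > max_eval_px) {
    round(seq(1L, length(idx), length.out = max_eval_px))
  } else seq_along(idx)
  fixed_vals <- fixed[idx]

  obj_coarse <- function(par) reg_objective(par, moving,
                                            fixed_vals[sub], rr[sub], cc[sub], centre)
  obj_full <- function(par) reg_objective(par, moving,
                                          fixed_vals, rr, cc, centre)

  ts <- seq(-trans_range, trans_range, by = trans_step)
  as <- seq(-angle_range, angle_range, by = angle_step)
  best <- c(0, 0, 0); best_val <- obj_coarse(best)
  for (a in as) for (dx in ts) for (dy in ts) {
    v <- obj_coarse(c(dx, dy, a))
    if (v < best_val) { best_val <- v; best <- c(dx, dy, a) }
  }
  opt <- stats::optim(best, obj_full, method = "Nelder-Mead",
                      control = list(reltol = 1e-9, maxit = 400))
  id_val <- obj_full(c(0, 0, 0))
  converged <- is.finite(opt$value) && opt$value <= id_val
  par <- if (converged) opt$par else c(0, 0, 0)
  if (!converged) {
    warning("registration failed to improve on the identity transform; returning identity")
  }
  tf <- rigid_transform(par[1L], par[2L], par[3L] * pi / 180)
  registered <- apply_transform(moving, tf)
  reg_mask_num <- apply_transform(moving_mask * 1, tf)
  registered_mask <- !is.na(reg_mask_num) & reg_mask_num >= 0.5
  list(transform = tf, registered = registered,
       registered_mask = registered_mask,
       mse = if (converged) opt$value else id_val, converged = converged)
}
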