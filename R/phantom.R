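#' Specify a synthetic plantar thermogram
#'
#' The phantom generator stands in for the acquisition hardware: a 160 x 120
#' temperature grid showing two mirror-placed plantar feet (an elliptical sole
#' fused with five toe disks) on a cold homogeneous background, optionally
#' with a heated-object hotspot of a standard shape, plus Gaussian sensor
#' noise at the 0.1 degree C sensitivity typical of mobile thermal cameras.
#' Every geometric element is returned as a ground-truth mask so each
#' pipeline stage can be scored.
#'
#' Defaults mirror the acquisition protocol the package targets: 160 x 120
#' resolution, background around 18 degrees C (a cold wet towel), plantar
#' skin between 33 and 37 degrees C, noise sigma 0.1 degrees C, and a pixel
#' pitch of 0.25 cm/px so that the standard heated-object sizes (0.5-3.5 cm)
#' span 2-14 px.
#'
#' @param height,width grid size in pixels.
#' @param pixel_pitch_cm physical pixel size, cm/px.
#' @param background_temp background temperature, degrees C.
#' @param foot_temp mean plantar skin temperature, degrees C (must exceed the
#'   background).
#' @param asymmetry baseline left/right offset: the left foot sits at
#'   `foot_temp + asymmetry/2`, the right at `foot_temp - asymmetry/2`.
#' @param hotspot `NULL` (healthy) or a [hotspot_spec()].
#' @param noise_sigma sensor noise standard deviation, degrees C.
#' @param seed integer RNG seed; the phantom is deterministic given the seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 120L, width = 160L, pixel_pitch_cm = 0.25,
                         background_temp = 18, foot_temp = 35, asymmetry = 0,
                         hotspot = NULL, noise_sigma = 0.1, seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 40L, width >= 40L, pixel_pitch_cm > 0,
            noise_sigma >= 0, is.finite(asymmetry))
  if (background_temp >= foot_temp) {
    stop("background_temp must be colder than foot_temp", call. = FALSE)
  }
  if (!is.null(hotspot)) {
    stopifnot(inherits(hotspot, "hotspot_spec"))
    if (hotspot$delta_T < 0) stop("hotspot delta_T must be >= 0", call. = FALSE)
  }
  structure(list(height = height, width = width,
                 pixel_pitch_cm = pixel_pitch_cm,
                 background_temp = background_temp, foot_temp = foot_temp,
                 asymmetry = asymmetry, hotspot = hotspot,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param shape `"disk"`, `"rectangle"` or `"half-ring"`.
#' @param size_cm characteristic size: disk diameter, rectangle length, or
#'   half-ring outer diameter, in cm.
#' @param delta_T temperature elevation above the foot baseline, degrees C.
#' @param foot which foot carries the hotspot.
#' @param center optional `(row, col)` of the hotspot centre; default is the
#'   forefoot of the chosen foot.
#' @export
hotspot_spec <- function(shape = c("disk", "rectangle", "half-ring"),
                         size_cm = 1.5, delta_T = 2.5,
                         foot = c("right", "left"), center = NULL) {
  shape <- match.arg(shape)
  foot <- match.arg(foot)
  stopifnot(size_cm > 0, delta_T >= 0)
  if (!is.null(center)) stopifnot(length(center) == 2L, all(is.finite(center)))
  structure(list(shape = shape, size_cm = size_cm, delta_T = delta_T,
                 foot = foot, center = center), class = "hotspot_spec")
}

#' Rasterize a standard hotspot shape
#'
#' Shapes emulate the heated objects used to simulate ulcers: coins (disks),
#' rectangles with a fixed 2:1 aspect ratio, and a half ring (an annulus of
#' outer diameter `size_cm` and inner diameter half that, with the lower half
#' removed). Rasterization is by centre-of-pixel inclusion.
#'
#' @param shape `"disk"`, `"rectangle"` or `"half-ring"`.
#' @param size_cm characteristic dimension in cm (see [hotspot_spec()]).
#' @param center `(row, col)` centre in pixels.
#' @param pixel_pitch_cm cm per pixel.
#' @param dim `(height, width)` of the target grid.
#' @return logical mask of shape `dim`.
#' @export
shape_mask <- function(shape, size_cm, center, pixel_pitch_cm, dim) {
  stopifnot(size_cm > 0, pixel_pitch_cm > 0, length(dim) == 2L)
  shape <- match.arg(shape, c("disk", "rectangle", "half-ring"))
  nr <- as.integer(dim[1L]); nc <- as.integer(dim[2L])
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- r - center[1L]; dc <- c - center[2L]
  px <- size_cm / pixel_pitch_cm
  switch(shape,
    "disk" = (dr^2 + dc^2) <= (px / 2)^2,
    "rectangle" = {
      # length along columns, 2:1 aspect; half-open box of len x len/2 px
      half_l <- px / 2; half_w <- px / 4
      dc >= -half_l & dc < half_l & dr >= -half_w & dr < half_w
    },
    "half-ring" = {
      d2 <- dr^2 + dc^2
      d2 <= (px / 2)^2 & d2 > (px / 4)^2 & dr <= 0   # keep the upper half
    })
}

# Soft indicator of a silhouette: Gaussian-blurred 1-px-dilated mask, clamped
# to 1 on the mask itself. The skirt decays outside only, so region means
# over the true mask are exact while the transition stays smooth enough to
# exercise edge detection and sub-pixel registration.
soft_indicator <- function(mask, sigma = 1, dilate = 1L) {
  m <- mask * 1
  if (dilate > 0L) m <- dilate_mask(mask, se_diamond(dilate)) * 1
  if (sigma > 0) m <- gaussian_blur(m, sigma)
  pmax(m, mask * 1)
}

# Soft indicator with a fixed radial profile: value profile[k] on the ring at
# L1 distance k outside the mask, 1 inside. Models the point-spread skirt of
# a warm body against a cold backdrop with a transition band of known width,
# so the silhouette boundary is soft for edge detection and sub-pixel
# registration while interior temperatures stay exactly at their nominal
# values.
ringed_indicator <- function(mask, profile = c(0.7, 0.2, 0.03)) {
  S <- mask * 1
  grown <- mask
  for (k in seq_along(profile)) {
    next_grown <- dilate_mask(grown, se_diamond(1L))
    S[next_grown & !grown] <- profile[k]
    grown <- next_grown
  }
  S
}

# Separable Gaussian blur with edge-replicated borders.
gaussian_blur <- function(m, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(x, along_rows) {
    out <- x * k[rad + 1L]
    for (d in seq_len(rad)) {
      if (along_rows) {
        up <- rbind(x[rep(1L, d), , drop = FALSE], x[seq_len(nrow(x) - d), , drop = FALSE])
        dn <- rbind(x[-seq_len(d), , drop = FALSE], x[rep(nrow(x), d), , drop = FALSE])
      } else {
        up <- cbind(x[, rep(1L, d), drop = FALSE], x[, seq_len(ncol(x) - d), drop = FALSE])
        dn <- cbind(x[, -seq_len(d), drop = FALSE], x[, rep(ncol(x), d), drop = FALSE])
      }
      out <- out + k[rad + 1L + d] * (up + dn)
    }
    out
  }
  blur1(blur1(m, TRUE), FALSE)
}

# Foot silhouette (sole ellipse + five overlapping toe disks) centred at
# (r0, c0); scaled by `scale` relative to the default 120-row frame. Toes sit
# on the upper boundary arc of the sole, dipping into it so the union is a
# single connected component that survives a radius-1 erosion.
foot_silhouette <- function(nr, nc, r0, c0, scale = 1) {
  a <- 30 * scale; b <- 11 * scale          # sole semi-axes (rows, cols)
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  m <- ((r - r0) / a)^2 + ((c - c0) / b)^2 <= 1
  toe_r <- c(2.6, 3.2, 3.6, 3.4, 3.0) * scale
  toe_x <- c(-8.2, -4.4, 0, 4.4, 8.2) * scale
  for (k in 1:5) {
    frac <- min(abs(toe_x[k]) / b, 0.95)
    y_edge <- r0 - a * sqrt(1 - frac^2)     # sole boundary row at this column
    toe_y <- y_edge - 0.4 * toe_r[k]
    m <- m | ((r - toe_y)^2 + (c - (c0 + toe_x[k]))^2 <= toe_r[k]^2)
  }
  # close single-pixel concavities between the toes; real silhouettes have no
  # notches sharper than the sensor resolution
  erode_mask(dilate_mask(m, se_diamond(1L)), se_diamond(1L))
}

#' Generate a synthetic plantar thermogram with ground truth
#'
#' Builds the temperature field `background + (foot - background) * S_feet +
#' delta_T * S_hot`, where `S` are soft silhouette indicators (exactly 1 on
#' the true masks, decaying smoothly just outside them), then adds Gaussian
#' sensor noise. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `phantom`: list with `thermogram`, logical masks
#'   `feet_mask`, `left_mask`, `right_mask`, `hotspot_mask`, and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(foot_temp = 36.9, seed = 2,
#'   hotspot = hotspot_spec("disk", 1.5, delta_T = 2.5)))
#' mean(ph$thermogram$temps[ph$hotspot_mask])
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$height; nc <- spec$width
  scale <- min(nr / 120, nc / 160)
  r0 <- nr * 0.58
  left <- foot_silhouette(nr, nc, r0, nc * 0.30, scale)
  right <- left[, rev(seq_len(nc))]         # exact mirror about the midline
  feet <- left | right

  hot <- matrix(FALSE, nr, nc)
  if (!is.null(spec$hotspot) && spec$hotspot$delta_T > 0) {
    hs <- spec$hotspot
    foot_mask <- if (hs$foot == "left") left else right
    centre <- hs$center
    if (is.null(centre)) {
      c0 <- if (hs$foot == "left") nc * 0.30 else nc + 1 - nc * 0.30
      centre <- round(c(r0 - 16 * scale, c0))   # forefoot, on the pixel grid
    }
    hot <- shape_mask(hs$shape, hs$size_cm, centre, spec$pixel_pitch_cm, c(nr, nc))
    if (!any(hot)) stop("hotspot rasterized to zero pixels", call. = FALSE)
    if (any(hot & !foot_mask)) {
      stop("hotspot does not lie inside the chosen foot", call. = FALSE)
    }
  }

  t_left <- spec$foot_temp + spec$asymmetry / 2
  t_right <- spec$foot_temp - spec$asymmetry / 2
  field <- spec$background_temp +
    (t_left - spec$background_temp) * ringed_indicator(left) +
    (t_right - spec$background_temp) * ringed_indicator(right)
  if (any(hot)) {
    field <- field + spec$hotspot$delta_T *
      soft_indicator(hot, sigma = 0.5, dilate = 0L)
  }
  if (spec$noise_sigma > 0) {
    noise <- with_phantom_seed(spec$seed,
      matrix(stats::rnorm(nr * nc, sd = spec$noise_sigma), nr, nc))
    field <- field + noise
  }
  structure(list(
    thermogram = thermogram(field, pixel_pitch_cm = spec$pixel_pitch_cm,
                            source_id = sprintf("phantom-seed%d", spec$seed)),
    feet_mask = feet, left_mask = left, right_mask = right,
    hotspot_mask = hot, spec = spec), class = "phantom")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_phantom_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, feet %d px, hotspot %d px (seed %d)\n",
              x$spec$height, x$spec$width, sum(x$feet_mask),
              sum(x$hotspot_mask), x$spec$seed))
  invisible(x)
}

# The eight-image synthetic test set: one healthy image plus seven hotspot
# variants covering the standard heated-object shapes. Baseline foot
# temperatures and elevations follow the published reference measurements.
fixture_specs <- function(seed = 20170L) {
  ref <- reference_measurements()
  shapes <- list(
    NULL,
    hotspot_spec("disk", 1.5, foot = "right"),
    hotspot_spec("disk", 0.5, foot = "left"),
    hotspot_spec("rectangle", 2.0, foot = "right"),
    hotspot_spec("half-ring", 2.0, foot = "left"),
    hotspot_spec("rectangle", 3.5, foot = "right"),
    hotspot_spec("disk", 2.5, foot = "left"),
    hotspot_spec("disk", 1.0, foot = "right"))
  lapply(1:8, function(i) {
    hs <- shapes[[i]]
    if (!is.null(hs)) hs$delta_T <- ref$mu_d_printed[i]
    phantom_spec(foot_temp = ref$mu_n[i], hotspot = hs,
                 seed = seed + i)
  })
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  if (!is.null(out$hotspot)) out$hotspot <- unclass(out$hotspot)
  out
}

list_to_spec <- function(lst) {
  hs <- lst$hotspot
  if (!is.null(hs)) {
    hs <- hotspot_spec(hs$shape, hs$size_cm, hs$delta_T, hs$foot,
                       center = unlist(hs$center))
  }
  phantom_spec(lst$height, lst$width, lst$pixel_pitch_cm, lst$background_temp,
               lst$foot_temp, lst$asymmetry, hs, lst$noise_sigma, lst$seed)
}

#' Write the standard eight-image synthetic test suite
#'
#' Generates one healthy phantom and seven hotspot phantoms (covering the
#' standard heated-object shapes: 0.5/1/1.5/2.5 cm disks, 2/3.5 cm
#' rectangles, a half ring), writes each as a matrix CSV plus ground-truth
#' mask PNGs, and a JSON manifest from which every [phantom_spec()]
#' round-trips exactly.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed base seed; image `i` uses `seed + i`.
#' @return character vector of the files written, invisibly; the manifest is
#'   `manifest.json`.
#' @export
make_fixture_suite <- function(out_dir, seed = 20170L) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  }
  specs <- fixture_specs(seed)
  files <- character(0)
  manifest <- list()
  for (i in seq_along(specs)) {
    ph <- make_phantom(specs[[i]])
    stem <- sprintf("image%02d", i)
    csv <- file.path(out_dir, paste0(stem, ".csv"))
    write_thermogram(ph$thermogram, csv, "matrix-csv")
    masks <- c(feet = "feet", hotspot = "hotspot")
    mask_files <- character(0)
    for (m in names(masks)) {
      p <- file.path(out_dir, sprintf("%s_%s.png", stem, m))
      write_mask_png(if (m == "feet") ph$feet_mask else ph$hotspot_mask, p)
      mask_files[m] <- p
    }
    manifest[[stem]] <- list(csv = basename(csv),
                             masks = as.list(basename(mask_files)),
                             spec = spec_to_list(specs[[i]]))
    files <- c(files, csv, mask_files)
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mpath))
}

#' Read a fixture-suite manifest back into phantom specs
#'
#' @param path a `manifest.json` written by [make_fixture_suite()].
#' @return named list of [phantom_spec()] objects.
#' @export
read_fixture_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(man, function(entry) list_to_spec(entry$spec))
}
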