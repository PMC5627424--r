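#' Radiometric thermogram
#'
#' A thermogram is a 2-D grid of per-pixel temperatures in degrees Celsius,
#' stored row-major with the origin at the top-left corner (row 1 = top).
#' It is the common currency of every operation in the package: segmentation,
#' hyperthermia detection and the phantom generator all consume and produce
#' thermograms.
#'
#' Temperatures must be finite and lie inside the scene range of the class of
#' mobile long-wave infrared sensors the package targets, -20 to 120 degrees C.
#' Values outside that range indicate a corrupted or mis-scaled input and are
#' rejected at construction.
#'
#' @param temps numeric matrix of temperatures (degrees C), at least 2 x 2.
#' @param pixel_pitch_cm optional physical size of one pixel (cm/pixel); needed
#'   only when hotspot shapes are specified in centimetres.
#' @param source_id optional free-text provenance label.
#' @return An object of class `thermogram`: a list with elements `temps`,
#'   `pixel_pitch_cm` and `source_id`. `height`/`width` are available via
#'   [dim.thermogram()].
#' @examples
#' tg <- thermogram(matrix(c(20, 21, 33, 34), 2, byrow = TRUE))
#' dim(tg)
#' @export
thermogram <- function(temps, pixel_pitch_cm = NULL, source_id = NULL) {
  if (is.data.frame(temps)) temps <- as.matrix(temps)
  if (!is.matrix(temps) || !is.numeric(temps)) {
    stop("`temps` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(temps) <- "double"
  dimnames(temps) <- NULL
  if (nrow(temps) < 2L || ncol(temps) < 2L) {
    stop("a thermogram must be at least 2 x 2 pixels", call. = FALSE)
  }
  if (!all(is.finite(temps))) {
    bad <- which(!is.finite(temps), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite temperature at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  rng <- range(temps)
  if (rng[1L] < SCENE_RANGE_C[1L] || rng[2L] > SCENE_RANGE_C[2L]) {
    stop(sprintf(
      "temperatures [%.2f, %.2f] fall outside the scene range [%g, %g] degrees C",
      rng[1L], rng[2L], SCENE_RANGE_C[1L], SCENE_RANGE_C[2L]), call. = FALSE)
  }
  if (!is.null(pixel_pitch_cm)) {
    stopifnot(is.numeric(pixel_pitch_cm), length(pixel_pitch_cm) == 1L,
              is.finite(pixel_pitch_cm), pixel_pitch_cm > 0)
    pixel_pitch_cm <- as.numeric(pixel_pitch_cm)
  }
  structure(
    list(temps = temps, pixel_pitch_cm = pixel_pitch_cm,
         source_id = if (is.null(source_id)) NULL else as.character(source_id)[1L]),
    class = "thermogram")
}

# Scene temperature limits (degrees C) of the target sensor class.
SCENE_RANGE_C <- c(-20, 120)

#' @export
dim.thermogram <- function(x) dim(x$temps)

#' @export
print.thermogram <- function(x, ...) {
  d <- dim(x$temps)
  cat(sprintf("<thermogram> %d x %d px, %.1f..%.1f degC", d[1L], d[2L],
              min(x$temps), max(x$temps)))
  if (!is.null(x$pixel_pitch_cm)) cat(sprintf(", %.3g cm/px", x$pixel_pitch_cm))
  if (!is.null(x$source_id)) cat(", ", x$source_id, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.thermogram <- function(x, ...) x$temps

is_thermogram <- function(x) inherits(x, "thermogram")

#' Coerce a thermogram to a long data frame
#'
#' One record per pixel with 1-based `row`/`col` indices and the temperature,
#' convenient for plotting or tabular summaries.
#'
#' @param x a [thermogram()].
#' @param ... unused.
#' @return data frame with columns `row`, `col`, `temp_c`.
#' @export
as.data.frame.thermogram <- function(x, ...) {
  d <- dim(x$temps)
  data.frame(row = rep.int(seq_len(d[1L]), d[2L]),
             col = rep(seq_len(d[2L]), each = d[1L]),
             temp_c = as.vector(x$temps))
}

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".json")

guess_format <- function(path) {
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) "scaled-image" else "matrix-csv"
}

#' Read a thermogram from disk
#'
#' Two plain interchange formats are supported:
#' \describe{
#'   \item{`matrix-csv`}{an RFC-4180 numeric matrix, one CSV row per pixel row,
#'     values in degrees C, `.` decimal separator, no header. This is the
#'     canonical lossless format.}
#'   \item{`scaled-image`}{a 16-bit grayscale TIFF whose gray levels map
#'     linearly onto `[t_min, t_max]`; a JSON sidecar (same path with a
#'     `.json` extension) supplies `t_min`, `t_max` and optionally
#'     `pixel_pitch_cm`. Round-trips to within one quantization step,
#'     `(t_max - t_min)/65535` degrees C.}
#' }
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"matrix-csv"` or `"scaled-image"`.
#' @return a validated [thermogram()].
#' @seealso [write_thermogram()]
#' @export
read_thermogram <- function(path, format = c("auto", "matrix-csv", "scaled-image")) {
  format <- match.arg(format)
  if (!file.exists(path) || dir.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") format <- guess_format(path)
  if (format == "matrix-csv") {
    raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                           strip.white = TRUE)
    vals <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
    if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
    bad <- is.na(vals) & !(toupper(as.matrix(raw)) %in% c("NA", ""))
    if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("cannot parse %s as a temperature at row %d, column %d (0-based)",
                   dQuote(as.matrix(raw)[ij[1L], ij[2L]]), ij[1L] - 1L, ij[2L] - 1L),
           call. = FALSE)
    }
    if (anyNA(vals)) {
      ij <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing temperature at row %d, column %d (0-based)",
                   ij[1L] - 1L, ij[2L] - 1L), call. = FALSE)
    }
    meta <- list()
    sc <- sidecar_path(path)
    if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    thermogram(unname(vals), pixel_pitch_cm = meta$pixel_pitch_cm,
               source_id = meta$source_id %||% path)
  } else {
    sc <- sidecar_path(path)
    if (!file.exists(sc)) {
      stop(sprintf("scaled-image format requires a JSON sidecar at %s", sc),
           call. = FALSE)
    }
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(meta$t_min) || is.null(meta$t_max)) {
      stop("sidecar must supply t_min and t_max", call. = FALSE)
    }
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    temps <- meta$t_min + img * (meta$t_max - meta$t_min)
    thermogram(temps, pixel_pitch_cm = meta$pixel_pitch_cm,
               source_id = meta$source_id %||% path)
  }
}

#' Write a thermogram to disk
#'
#' `matrix-csv` round-trips bit-exactly; `scaled-image` (16-bit grayscale TIFF
#' with JSON sidecar) round-trips to within one quantization step of the
#' written temperature range.
#'
#' @param tg a [thermogram()].
#' @param path destination file.
#' @param format see [read_thermogram()].
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(tg, path, format = c("auto", "matrix-csv", "scaled-image")) {
  stopifnot(is_thermogram(tg))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (dir.exists(path)) stop(sprintf("cannot write to a directory: %s", path), call. = FALSE)
  meta <- list(t_min = min(tg$temps), t_max = max(tg$temps))
  if (!is.null(tg$pixel_pitch_cm)) meta$pixel_pitch_cm <- tg$pixel_pitch_cm
  if (!is.null(tg$source_id)) meta$source_id <- tg$source_id
  if (format == "matrix-csv") {
    ok <- tryCatch({
      # 17 significant digits: doubles survive the text round-trip bit-exactly
      chars <- matrix(formatC(tg$temps, digits = 17, format = "g"),
                      nrow(tg$temps))
      writeLines(apply(chars, 1L, paste, collapse = ","), path)
      TRUE
    }, error = function(e) e, warning = function(w) w)
    if (!isTRUE(ok)) stop(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                          call. = FALSE)
    if (!is.null(tg$pixel_pitch_cm) || !is.null(tg$source_id)) {
      jsonlite::write_json(meta[setdiff(names(meta), c("t_min", "t_max"))],
                           sidecar_path(path), auto_unbox = TRUE, digits = NA)
    }
  } else {
    rng <- meta$t_max - meta$t_min
    scaled <- if (rng > 0) (tg$temps - meta$t_min) / rng else tg$temps * 0
    ok <- tryCatch(tiff::writeTIFF(scaled, path, bits.per.sample = 16L),
                   error = function(e) e, warning = function(w) w)
    if (inherits(ok, "condition")) {
      stop(sprintf("cannot write %s: %s", path, conditionMessage(ok)), call. = FALSE)
    }
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
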