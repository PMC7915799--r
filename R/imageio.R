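#' 2-D median filtering of a volume
#'
#' Removes impulse noise from tomographic slices. Each slice is filtered
#' independently (the acquisition is a stack of 2-D images): every voxel
#' is replaced by the median of its (2r+1) x (2r+1) in-slice
#' neighbourhood, with edges handled by mirror reflection (the edge row
#' itself is not duplicated).
#'
#' @param volume a [sinus_volume()].
#' @param window_radius integer r >= 1; default 1 (3 x 3 window).
#' @return The filtered [sinus_volume()].
#' @export
median_filter <- function(volume, window_radius = 1L) {
  stopifnot(inherits(volume, "sinus_volume"))
  r <- as.integer(window_radius)
  if (r < 1L) stop("window_radius must be >= 1")
  d <- dim(volume$intensities)
  if (d[2] <= r || d[3] <= r)
    stop("slice dimensions must exceed the window radius")
  out <- volume$intensities
  refl <- function(n) c(seq(r + 1L, 2L), seq_len(n), seq(n - 1L, n - r))
  iy <- refl(d[2]); ix <- refl(d[3])
  w <- 2L * r + 1L
  for (k in seq_len(d[1])) {
    padded <- volume$intensities[k, , ][iy, ix]
    stack <- matrix(0, nrow = d[2] * d[3], ncol = w * w)
    col <- 0L
    for (dy in 0:(w - 1L)) for (dx in 0:(w - 1L)) {
      col <- col + 1L
      stack[, col] <- padded[dy + seq_len(d[2]), dx + seq_len(d[3])]
    }
    # median of an odd-sized window = middle order statistic per row
    stack <- matrix(stack[order(row(stack), stack)],
                    nrow = d[2] * d[3], byrow = TRUE)
    out[k, , ] <- matrix(stack[, (w * w + 1L) %/% 2L], d[2], d[3])
  }
  sinus_volume(out, spacing_mm = volume$spacing_mm, unit = volume$unit,
               window = volume$window)
}

# deterministic half-up rounding (round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

#' Hounsfield display windowing to 8-bit
#'
#' Linearly maps the Hounsfield interval
#' `[center - width/2, center + width/2]` onto 0..255, clipping outside
#' and rounding half-up. The soft-tissue window (center 40, width 400)
#' is the usual choice when profiling sinus content.
#'
#' @param volume a [sinus_volume()] in Hu.
#' @param center window centre, Hu.
#' @param width window width, Hu; must be > 0.
#' @return An 8-bit [sinus_volume()] with the window recorded.
#' @export
hu_window_to_8bit <- function(volume, center = 40, width = 400) {
  stopifnot(inherits(volume, "sinus_volume"))
  if (volume$unit != "Hu") stop("volume is not in Hounsfield units")
  if (!is.finite(width) || width <= 0) stop("width must be > 0")
  lo <- center - width / 2
  scaled <- (volume$intensities - lo) / width * 255
  v <- round_half_up(pmin(pmax(scaled, 0), 255))
  sinus_volume(array(v, dim = dim(volume$intensities)),
               spacing_mm = volume$spacing_mm, unit = "8bit",
               window = c(center, width))
}

#' DICOM-style affine rescale of stored values to Hounsfield units
#'
#' `hu = stored * slope + intercept`, the standard CT calibration
#' (typically slope 1, intercept -1024).
#'
#' @param stored numeric stored values.
#' @param slope rescale slope.
#' @param intercept rescale intercept.
#' @return Numeric Hu values.
#' @export
rescale_to_hu <- function(stored, slope = 1, intercept = -1024) {
  stored * slope + intercept
}

#' Write / read a slice-stack volume
#'
#' The on-disk format is a directory of equally sized PNG slices
#' (`slice_0000.png`, `slice_0001.png`, ...) plus a `volume.json`
#' sidecar recording spacing, intensity unit and any display window.
#' 8-bit volumes are stored as plain grayscale PNGs and round-trip
#' bit-identically. Hu volumes are stored losslessly as 16-bit unsigned
#' values (offset by the recorded rescale intercept) split across the
#' two 8-bit channels of a grey+alpha PNG; integer Hu in
#' [-1024, 64511] round-trip exactly.
#'
#' @param volume a [sinus_volume()].
#' @param path directory to create/overwrite.
#' @return `write_volume` returns `path` invisibly; `read_volume`
#'   returns a [sinus_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "sinus_volume"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$intensities)
  intercept <- -1024
  sidecar <- list(spacing_mm = volume$spacing_mm,
                  intensity_unit = volume$unit,
                  window = volume$window,
                  n_slices = d[1], shape_kyx = d,
                  encoding = if (volume$unit == "8bit") "gray8" else "hu16",
                  rescale_slope = 1, rescale_intercept = intercept)
  jsonlite::write_json(sidecar, file.path(path, "volume.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (k in seq_len(d[1])) {
    sl <- volume$intensities[k, , ]
    f <- file.path(path, sprintf("slice_%04d.png", k - 1L))
    if (volume$unit == "8bit") {
      png::writePNG(sl / 255, f)
    } else {
      stored <- round_half_up(sl) - intercept
      if (any(stored < 0 | stored > 65535))
        stop("Hu values outside the storable range [-1024, 64511]")
      img <- array(0, dim = c(d[2], d[3], 2))
      img[, , 1] <- (stored %/% 256) / 255
      img[, , 2] <- (stored %% 256) / 255
      png::writePNG(img, f)
    }
  }
  invisible(path)
}

#' @rdname write_volume
#' @param path directory written by [write_volume()].
#' @export
read_volume <- function(path) {
  sidecar_file <- file.path(path, "volume.json")
  if (!file.exists(sidecar_file)) stop("missing volume.json sidecar in ", path)
  side <- jsonlite::read_json(sidecar_file, simplifyVector = TRUE)
  for (f in c("spacing_mm", "intensity_unit", "n_slices", "encoding"))
    if (is.null(side[[f]])) stop("sidecar missing field '", f, "'")
  n <- side$n_slices
  slices <- vector("list", n)
  shape <- NULL
  for (k in seq_len(n)) {
    f <- file.path(path, sprintf("slice_%04d.png", k - 1L))
    if (!file.exists(f)) stop("missing slice file ", basename(f))
    img <- png::readPNG(f)
    if (side$encoding == "gray8") {
      if (length(dim(img)) == 3L) img <- img[, , 1]
      sl <- round_half_up(img * 255)
    } else {
      if (length(dim(img)) != 3L || dim(img)[3] < 2L)
        stop("slice ", k - 1L, " is not a two-channel hu16 image")
      stored <- round_half_up(img[, , 1] * 255) * 256 +
        round_half_up(img[, , 2] * 255)
      sl <- rescale_to_hu(stored, side$rescale_slope, side$rescale_intercept)
    }
    if (is.null(shape)) shape <- dim(sl)
    if (!identical(dim(sl), shape))
      stop(sprintf("slice %d has shape %s, expected %s", k - 1L,
                   paste(dim(sl), collapse = "x"),
                   paste(shape, collapse = "x")))
    slices[[k]] <- sl
  }
  vol <- array(0, dim = c(n, shape[1], shape[2]))
  for (k in seq_len(n)) vol[k, , ] <- slices[[k]]
  win <- side$window
  if (!is.null(win) && length(win) == 0) win <- NULL
  sinus_volume(vol, spacing_mm = side$spacing_mm,
               unit = side$intensity_unit, window = win)
}
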