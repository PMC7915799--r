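#' Volumetric image containers
#'
#' A `sinus_volume` wraps a 3-D intensity array indexed `[k, y, x]`
#' (slice, row, column; 0-based voxel coordinates at the interface,
#' 1-based internally as usual in R) together with per-axis voxel
#' spacing in millimetres and an intensity-unit tag. CT volumes carry
#' calibrated Hounsfield units (`"Hu"`); display volumes carry windowed
#' 8-bit values (`"8bit"`, range 0..255). An optional `window` records
#' the (center, width) Hounsfield display window that produced an 8-bit
#' volume.
#'
#' @param intensities numeric 3-D array, dimensions `(k, y, x)`.
#' @param spacing_mm numeric length-3, strictly positive: voxel size in
#'   mm along (slice step, row, column). Default `c(1, 0.4, 0.4)`, the
#'   usual spiral-CT acquisition geometry for paranasal studies.
#' @param unit `"Hu"` or `"8bit"`.
#' @param window optional numeric length-2 `(center, width)` in Hu.
#' @return An object of class `sinus_volume`.
#' @export
sinus_volume <- function(intensities, spacing_mm = c(1, 0.4, 0.4),
                         unit = c("Hu", "8bit"), window = NULL) {
  unit <- match.arg(unit)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3-D array (k, y, x)")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 strictly positive numbers")
  if (unit == "8bit") {
    rng <- range(intensities)
    if (rng[1] < 0 || rng[2] > 255)
      stop("8bit volumes must have values in [0, 255]")
  }
  if (!is.null(window)) {
    window <- as.numeric(window)
    if (length(window) != 2L || window[2] <= 0)
      stop("'window' must be (center, width) with width > 0")
  }
  structure(list(intensities = intensities, spacing_mm = spacing_mm,
                 unit = unit, window = window),
            class = "sinus_volume")
}

#' @export
print.sinus_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("sinus_volume: %d x %d x %d (k,y,x), unit %s, spacing %s mm\n",
              d[1], d[2], d[3], x$unit,
              paste(format(x$spacing_mm), collapse = " x ")))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$intensities), max(x$intensities)))
  if (!is.null(x$window))
    cat(sprintf("  display window C %g / W %g Hu\n", x$window[1], x$window[2]))
  invisible(x)
}

#' @export
dim.sinus_volume <- function(x) dim(x$intensities)

# tissue classes used throughout: integer codes into this fixed set
SINUS_CLASSES <- c("background", "bone", "air", "fluid", "mucosa",
                   "cyst", "foreign_body")

# classes making up the sinus cavity interior
SINUS_INTERIOR <- c("air", "fluid", "mucosa", "cyst", "foreign_body")

#' Label volume of tissue classes
#'
#' A `sinus_labels` holds a per-voxel tissue class on the same grid as a
#' paired [sinus_volume()]. Classes are the fixed set background, bone,
#' air, fluid, mucosa, cyst, foreign_body; stored as a character-coded
#' integer array.
#'
#' @param labels 3-D array of class names (character) or integer codes
#'   into `sinus_classes()`.
#' @param spacing_mm per-axis voxel size, mm.
#' @return An object of class `sinus_labels`.
#' @export
sinus_labels <- function(labels, spacing_mm = c(1, 0.4, 0.4)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3-D array (k, y, x)")
  if (is.character(labels)) {
    codes <- match(labels, SINUS_CLASSES)
    if (anyNA(codes)) {
      bad <- unique(labels[is.na(codes)])
      stop("unknown tissue class: ", paste(bad, collapse = ", "))
    }
    labels <- array(codes, dim = dim(labels))
  }
  if (!all(labels %in% seq_along(SINUS_CLASSES)))
    stop("label codes must index the fixed tissue-class set")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 strictly positive numbers")
  structure(list(labels = labels, spacing_mm = spacing_mm),
            class = "sinus_labels")
}

#' Tissue class vocabulary
#' @return Character vector of the seven tissue classes.
#' @export
sinus_classes <- function() SINUS_CLASSES

#' @export
print.sinus_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("sinus_labels: %d x %d x %d (k,y,x)\n", d[1], d[2], d[3]))
  tab <- table(factor(SINUS_CLASSES[x$labels], levels = SINUS_CLASSES))
  print(tab)
  invisible(x)
}

#' @export
dim.sinus_labels <- function(x) dim(x$labels)

# logical mask of voxels whose class is in `classes` (character)
label_mask <- function(labels, classes) {
  stopifnot(inherits(labels, "sinus_labels"))
  array(labels$labels %in% match(classes, SINUS_CLASSES),
        dim = dim(labels$labels))
}

#' Default Hounsfield values per tissue class
#'
#' Air is calibrated at -1000 Hu; serous and purulent effusions sit near
#' 19 and 37 Hu respectively (clinical cohort means); mucosa/polyp,
#' cortical bone and metallic/dental foreign bodies use typical CT
#' values and are configurable.
#'
#' @param fluid_type `"serous"` or `"purulent"`; selects the Hu assigned
#'   to the `fluid` class.
#' @return Named numeric vector over `sinus_classes()`.
#' @export
default_hu_values <- function(fluid_type = c("serous", "purulent")) {
  fluid_type <- match.arg(fluid_type)
  c(background = 40, bone = 700, air = -1000,
    fluid = if (fluid_type == "serous") 19 else 37,
    mucosa = 45, cyst = 45, foreign_body = 2000)
}

#' Render a label volume to Hounsfield intensities
#'
#' @param labels a [sinus_labels()].
#' @param hu_values named numeric: Hu per tissue class present.
#' @return A [sinus_volume()] in Hu.
#' @export
labels_to_volume <- function(labels, hu_values = default_hu_values()) {
  stopifnot(inherits(labels, "sinus_labels"))
  present <- SINUS_CLASSES[sort(unique(as.vector(labels$labels)))]
  missing <- setdiff(present, names(hu_values))
  if (length(missing))
    stop("no Hu value supplied for class(es): ",
         paste(missing, collapse = ", "))
  lut <- rep(NA_real_, length(SINUS_CLASSES))
  lut[match(names(hu_values), SINUS_CLASSES)] <- hu_values
  vol <- array(lut[labels$labels], dim = dim(labels$labels))
  sinus_volume(vol, spacing_mm = labels$spacing_mm, unit = "Hu")
}
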