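#' Mean fluid density (indicator x1)
#'
#' Arithmetic mean of the Hounsfield values over fluid-labelled voxels.
#' Serous effusions sit near 19 Hu, purulent near 37 Hu, so this is the
#' key discriminator between the acute forms. Undefined (NA, flagged)
#' when the sinus contains no fluid; refuses windowed 8-bit volumes,
#' which have lost the calibration.
#'
#' @param volume a [sinus_volume()] in Hu.
#' @param labels the paired [sinus_labels()].
#' @return Mean fluid density, Hu, or `NA` with attribute
#'   `undefined = TRUE` when no fluid voxels exist.
#' @export
fluid_density <- function(volume, labels) {
  stopifnot(inherits(volume, "sinus_volume"), inherits(labels, "sinus_labels"))
  if (volume$unit != "Hu")
    stop("fluid density requires a calibrated Hu volume, not 8-bit display values")
  if (!identical(dim(volume$intensities), dim(labels$labels)))
    stop("volume and labels have different shapes")
  mask <- label_mask(labels, "fluid")
  if (!any(mask)) return(structure(NA_real_, undefined = TRUE))
  mean(volume$intensities[mask])
}

#' Anastomosis (ostium) opening indicator x2
#'
#' Percentage of the ostium reference region that is air-labelled, i.e.
#' how much of the natural anastomosis remains free for aeration and
#' mucociliary drainage. The reference region (the anatomical ostium
#' cross-section / canal) must be supplied as a mask; for phantoms it is
#' the generator's `ostium_mask`.
#'
#' @param labels a [sinus_labels()].
#' @param anastomosis_region logical array (same shape) or voxel index
#'   vector marking the ostium reference region.
#' @return Percentage in [0, 100].
#' @export
anastomosis_opening <- function(labels, anastomosis_region) {
  stopifnot(inherits(labels, "sinus_labels"))
  idx <- if (is.logical(anastomosis_region)) which(anastomosis_region)
         else as.integer(anastomosis_region)
  if (length(idx) == 0L) stop("empty anastomosis region")
  100 * sum(labels$labels[idx] == match("air", SINUS_CLASSES)) / length(idx)
}

# cavity voxel count: union of interior classes
cavity_count <- function(labels) {
  n <- sum(label_mask(labels, SINUS_INTERIOR))
  if (n == 0L) stop("empty sinus cavity: no interior-class voxels")
  n
}

#' Mucosa volume fraction (indicator x3)
#'
#' Percentage of the sinus cavity (air + fluid + mucosa + cyst +
#' foreign body) occupied by mucosa-class content; cystic content is
#' counted with the soft tissue unless requested separately.
#'
#' @param labels a [sinus_labels()].
#' @param include_cyst count cyst voxels as soft-tissue content
#'   (default TRUE).
#' @return Percentage in [0, 100].
#' @export
mucosa_volume_fraction <- function(labels, include_cyst = TRUE) {
  cls <- if (include_cyst) c("mucosa", "cyst") else "mucosa"
  100 * sum(label_mask(labels, cls)) / cavity_count(labels)
}

#' Fluid volume fraction (indicator x4)
#'
#' @param labels a [sinus_labels()].
#' @return Percentage of the cavity occupied by fluid, in [0, 100].
#' @export
fluid_volume_fraction <- function(labels) {
  100 * sum(label_mask(labels, "fluid")) / cavity_count(labels)
}

#' Assemble the five diagnostic indicators
#'
#' x1-x4 are measured on the labelled volume; the aerodynamic drag
#' coefficient x5 comes either from a measured rhinomanometric pair
#' (`dp_kpa`, `q_lps`) or from the hydraulic model (`channels`, a list
#' of two [channel_model()]s, with total flow `q_total` in m^3/s; x5 is
#' then the predicted drop over the total flow, the integral drag
#' index).
#'
#' @param volume a [sinus_volume()] in Hu.
#' @param labels the paired [sinus_labels()].
#' @param anastomosis_region ostium mask, as in [anastomosis_opening()].
#' @param dp_kpa,q_lps measured pressure drop (kPa) and flow (L/s).
#' @param channels list of two [channel_model()]s (geometry route).
#' @param q_total total flow for the geometry route, m^3/s.
#' @return Object of class `indicator_vector`: named numeric
#'   `x1`..`x5` plus a `flags` attribute (e.g. `x1_undefined`,
#'   `x5_missing`).
#' @export
extract_indicators <- function(volume, labels, anastomosis_region,
                               dp_kpa = NULL, q_lps = NULL,
                               channels = NULL, q_total = NULL) {
  x1 <- fluid_density(volume, labels)
  x2 <- anastomosis_opening(labels, anastomosis_region)
  x3 <- mucosa_volume_fraction(labels)
  x4 <- fluid_volume_fraction(labels)
  flags <- character(0)
  if (isTRUE(attr(x1, "undefined"))) flags <- c(flags, "x1_undefined")
  if (!is.null(dp_kpa) && !is.null(q_lps)) {
    x5 <- drag_coefficient(dp_kpa, q_lps)
  } else if (!is.null(channels) && !is.null(q_total)) {
    if (length(channels) != 2L)
      stop("geometry route needs two channel models (left/right passage)")
    fr <- split_flow(channels[[1]], channels[[2]], q_total)
    x5 <- drag_coefficient(fr$dp_kpa, q_total * 1e3)
  } else {
    x5 <- NA_real_
    flags <- c(flags, "x5_missing")
  }
  out <- c(x1 = as.numeric(x1), x2 = x2, x3 = x3, x4 = x4, x5 = x5)
  structure(out, flags = flags, class = "indicator_vector")
}

#' @export
print.indicator_vector <- function(x, ...) {
  cat("diagnostic indicators:\n")
  lab <- c("fluid density, Hu", "ostium opening, %", "mucosa volume, %",
           "fluid volume, %", "nasal drag A, kPa/(L/s)")
  for (i in 1:5)
    cat(sprintf("  x%d %-24s %s\n", i, lab[i],
                format(round(unclass(x)[i], 3))))
  fl <- attr(x, "flags")
  if (length(fl)) cat("  flags:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}
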