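#' Configure a synthetic maxillary-sinus phantom
#'
#' The phantom is a spherical air cavity inside a bone shell, embedded in
#' a soft-tissue background, on a regular voxel grid. Pathological
#' content is added as horizontal layers filling the cavity from the
#' bottom (fluid lowest, polypous soft tissue above it), mimicking
#' gravity-dependent fluid levels; optional lesions are a mucosal lining,
#' an intracavitary cyst, a high-density foreign body, a perforation of
#' the bone floor, and a partially blocked ostium (anastomosis) channel
#' through the medial bone wall.
#'
#' All geometry is specified in millimetres so the same physical phantom
#' can be rendered at different grid resolutions. Within a slice the
#' y axis points downward (image-row convention), so "the cavity floor"
#' is at large y.
#'
#' @param grid_shape integer length-3 voxel counts `(k, y, x)`.
#' @param spacing_mm numeric length-3 voxel size in mm.
#' @param sinus_radius_mm radius of the spherical cavity.
#' @param bone_thickness_mm thickness of the surrounding bone shell.
#' @param fluid_fraction fraction (0-1) of cavity volume occupied by
#'   fluid at the bottom.
#' @param polyp_fraction fraction (0-1) of cavity volume occupied by
#'   polypous (mucosa-class) content layered directly above the fluid.
#' @param mucosa_thickness_mm uniform mucosal lining thickness (>= 0).
#' @param fluid_type `"serous"` or `"purulent"` (sets the fluid Hu).
#' @param cyst optional `list(offset_mm =, radius_mm =)`: a spherical
#'   cyst at `center + offset_mm` (offsets in `(k, y, x)` order).
#' @param foreign_body optional `list(offset_mm =, radius_mm =, hu =)`.
#' @param perforation optional `list(center_deg =, half_width_deg =)`:
#'   removes bone voxels whose in-plane angle from the cavity centre
#'   (measured from +x, y downward, so 90 deg is straight down) lies in
#'   the window; exposes the cavity to the background.
#' @param anastomosis_open_fraction fraction (0-1) of the ostium channel
#'   cross-section left air-filled; the rest is mucosa (swelling narrows
#'   the lumen from the wall inward).
#' @param ostium_radius_mm radius of the cylindrical ostium channel
#'   through the medial (-x) bone wall.
#' @param noise optional `list(probability =, seed =)` impulse noise
#'   applied to the rendered intensities.
#' @param hu_values named numeric, Hu per tissue class; defaults from
#'   [default_hu_values()] for the chosen `fluid_type`.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           spacing_mm = c(0.4, 0.4, 0.4),
                           sinus_radius_mm = 10,
                           bone_thickness_mm = 1.6,
                           fluid_fraction = 0,
                           polyp_fraction = 0,
                           mucosa_thickness_mm = 0,
                           fluid_type = c("serous", "purulent"),
                           cyst = NULL,
                           foreign_body = NULL,
                           perforation = NULL,
                           anastomosis_open_fraction = 1,
                           ostium_radius_mm = 1.2,
                           noise = NULL,
                           hu_values = NULL) {
  fluid_type <- match.arg(fluid_type)
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  for (f in c(fluid_fraction, polyp_fraction, anastomosis_open_fraction))
    if (!is.finite(f) || f < 0 || f > 1)
      stop("fractions must lie in [0, 1]")
  if (fluid_fraction + polyp_fraction > 1)
    stop("fluid_fraction + polyp_fraction must not exceed 1")
  if (mucosa_thickness_mm < 0) stop("mucosa_thickness_mm must be >= 0")
  if (sinus_radius_mm <= 0 || bone_thickness_mm <= 0)
    stop("sinus radius and bone thickness must be positive")

  half_extent <- grid_shape * spacing_mm / 2
  outer <- sinus_radius_mm + bone_thickness_mm
  ax_names <- c("k (slice)", "y (row)", "x (column)")
  for (a in 1:3)
    if (outer >= half_extent[a] - spacing_mm[a])
      stop(sprintf(
        "cavity plus bone shell (%.1f mm) does not fit the grid along axis %s (half extent %.1f mm)",
        outer, ax_names[a], half_extent[a]))
  if (mucosa_thickness_mm >= sinus_radius_mm)
    stop("mucosal lining thicker than the cavity radius")
  check_inclusion <- function(obj, what) {
    if (is.null(obj)) return(invisible())
    off <- as.numeric(obj$offset_mm); r <- as.numeric(obj$radius_mm)
    if (length(off) != 3L || r <= 0)
      stop(what, " needs offset_mm (k,y,x) and radius_mm > 0")
    if (sqrt(sum(off^2)) + r > sinus_radius_mm)
      stop(what, " does not fit inside the cavity (offset + radius > sinus radius)")
  }
  check_inclusion(cyst, "cyst")
  check_inclusion(foreign_body, "foreign_body")
  if (!is.null(perforation)) {
    if (is.null(perforation$half_width_deg) || perforation$half_width_deg <= 0)
      stop("perforation needs half_width_deg > 0")
    if (is.null(perforation$center_deg)) perforation$center_deg <- 90
  }
  if (!is.null(noise)) {
    if (is.null(noise$probability) || noise$probability < 0 ||
        noise$probability > 1)
      stop("noise probability must lie in [0, 1]")
    if (is.null(noise$seed)) stop("noise needs an explicit seed")
  }
  if (is.null(hu_values)) hu_values <- default_hu_values(fluid_type)
  if (!is.null(foreign_body) && !is.null(foreign_body$hu))
    hu_values["foreign_body"] <- foreign_body$hu

  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 sinus_radius_mm = sinus_radius_mm,
                 bone_thickness_mm = bone_thickness_mm,
                 fluid_fraction = fluid_fraction,
                 polyp_fraction = polyp_fraction,
                 mucosa_thickness_mm = mucosa_thickness_mm,
                 fluid_type = fluid_type, cyst = cyst,
                 foreign_body = foreign_body, perforation = perforation,
                 anastomosis_open_fraction = anastomosis_open_fraction,
                 ostium_radius_mm = ostium_radius_mm,
                 noise = noise, hu_values = hu_values),
            class = "phantom_config")
}

#' Named phantom presets
#'
#' Presets reproduce the canonical sinus-filling configurations used to
#' define the volumetric indicators, plus one archetype per densitogram
#' signature:
#' \describe{
#'   \item{conditional_norm}{empty, fully aerated sinus (x3 = x4 = 0).}
#'   \item{chronic_polyposis}{60\% of the cavity filled with polypous
#'     content (x3 = 60).}
#'   \item{acute_serous}{40\% serous fluid (x1 = 19 Hu, x4 = 40).}
#'   \item{acute_purulent}{40\% purulent fluid (x1 = 37 Hu, x4 = 40).}
#'   \item{exacerbated_mixed}{30\% polypous + 20\% fluid (x3 = 30,
#'     x4 = 20).}
#'   \item{cyst}{aerated sinus with an intracavitary cyst below centre.}
#'   \item{foreign_body}{40\% fluid plus a dense foreign body in the
#'     fluid layer.}
#'   \item{perforation}{40\% fluid with the bone floor perforated.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_preset <- function(name = c("conditional_norm", "chronic_polyposis",
                                    "acute_serous", "acute_purulent",
                                    "exacerbated_mixed", "cyst",
                                    "foreign_body", "perforation"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    conditional_norm  = list(),
    chronic_polyposis = list(polyp_fraction = 0.6),
    acute_serous      = list(fluid_fraction = 0.4, fluid_type = "serous"),
    acute_purulent    = list(fluid_fraction = 0.4, fluid_type = "purulent"),
    exacerbated_mixed = list(polyp_fraction = 0.3, fluid_fraction = 0.2),
    cyst              = list(cyst = list(offset_mm = c(0, 4, 0),
                                         radius_mm = 3)),
    foreign_body      = list(fluid_fraction = 0.4,
                             foreign_body = list(offset_mm = c(0, 5, 0),
                                                 radius_mm = 1.6,
                                                 hu = 2000)),
    perforation       = list(fluid_fraction = 0.4,
                             perforation = list(center_deg = 90,
                                                half_width_deg = 25)))
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

#' Generate a synthetic sinus phantom
#'
#' Renders the configured geometry into a label volume, an intensity
#' volume in Hounsfield units, an ostium mask and brute-force ground
#' truth for the volumetric indicators. Deterministic: identical configs
#' (including any noise seed) produce identical output.
#'
#' @param config a [phantom_config()].
#' @return A list of class `sinus_phantom` with elements `volume`
#'   ([sinus_volume()], Hu), `labels` ([sinus_labels()]), `ostium_mask`
#'   (logical array; the anastomosis reference region), `ground_truth`
#'   (`expected_x1`, `expected_x2`, `expected_x3`, `expected_x4`,
#'   `class_counts`), `center_vox` (1-based `(k, y, x)` cavity centre)
#'   and the `config`.
#' @export
make_sinus_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape; sp <- config$spacing_mm
  # physical coordinates of voxel centres, origin at grid centre
  ck <- (seq_len(gs[1]) - (gs[1] + 1) / 2) * sp[1]
  cy <- (seq_len(gs[2]) - (gs[2] + 1) / 2) * sp[2]
  cx <- (seq_len(gs[3]) - (gs[3] + 1) / 2) * sp[3]
  K <- array(ck, dim = gs)
  Y <- array(rep(cy, each = gs[1]), dim = gs)
  X <- array(rep(cx, each = gs[1] * gs[2]), dim = gs)
  dist <- sqrt(K^2 + Y^2 + X^2)

  r <- config$sinus_radius_mm
  outer <- r + config$bone_thickness_mm
  lab <- array(match("background", SINUS_CLASSES), dim = gs)
  lab[dist <= outer] <- match("bone", SINUS_CLASSES)
  cavity <- dist <= r
  lab[cavity] <- match("air", SINUS_CLASSES)
  if (config$mucosa_thickness_mm > 0)
    lab[cavity & dist > r - config$mucosa_thickness_mm] <-
      match("mucosa", SINUS_CLASSES)

  # gravity-layered content: cavity voxels in depth order (y down),
  # deterministic tie-break by (k, x); fluid first, polyp above it
  n_cav <- sum(cavity)
  n_fl <- round(config$fluid_fraction * n_cav)
  n_pl <- round(config$polyp_fraction * n_cav)
  if (n_fl + n_pl > 0) {
    idx <- which(cavity)
    ord <- idx[order(-Y[idx], K[idx], X[idx])]
    air_ord <- ord[lab[ord] == match("air", SINUS_CLASSES)]
    if (n_fl > 0)
      lab[air_ord[seq_len(min(n_fl, length(air_ord)))]] <-
        match("fluid", SINUS_CLASSES)
    if (n_pl > 0 && length(air_ord) > n_fl)
      lab[air_ord[(n_fl + 1):min(n_fl + n_pl, length(air_ord))]] <-
        match("mucosa", SINUS_CLASSES)
  }

  put_sphere <- function(lab, obj, class) {
    off <- as.numeric(obj$offset_mm)
    d2 <- (K - off[1])^2 + (Y - off[2])^2 + (X - off[3])^2
    lab[cavity & d2 <= obj$radius_mm^2] <- match(class, SINUS_CLASSES)
    lab
  }
  if (!is.null(config$cyst)) lab <- put_sphere(lab, config$cyst, "cyst")
  if (!is.null(config$foreign_body))
    lab <- put_sphere(lab, config$foreign_body, "foreign_body")

  if (!is.null(config$perforation)) {
    ang <- atan2(Y, X) * 180 / pi      # y down: 90 deg = floor
    dang <- abs(((ang - config$perforation$center_deg + 180) %% 360) - 180)
    lab[lab == match("bone", SINUS_CLASSES) &
          dang <= config$perforation$half_width_deg] <-
      match("background", SINUS_CLASSES)
  }

  # ostium: cylindrical channel through the superomedial bone wall
  # (above the equator, so it never lies in the lower-hemisphere fan)
  shell <- dist > r & dist <= outer
  y_ost <- -0.4 * r
  axis_d2 <- K^2 + (Y - y_ost)^2
  ostium <- shell & X < 0 & axis_d2 <= config$ostium_radius_mm^2
  if (any(ostium)) {
    oid <- which(ostium)
    # swelling narrows the lumen from the wall inward: keep the
    # axis-nearest fraction open
    ord <- oid[order(axis_d2[oid], K[oid], Y[oid], X[oid])]
    n_open <- round(config$anastomosis_open_fraction * length(ord))
    lab[ord] <- match("mucosa", SINUS_CLASSES)
    if (n_open > 0)
      lab[ord[seq_len(n_open)]] <- match("air", SINUS_CLASSES)
  }

  labels <- sinus_labels(array(lab, dim = gs), spacing_mm = sp)
  volume <- labels_to_volume(labels, config$hu_values)
  if (!is.null(config$noise))
    volume <- add_impulse_noise(volume, config$noise$probability,
                                config$noise$seed)

  counts <- tabulate(lab, nbins = length(SINUS_CLASSES))
  names(counts) <- SINUS_CLASSES
  cav_classes <- match(SINUS_INTERIOR, SINUS_CLASSES)
  n_cavity <- sum(counts[SINUS_INTERIOR])
  gt <- list(
    expected_x1 = if (counts["fluid"] > 0)
      unname(config$hu_values["fluid"]) else NA_real_,
    expected_x2 = if (any(ostium))
      100 * sum(lab[ostium] == match("air", SINUS_CLASSES)) / sum(ostium)
      else NA_real_,
    expected_x3 = unname(100 * sum(counts[c("mucosa", "cyst")]) / n_cavity),
    expected_x4 = unname(100 * counts[["fluid"]] / n_cavity),
    class_counts = counts)
  # 0-based (k, y, x) voxel nearest the cavity centre, matching the
  # trajectory interface convention
  center_vox <- floor(c((gs[1] + 1) / 2, (gs[2] + 1) / 2,
                        (gs[3] + 1) / 2) + 0.5) - 1L
  structure(list(volume = volume, labels = labels, ostium_mask = ostium,
                 ground_truth = gt, center_vox = center_vox,
                 config = config),
            class = "sinus_phantom")
}

#' @export
print.sinus_phantom <- function(x, ...) {
  gt <- x$ground_truth
  cat("sinus_phantom:", paste(dim(x$labels), collapse = " x "),
      "voxels,", x$config$sinus_radius_mm, "mm cavity\n")
  cat(sprintf("  ground truth: x1 %s Hu, x2 %s%%, x3 %.1f%%, x4 %.1f%%\n",
              format(gt$expected_x1), format(round(gt$expected_x2, 1)),
              gt$expected_x3, gt$expected_x4))
  invisible(x)
}

#' Add impulse (salt-and-pepper) noise to a volume
#'
#' Each voxel is independently replaced, with the stated probability, by
#' the minimum or maximum intensity of the volume's range (0/255 for
#' 8-bit volumes, the observed extremes for Hu volumes); replacements
#' are split evenly between the two extremes. Reproducible for a given
#' seed; the global RNG state is left untouched.
#'
#' @param volume a [sinus_volume()].
#' @param probability per-voxel corruption probability in [0, 1].
#' @param seed integer seed.
#' @return A corrupted [sinus_volume()].
#' @export
add_impulse_noise <- function(volume, probability, seed) {
  stopifnot(inherits(volume, "sinus_volume"))
  if (!is.finite(probability) || probability < 0 || probability > 1)
    stop("probability must lie in [0, 1]")
  if (probability == 0) return(volume)
  lo_hi <- if (volume$unit == "8bit") c(0, 255) else range(volume$intensities)
  v <- volume$intensities
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  hit <- stats::runif(length(v)) < probability
  if (any(hit))
    v[hit] <- ifelse(stats::runif(sum(hit)) < 0.5, lo_hi[1], lo_hi[2])
  sinus_volume(v, spacing_mm = volume$spacing_mm, unit = volume$unit,
               window = volume$window)
}
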