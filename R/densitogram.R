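#' Parametric line trajectory across a slice
#'
#' The trajectory from start point Ts to end point Te on slice k is the
#' parametric line `x(t) = xs + (xe - xs) t`, `y(t) = ys + (ye - ys) t`,
#' `t` in [0, 1], sampled at steps of `dt = 1/d` where
#' `d = sqrt((xe - xs)^2 + (ye - ys)^2)` is the Euclidean length in
#' pixels; `t = 1` is always included, so roughly one sample per pixel
#' of path length. Pixel coordinates are 0-based `(x = column,
#' y = row)`, matching the acquisition convention.
#'
#' @param ts numeric length-2 start `(x, y)`, pixels, 0-based.
#' @param te numeric length-2 end `(x, y)`.
#' @param k slice index, 0-based.
#' @param slice_shape optional `(ny, nx)`; when given, endpoints outside
#'   `[0, nx-1] x [0, ny-1]` are rejected.
#' @return Object of class `sinus_trajectory` with fields `start`,
#'   `end`, `k`, `d`, `dt`, `t_samples`, `x`, `y`.
#' @export
line_trajectory <- function(ts, te, k = 0L, slice_shape = NULL) {
  ts <- as.numeric(ts); te <- as.numeric(te)
  stopifnot(length(ts) == 2L, length(te) == 2L)
  if (all(ts == te)) stop("trajectory endpoints coincide")
  if (!is.null(slice_shape)) {
    ny <- slice_shape[1]; nx <- slice_shape[2]
    for (p in list(ts, te))
      if (p[1] < 0 || p[1] > nx - 1 || p[2] < 0 || p[2] > ny - 1)
        stop("trajectory endpoint outside the slice bounds")
  }
  d <- sqrt(sum((te - ts)^2))
  dt <- 1 / d
  t <- (0:floor(d)) / d
  if (t[length(t)] < 1 - 1e-12) t <- c(t, 1) else t[length(t)] <- 1
  structure(list(start = ts, end = te, k = as.integer(k), d = d, dt = dt,
                 t_samples = t,
                 x = ts[1] + (te[1] - ts[1]) * t,
                 y = ts[2] + (te[2] - ts[2]) * t),
            class = "sinus_trajectory")
}

#' @export
print.sinus_trajectory <- function(x, ...) {
  cat(sprintf(
    "sinus_trajectory: (%g, %g) -> (%g, %g) on slice %d; d = %.3f px, %d samples\n",
    x$start[1], x$start[2], x$end[1], x$end[2], x$k, x$d,
    length(x$t_samples)))
  invisible(x)
}

#' Sample a brightness profile (densitogram) along a trajectory
#'
#' @param volume a [sinus_volume()].
#' @param trajectory a [line_trajectory()].
#' @param interpolation `"nearest"` (pixel intensities, the default) or
#'   `"linear"` (bilinear within the slice).
#' @return Object of class `densitogram`: `positions` (pixels along the
#'   trajectory), `positions_mm`, `values`, `unit`, `trajectory`.
#' @export
sample_profile <- function(volume, trajectory,
                           interpolation = c("nearest", "linear")) {
  stopifnot(inherits(volume, "sinus_volume"),
            inherits(trajectory, "sinus_trajectory"))
  interpolation <- match.arg(interpolation)
  d <- dim(volume$intensities)
  k <- trajectory$k + 1L
  if (k < 1L || k > d[1]) stop("trajectory slice outside the volume")
  xs <- trajectory$x; ys <- trajectory$y
  if (any(xs < 0 | xs > d[3] - 1 | ys < 0 | ys > d[2] - 1))
    stop("trajectory leaves the slice bounds")
  sl <- volume$intensities[k, , ]
  if (interpolation == "nearest") {
    ix <- round_half_up(xs) + 1L
    iy <- round_half_up(ys) + 1L
    vals <- sl[cbind(iy, ix)]
  } else {
    x0 <- pmin(floor(xs), d[3] - 2); y0 <- pmin(floor(ys), d[2] - 2)
    fx <- xs - x0; fy <- ys - y0
    i00 <- cbind(y0 + 1L, x0 + 1L); i01 <- cbind(y0 + 1L, x0 + 2L)
    i10 <- cbind(y0 + 2L, x0 + 1L); i11 <- cbind(y0 + 2L, x0 + 2L)
    vals <- (1 - fy) * ((1 - fx) * sl[i00] + fx * sl[i01]) +
      fy * ((1 - fx) * sl[i10] + fx * sl[i11])
  }
  dxy <- trajectory$end - trajectory$start
  len_mm <- sqrt((dxy[1] * volume$spacing_mm[3])^2 +
                 (dxy[2] * volume$spacing_mm[2])^2)
  structure(list(positions = trajectory$t_samples * trajectory$d,
                 positions_mm = trajectory$t_samples * len_mm,
                 values = vals, unit = volume$unit,
                 trajectory = trajectory),
            class = "densitogram")
}

#' @export
print.densitogram <- function(x, ...) {
  cat(sprintf("densitogram: %d samples over %.1f px (%.1f mm), unit %s\n",
              length(x$values), max(x$positions), max(x$positions_mm),
              x$unit))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.densitogram <- function(x, mm = TRUE, ...) {
  pos <- if (mm) x$positions_mm else x$positions
  graphics::plot(pos, x$values, type = "l",
                 xlab = if (mm) "position along trajectory, mm"
                        else "position, px",
                 ylab = sprintf("intensity (%s)", x$unit), ...)
  invisible(x)
}

#' Locate the sinus centre on a slice
#'
#' Centroid (arithmetic mean of coordinates, rounded to the nearest
#' voxel) of the sinus-interior voxels (air, fluid, mucosa, cyst,
#' foreign body) on the chosen slice.
#'
#' @param labels a [sinus_labels()].
#' @param k slice index, 0-based.
#' @return Named numeric `(x, y)` centre, 0-based pixel coordinates.
#' @export
sinus_center <- function(labels, k) {
  stopifnot(inherits(labels, "sinus_labels"))
  d <- dim(labels$labels)
  if (k < 0 || k > d[1] - 1) stop("slice index outside the volume")
  sl <- labels$labels[k + 1L, , ]
  inside <- which(matrix(sl %in% match(SINUS_INTERIOR, SINUS_CLASSES),
                         d[2], d[3]), arr.ind = TRUE)
  if (nrow(inside) == 0L)
    stop("center undeterminable: no sinus-interior voxels on slice ", k)
  c(x = round_half_up(mean(inside[, 2] - 1)),
    y = round_half_up(mean(inside[, 1] - 1)))
}

#' Radial fan of trajectories from the sinus centre
#'
#' Rays at equally spaced angles. For the lower-hemisphere sector the
#' angles span [0, 180] degrees inclusive, measured from the +x axis
#' with y pointing down (so 0 is horizontal, 90 straight down); for the
#' full sector they cover [0, 360). Each ray runs from the centre
#' towards `center + radius * (cos a, sin a)`, shortened where needed so
#' it stays inside the slice.
#'
#' @param center named/plain numeric `(x, y)`, 0-based pixels.
#' @param radius ray length, pixels.
#' @param n_rays number of rays (>= 3). Default 13 (15-degree spacing on
#'   the lower hemisphere).
#' @param sector `"lower_hemisphere"` or `"full"`.
#' @param slice_shape `(ny, nx)` of the slice.
#' @param k slice index, 0-based.
#' @return List of [line_trajectory()] objects; each carries its angle
#'   (degrees) as attribute `"angle_deg"`.
#' @export
radial_fan <- function(center, radius, n_rays = 13L,
                       sector = c("lower_hemisphere", "full"),
                       slice_shape, k = 0L) {
  sector <- match.arg(sector)
  center <- as.numeric(center)
  if (n_rays < 3L) stop("n_rays must be >= 3")
  if (radius <= 0) stop("radius must be positive")
  ny <- slice_shape[1]; nx <- slice_shape[2]
  if (center[1] < 0 || center[1] > nx - 1 ||
      center[2] < 0 || center[2] > ny - 1)
    stop("center outside the slice")
  angles <- if (sector == "lower_hemisphere")
    seq(0, 180, length.out = n_rays) else
    seq(0, 360, length.out = n_rays + 1L)[seq_len(n_rays)]
  lapply(angles, function(a) {
    dir <- c(cos(a * pi / 180), sin(a * pi / 180))
    # largest step s <= radius keeping center + s*dir inside the slice
    s <- radius
    lims <- c(nx - 1, ny - 1)
    for (i in 1:2) {
      if (dir[i] > 1e-12) s <- min(s, (lims[i] - center[i]) / dir[i])
      if (dir[i] < -1e-12) s <- min(s, -center[i] / dir[i])
    }
    tr <- line_trajectory(center, center + s * dir, k = k)
    attr(tr, "angle_deg") <- a
    tr
  })
}

#' Default profile-classification thresholds (Hounsfield scale)
#'
#' Intensity cut-offs separating air, soft-tissue content, bone and
#' foreign-body material, plus the minimum prominence of the terminal
#' bone peak over the cavity plateau and the minimum run length counting
#' as a content plateau. Must be re-specified when profiles are in
#' windowed 8-bit units.
#'
#' @param t_air,t_tissue,t_bone,t_foreign intensity cut-offs (ordered
#'   `t_air < t_tissue < t_bone <= t_foreign`).
#' @param prominence minimum excess of the bone peak over the plateau
#'   median.
#' @param min_plateau minimum consecutive samples for a content plateau.
#' @return Named list of thresholds.
#' @export
profile_thresholds <- function(t_air = -500, t_tissue = 0, t_bone = 300,
                               t_foreign = 1500, prominence = 200,
                               min_plateau = 3L) {
  th <- list(t_air = t_air, t_tissue = t_tissue, t_bone = t_bone,
             t_foreign = t_foreign, prominence = prominence,
             min_plateau = as.integer(min_plateau))
  if (!(th$t_air < th$t_tissue && th$t_tissue < th$t_bone &&
        th$t_bone <= th$t_foreign))
    stop("thresholds must be ordered t_air < t_tissue < t_bone <= t_foreign")
  th
}

PROFILE_LABELS <- c("FOREIGN_BODY", "PERFORATION", "CYST",
                    "TISSUE_CONTENT", "NORMAL")

#' Classify a densitogram signature
#'
#' Decision rules, applied in priority order (most specific evidence
#' first):
#' \enumerate{
#'   \item FOREIGN_BODY - any sample at or above `t_foreign` (dense
#'     inclusion);
#'   \item PERFORATION - a soft-tissue plateau but no terminal bone
#'     peak (the bone border is missing);
#'   \item CYST - the profile crosses `t_tissue` upward at least twice
#'     up to the bone peak (an additional border inside the cavity),
#'     with a bone peak present;
#'   \item TISSUE_CONTENT - a soft-tissue plateau with a single rise
#'     and a terminal bone peak;
#'   \item NORMAL - air-level cavity throughout with a terminal bone
#'     peak.
#' }
#' A bone peak is a sample at or above `t_bone` whose height exceeds
#' the plateau median by at least `prominence`. Samples beyond the
#' first bone-peak sample do not affect the decision, so padding the
#' ray past the sinus wall is harmless.
#'
#' @param profile a [sample_profile()] result with >= 5 samples.
#' @param thresholds a [profile_thresholds()] list (Hu-scale defaults).
#' @return Object of class `profile_signature`: `label` plus an
#'   `evidence` list (crossings, bone-peak position/value, plateau run
#'   length, interior maximum, foreign-body position).
#' @export
classify_profile <- function(profile, thresholds = profile_thresholds()) {
  stopifnot(inherits(profile, "densitogram"))
  v <- profile$values
  n <- length(v)
  if (n < 5L) stop("profile too short: need >= 5 samples")
  th <- do.call(profile_thresholds, thresholds[c("t_air", "t_tissue",
                                                 "t_bone", "t_foreign",
                                                 "prominence",
                                                 "min_plateau")])

  below_bone <- v[v < th$t_bone]
  plateau_med <- if (length(below_bone)) stats::median(below_bone)
                 else stats::median(v)
  peak_ok <- v >= th$t_bone & v >= plateau_med + th$prominence
  has_bone_peak <- any(peak_ok)
  ib <- if (has_bone_peak) which(peak_ok)[1] else n
  # analysis window: up to and including the first bone-peak sample
  w <- v[seq_len(ib)]
  crossings <- sum(w[-1] >= th$t_tissue & w[-length(w)] < th$t_tissue) +
    as.integer(w[1] >= th$t_tissue)
  interior <- if (has_bone_peak && ib > 1L) v[seq_len(ib - 1L)] else w
  runs <- rle(interior >= th$t_tissue)
  plateau_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  has_tissue <- plateau_run >= th$min_plateau
  fb_idx <- which(v >= th$t_foreign)

  label <-
    if (length(fb_idx)) "FOREIGN_BODY"
    else if (!has_bone_peak && has_tissue) "PERFORATION"
    else if (has_bone_peak && crossings >= 2L) "CYST"
    else if (has_bone_peak && has_tissue) "TISSUE_CONTENT"
    else "NORMAL"

  structure(list(
    label = label,
    evidence = list(
      crossings = crossings,
      has_bone_peak = has_bone_peak,
      bone_peak_index = if (has_bone_peak) ib else NA_integer_,
      bone_peak_value = if (has_bone_peak) max(v[peak_ok]) else NA_real_,
      plateau_run = plateau_run,
      interior_max = max(interior),
      plateau_median = plateau_med,
      foreign_index = if (length(fb_idx)) fb_idx[1] else NA_integer_),
    thresholds = th),
    class = "profile_signature")
}

#' @export
print.profile_signature <- function(x, ...) {
  e <- x$evidence
  cat("profile_signature:", x$label, "\n")
  cat(sprintf("  bone peak: %s; tissue plateau run %d; upward crossings %d\n",
              if (e$has_bone_peak)
                sprintf("%g at sample %d", e$bone_peak_value,
                        e$bone_peak_index) else "absent",
              e$plateau_run, e$crossings))
  invisible(x)
}

#' Aggregate per-ray signatures into a sinus-level finding
#'
#' Labels are ranked FOREIGN_BODY > PERFORATION > CYST > TISSUE_CONTENT
#' > NORMAL; the highest-priority label supported by at least
#' `min_support` rays wins (single-ray artifacts can be suppressed by
#' raising the support). If no label reaches the support threshold the
#' most frequent label is returned.
#'
#' @param signatures list of [classify_profile()] results.
#' @param min_support minimum number of supporting rays (default 1).
#' @return List of class `sinus_finding`: `label`, `support`, `counts`.
#' @export
aggregate_signatures <- function(signatures, min_support = 1L) {
  if (length(signatures) == 0L) stop("no signatures to aggregate")
  labels <- vapply(signatures, function(s) s$label, character(1))
  counts <- table(factor(labels, levels = PROFILE_LABELS))
  label <- NA_character_
  for (lv in PROFILE_LABELS)
    if (counts[[lv]] >= min_support) { label <- lv; break }
  if (is.na(label)) label <- names(which.max(counts))
  structure(list(label = label, support = as.integer(counts[[label]]),
                 counts = counts, n_rays = length(signatures)),
            class = "sinus_finding")
}

#' @export
print.sinus_finding <- function(x, ...) {
  cat(sprintf("sinus_finding: %s (%d of %d rays)\n",
              x$label, x$support, x$n_rays))
  invisible(x)
}
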