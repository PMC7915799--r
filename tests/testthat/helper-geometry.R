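# shared fixtures and geometric oracles, built in code at test time

# phantom preset rendered at grid size n with constant physical extent
# (25.6 mm across), so the same anatomy appears at different resolutions
preset_at_resolution <- function(name, n, ...) {
  make_sinus_phantom(phantom_preset(name, grid_shape = c(n, n, n),
                                    spacing_mm = rep(25.6 / n, 3), ...))
}

# chord length (mm) of a ray in direction `angle_deg` (x right, y down)
# through a sphere, given the (y, x) offset of the sphere centre from
# the ray origin; 0 if missed
ray_sphere_chord <- function(angle_deg, sph_offset_yx_mm, sph_r_mm,
                             ray_len_mm = Inf) {
  dirv <- c(sin(angle_deg * pi / 180), cos(angle_deg * pi / 180)) # (y, x)
  proj <- sum(dirv * sph_offset_yx_mm)
  d2 <- sum(sph_offset_yx_mm^2) - proj^2
  if (d2 >= sph_r_mm^2 || proj < 0) return(0)
  half <- sqrt(sph_r_mm^2 - d2)
  max(0, min(proj + half, ray_len_mm) - max(proj - half, 0))
}

# in-slice chords through a spherical lesion for a set of fan angles,
# using the *actual* discretized ray origin (`ctr`, 0-based x,y) and
# the slice's physical offset from the lesion centre plane
phantom_lesion_chords <- function(ph, angles, ctr, k, lesion) {
  sp <- ph$labels$spacing_mm
  gs <- dim(ph$labels)
  grid_c <- (gs - 1) / 2                # 0-based continuous centre
  lesion_kyx <- lesion$offset_mm        # (k, y, x) mm from the mm origin
  origin_yx <- c(ctr["y"] - grid_c[2], ctr["x"] - grid_c[3]) * sp[2:3]
  zk <- (k - grid_c[1]) * sp[1] - lesion_kyx[1]
  r_eff2 <- lesion$radius_mm^2 - zk^2
  if (r_eff2 <= 0) return(rep(0, length(angles)))
  off <- c(lesion_kyx[2], lesion_kyx[3]) - origin_yx   # (y, x) mm
  vapply(angles, ray_sphere_chord, numeric(1),
         sph_offset_yx_mm = off, sph_r_mm = sqrt(r_eff2))
}

# lower-hemisphere fan over a phantom's central slice, with profiles
phantom_fan <- function(ph, n_rays = 13, radius_px = NULL) {
  k <- ph$center_vox[1]
  ctr <- sinus_center(ph$labels, k)
  shp <- dim(ph$labels)[2:3]
  if (is.null(radius_px)) radius_px <- max(shp)
  fan <- radial_fan(ctr, radius_px, n_rays, "lower_hemisphere",
                    slice_shape = shp, k = k)
  profiles <- lapply(fan, function(tr) sample_profile(ph$volume, tr))
  list(fan = fan, profiles = profiles,
       signatures = lapply(profiles, classify_profile),
       center = ctr, k = k)
}

# hand-built densitogram from raw values (1 px spacing)
toy_profile <- function(values) {
  n <- length(values)
  tr <- line_trajectory(c(0, 0), c(n - 1, 0), k = 0L)
  structure(list(positions = seq_len(n) - 1,
                 positions_mm = seq_len(n) - 1,
                 values = values, unit = "Hu", trajectory = tr),
            class = "densitogram")
}
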