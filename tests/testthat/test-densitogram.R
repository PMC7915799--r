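test_that("parametric trajectories follow the line equations", {
  tr <- line_trajectory(c(0, 0), c(3, 4))
  expect_equal(tr$d, 5)
  expect_equal(tr$dt, 0.2)
  expect_equal(tr$t_samples, seq(0, 1, 0.2))
  ax <- line_trajectory(c(0, 0), c(10, 0))
  expect_equal(ax$x, 0:10)
  expect_equal(ax$y, rep(0, 11))
  tr2 <- line_trajectory(c(2, 3), c(7, 15))
  expect_equal(tr2$d, 13)
  expect_length(tr2$t_samples, 14)
  # brute-force evaluation of the parametric equations at each t
  expect_equal(tr2$x, 2 + (7 - 2) * tr2$t_samples)
  expect_equal(tr2$y, 3 + (15 - 3) * tr2$t_samples)
  expect_error(line_trajectory(c(1, 1), c(1, 1)), "coincide")
  expect_error(line_trajectory(c(-1, 0), c(3, 3), slice_shape = c(10, 10)),
               "outside")
})

test_that("random trajectories match brute-force sampling", {
  set.seed(101)
  for (i in 1:100) {
    ts <- stats::runif(2, 0, 50); te <- stats::runif(2, 0, 50)
    if (all(abs(te - ts) < 1e-6)) next
    tr <- line_trajectory(ts, te)
    d <- sqrt(sum((te - ts)^2))
    expect_equal(tr$d, d)
    expect_lte(abs(length(tr$t_samples) - (ceiling(d) + 1)), 1)
    expect_equal(tr$x, ts[1] + (te[1] - ts[1]) * tr$t_samples)
    expect_equal(tr$y, ts[2] + (te[2] - ts[2]) * tr$t_samples)
    expect_true(all(diff(tr$t_samples) > 0))
    expect_equal(tr$t_samples[length(tr$t_samples)], 1)
  }
})

test_that("profiles sample the slice under both interpolators", {
  sl <- array(100, dim = c(1, 20, 20))
  vol <- sinus_volume(sl, unit = "Hu")
  tr <- line_trajectory(c(1, 2), c(15, 17))
  expect_true(all(sample_profile(vol, tr, "nearest")$values == 100))
  expect_true(all(abs(sample_profile(vol, tr, "linear")$values - 100) < 1e-9))
  # vertical step edge: nearest interpolation gives a step at the crossing
  step <- array(0, dim = c(1, 20, 20)); step[1, , 11:20] <- 200
  vs <- sinus_volume(step, unit = "Hu")
  prof <- sample_profile(vs, line_trajectory(c(0, 5), c(19, 5)), "nearest")
  expect_equal(unique(prof$values), c(0, 200))
  expect_equal(prof$values, ifelse(round(prof$trajectory$x) + 1 >= 11, 200, 0))
  # endpoints equal intensities at Ts/Te; reversal reverses the profile
  # (exact for integer-length trajectories, whose sample sets coincide)
  set.seed(7)
  rnd <- sinus_volume(array(stats::rnorm(400), dim = c(1, 20, 20)),
                      unit = "Hu")
  fwd <- sample_profile(rnd, line_trajectory(c(2, 3), c(7, 15)), "nearest")
  rev <- sample_profile(rnd, line_trajectory(c(7, 15), c(2, 3)), "nearest")
  expect_equal(fwd$values, base::rev(rev$values))
  expect_equal(fwd$values[1], rnd$intensities[1, 4, 3])
  expect_equal(fwd$values[length(fwd$values)], rnd$intensities[1, 16, 8])
  expect_error(sample_profile(vol, line_trajectory(c(0, 0), c(30, 0))),
               "bounds")
})

test_that("sinus centre is the interior-class centroid", {
  ph <- make_sinus_phantom(phantom_config())
  k <- ph$center_vox[1]
  ctr <- sinus_center(ph$labels, k)
  expect_lte(max(abs(ctr - ph$center_vox[c(3, 2)])), 1)
  # half-filled sinus: content classes all count, centroid unchanged
  half <- make_sinus_phantom(phantom_config(fluid_fraction = 0.5))
  expect_equal(sinus_center(half$labels, k), ctr)
  # crescent region: brute-force coordinate averaging
  lab <- array(match("background", sinus_classes()), dim = c(1, 40, 40))
  for (y in 0:39) for (x in 0:39) {
    r1 <- sqrt((y - 20)^2 + (x - 20)^2)
    r2 <- sqrt((y - 20)^2 + (x - 14)^2)
    if (r1 < 15 && r2 > 10) lab[1, y + 1, x + 1] <- match("air",
                                                          sinus_classes())
  }
  lv <- sinus_labels(lab, spacing_mm = c(1, 1, 1))
  got <- sinus_center(lv, 0)
  idx <- which(lab[1, , ] == match("air", sinus_classes()), arr.ind = TRUE)
  expect_equal(unname(got["x"]), floor(mean(idx[, 2] - 1) + 0.5))
  expect_equal(unname(got["y"]), floor(mean(idx[, 1] - 1) + 0.5))
  empty <- sinus_labels(array(match("bone", sinus_classes()),
                              dim = c(1, 5, 5)), spacing_mm = c(1, 1, 1))
  expect_error(sinus_center(empty, 0), "center undeterminable")
})

test_that("radial fans span the lower hemisphere and clip to the slice", {
  f3 <- radial_fan(c(20, 20), 10, 3, "lower_hemisphere",
                   slice_shape = c(41, 41))
  expect_equal(vapply(f3, attr, numeric(1), "angle_deg"), c(0, 90, 180))
  f5 <- radial_fan(c(20, 20), 10, 5, "lower_hemisphere",
                   slice_shape = c(41, 41))
  expect_equal(diff(vapply(f5, attr, numeric(1), "angle_deg")),
               rep(45, 4))
  # centre near the edge: every ray stays inside, d <= radius
  fe <- radial_fan(c(2, 38), 25, 13, "lower_hemisphere",
                   slice_shape = c(41, 41))
  for (tr in fe) {
    expect_lte(tr$d, 25 + 1e-9)
    expect_true(all(tr$x >= 0 & tr$x <= 40 & tr$y >= 0 & tr$y <= 40))
  }
  expect_error(radial_fan(c(50, 20), 10, 5, slice_shape = c(41, 41)),
               "outside")
})

test_that("toy profiles trigger the documented signature rules", {
  th <- profile_thresholds()
  # air plateau with a pronounced terminal bone peak
  expect_equal(classify_profile(toy_profile(c(rep(-1000, 20), 700)),
                                th)$label, "NORMAL")
  # tissue plateau, no bone border anywhere
  expect_equal(classify_profile(toy_profile(c(rep(-1000, 5), rep(40, 15))),
                                th)$label, "PERFORATION")
  # a dense inclusion dominates every other feature
  expect_equal(classify_profile(toy_profile(c(rep(-1000, 5), 2000,
                                              rep(40, 5), 700)),
                                th)$label, "FOREIGN_BODY")
  # additional border inside the cavity: two upward crossings
  expect_equal(classify_profile(toy_profile(c(rep(-1000, 5), rep(45, 5),
                                              rep(-1000, 5), 700)),
                                th)$label, "CYST")
  # single tissue rise with a bone border
  expect_equal(classify_profile(toy_profile(c(rep(-1000, 5), rep(45, 8),
                                              700)), th)$label,
               "TISSUE_CONTENT")
  expect_error(classify_profile(toy_profile(c(1, 2, 3))), "too short")
  expect_error(classify_profile(toy_profile(rep(0, 9)),
                                profile_thresholds(t_air = 10,
                                                   t_tissue = 0)),
               "ordered")
})

test_that("classification ignores samples beyond the bone peak", {
  th <- profile_thresholds()
  base <- c(rep(-1000, 10), rep(45, 6), rep(-1000, 4), 700)
  padded <- c(base, rep(40, 15), 700, rep(-1000, 5))
  expect_equal(classify_profile(toy_profile(base), th)$label,
               classify_profile(toy_profile(padded), th)$label)
  norm <- c(rep(-1000, 15), 700)
  expect_equal(classify_profile(toy_profile(c(norm, rep(40, 20))),
                                th)$label, "NORMAL")
})

test_that("signature aggregation follows the priority order", {
  mk <- function(lbl) structure(list(label = lbl), class = "profile_signature")
  expect_equal(aggregate_signatures(lapply(1:5, function(i)
    mk("NORMAL")))$label, "NORMAL")
  mixed <- c(lapply(1:11, function(i) mk("NORMAL")),
             lapply(1:2, function(i) mk("PERFORATION")))
  expect_equal(aggregate_signatures(mixed, min_support = 2)$label,
               "PERFORATION")
  expect_equal(aggregate_signatures(mixed, min_support = 3)$label, "NORMAL")
  expect_error(aggregate_signatures(list()), "no signatures")
})

test_that("phantom fans classify lesions on the intersecting rays", {
  # healthy sinus: every lower-hemisphere ray is NORMAL
  hp <- phantom_fan(make_sinus_phantom(phantom_preset("conditional_norm")))
  expect_true(all(vapply(hp$signatures, function(s) s$label,
                         character(1)) == "NORMAL"))

  check_lesion <- function(preset, expected) {
    ph <- make_sinus_phantom(phantom_preset(preset))
    res <- phantom_fan(ph)
    angles <- vapply(res$fan, attr, numeric(1), "angle_deg")
    labels <- vapply(res$signatures, function(s) s$label, character(1))
    if (preset == "perforation") {
      win <- ph$config$perforation
      hit <- abs(angles - win$center_deg) < win$half_width_deg
    } else {
      lesion <- ph$config[[if (preset == "cyst") "cyst" else "foreign_body"]]
      vox_mm <- max(ph$labels$spacing_mm[2:3])
      chords <- phantom_lesion_chords(ph, angles, res$center, res$k, lesion)
      hit <- chords >= 2 * vox_mm
    }
    expect_true(any(hit))
    expect_true(all(labels[hit] == expected),
                label = sprintf("%s rays %s classified %s", preset,
                                paste(angles[hit], collapse = ","),
                                paste(labels[hit], collapse = ",")))
    aggregate_signatures(res$signatures)$label
  }
  expect_equal(check_lesion("cyst", "CYST"), "CYST")
  expect_equal(check_lesion("foreign_body", "FOREIGN_BODY"), "FOREIGN_BODY")
  expect_equal(check_lesion("perforation", "PERFORATION"), "PERFORATION")
})

test_that("phantom ray profiles show the minimum plateau and wall peak", {
  ph <- make_sinus_phantom(phantom_config())
  res <- phantom_fan(ph)
  r_px <- ph$config$sinus_radius_mm / ph$labels$spacing_mm[3]
  for (p in res$profiles) {
    sig <- classify_profile(p)
    expect_true(sig$evidence$has_bone_peak)
    # bone border appears at the cavity radius within one voxel
    peak_px <- p$positions[sig$evidence$bone_peak_index]
    expect_lt(abs(peak_px - r_px), 2.5)
    expect_true(all(p$values[p$positions < r_px - 2] == -1000))
  }
})
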