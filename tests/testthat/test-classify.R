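test_that("LD band signs encode helix orientation", {
  par90 <- predict_ld_signs(90)
  expect_equal(par90$sign, c("+", "-")) # surface-parallel helix
  per0 <- predict_ld_signs(0)
  expect_equal(per0$sign, c("-", "+")) # upright helix
  magic <- predict_ld_signs(54.7)
  expect_equal(magic$sign, c("0", "0"))
  expect_error(predict_ld_signs(95), "0, 90")
  expect_error(predict_ld_signs(-1), "0, 90")
})

test_that("the two LD band signs are always opposite or both zero", {
  for (tilt in 0:90) {
    p <- predict_ld_signs(tilt)
    s <- p$sign
    opposite <- (s[1] == "+" && s[2] == "-") || (s[1] == "-" && s[2] == "+")
    both_zero <- all(s == "0")
    expect_true(opposite || both_zero)
    # and the factors satisfy f222 = -f210 / 2 exactly
    expect_equal(p$orientation_factor[2], -p$orientation_factor[1] / 2,
                 tolerance = 1e-12)
  }
})

test_that("surface footprint is the projected convex-hull area", {
  sq <- tibble::tibble(
    residue = 1:4, resname = "ALA", aa = "A", atom = "CA",
    x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0,
    part = "peptide", leaflet = NA_character_
  )
  expect_equal(surface_footprint(sq), 1.0)
  expect_equal(surface_footprint(sq[1:2, ]), 0)
  collinear <- sq; collinear$y <- 0
  expect_equal(surface_footprint(collinear), 0)
  # a lying helix covers more surface than a standing one
  h <- build_ideal_helix("FKRIVQRIKDFLRNLV") # axis along z: standing
  standing <- surface_footprint(h)
  R <- helimode:::.rot_between(c(0, 0, 1), c(1, 0, 0))
  lying <- h
  xyz <- as.matrix(h[, c("x", "y", "z")]) %*% t(R)
  lying$x <- xyz[, 1]; lying$y <- xyz[, 2]; lying$z <- xyz[, 3]
  expect_gt(surface_footprint(lying), surface_footprint(h))
})

test_that("footprint does not increase as the axis approaches the normal", {
  h <- build_ideal_helix("FKRIVQRIKDFLRNLV")
  xyz0 <- as.matrix(h[, c("x", "y", "z")])
  foot_at <- function(tilt_deg) {
    # rotate the (z-aligned) helix axis to the given tilt from the normal
    R <- helimode:::.rot_between(
      c(0, 0, 1),
      c(sin(tilt_deg * pi / 180), 0, cos(tilt_deg * pi / 180))
    )
    fr <- h
    xyz <- xyz0 %*% t(R)
    fr$x <- xyz[, 1]; fr$y <- xyz[, 2]; fr$z <- xyz[, 3]
    surface_footprint(fr)
  }
  tilts <- seq(90, 0, by = -15)
  areas <- vapply(tilts, foot_at, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("classification recovers the generating mode", {
  for (m in c("I", "II", "III", "unbound")) {
    spec <- example_mode_spec(m, seed = 77, n_frames = 60)
    an <- pipeline_analyze(generate_mode_trajectory(spec), alpha = NULL)
    expect_equal(an$call$mode, m)
    expect_false(an$call$low_confidence)
  }
})

test_that("a peptide that never approaches the membrane is unbound", {
  spec <- example_mode_spec("unbound", seed = 3, n_frames = 60)
  traj <- generate_mode_trajectory(spec)
  an <- pipeline_analyze(traj, alpha = NULL)
  expect_equal(an$call$mode, "unbound")
  expect_gte(mean(an$traces$distance$value), 3)
  expect_equal(an$call$evidence[["bound_fraction"]], 0)
})

test_that("classification validates its inputs", {
  spec <- example_mode_spec("I", seed = 1, n_frames = 60)
  tr <- helimode:::.all_traces(generate_mode_trajectory(spec), alpha = NULL)
  # misaligned traces are rejected
  short <- tr$distance[1:30, ]
  expect_error(
    classify_binding_mode(tr$helicity, short, tr$tilt, tr$depth),
    "time-aligned"
  )
  # too-short analysis window is rejected
  spec2 <- example_mode_spec("I", seed = 1, n_frames = 2)
  tr2 <- helimode:::.all_traces(generate_mode_trajectory(spec2), alpha = NULL)
  expect_error(
    classify_binding_mode(tr2$helicity, tr2$distance, tr2$tilt, tr2$depth),
    "window"
  )
})

test_that("low-confidence fallback is total and flagged", {
  spec <- example_mode_spec("I", seed = 2, n_frames = 60)
  tr <- helimode:::.all_traces(generate_mode_trajectory(spec), alpha = NULL)
  # force an inconsistent evidence pattern: bound, helical, but tilt in the
  # dead zone between the upright and parallel cuts
  tilt_mid <- tr$tilt
  tilt_mid$value <- rep(52, nrow(tilt_mid))
  call <- classify_binding_mode(tr$helicity, tr$distance, tilt_mid, tr$depth,
                                com_height = tr$com_height)
  expect_true(call$low_confidence)
  expect_true(call$mode %in% c("I", "II", "III", "unbound"))
})

test_that("mode calls tidy and glance into tibbles", {
  spec <- example_mode_spec("III", seed = 5, n_frames = 60)
  an <- pipeline_analyze(generate_mode_trajectory(spec), alpha = NULL)
  td <- tidy(an$call)
  expect_true(all(c("bound_fraction", "mean_helicity", "median_tilt",
                    "azimuth_circular_variance") %in% td$criterion))
  g <- glance(an)
  expect_equal(g$mode, "III")
  expect_true(is.character(g$config_hash))
  expect_equal(nrow(g), 1)
})
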