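test_that("leaflet splitting partitions by the median plane", {
  m <- rbind(
    cbind(1:4, 0, 2), cbind(1:4, 0, -2)
  )
  b <- split_leaflets(m)
  expect_equal(sum(b$leaflet == "upper"), 4)
  expect_equal(sum(b$leaflet == "lower"), 4)
  # jittered planes recover generation labels exactly
  withr::with_seed(3, {
    bl <- make_bilayer(n_p_per_leaflet = 32, bilayer_z = 2, jitter_sigma = 0.1)
    re <- split_leaflets(as.matrix(bl[, c("x", "y", "z")]))
    expect_equal(re$leaflet, bl$leaflet)
  })
  # flat single plane is not a bilayer
  expect_error(split_leaflets(cbind(1:6, 0, 0)), "no bilayer")
  expect_error(split_leaflets(cbind(1, 0, 0)), "at least 2")
})

test_that("surface distance follows the nearer-leaflet COM definition", {
  fr <- point_frame(pep_z = 3.0)
  expect_equal(as.numeric(peptide_surface_distance(fr)), 1.0)
  expect_equal(attr(peptide_surface_distance(fr), "leaflet"), "upper")
  # equidistant peptide ties to the upper leaflet
  fr0 <- point_frame(pep_z = 0)
  d0 <- peptide_surface_distance(fr0)
  expect_equal(as.numeric(d0), 2.0)
  expect_equal(attr(d0, "leaflet"), "upper")
  expect_error(
    peptide_surface_distance(point_frame(numeric(0))),
    "no peptide atoms"
  )
})

test_that("surface distance is invariant under xy translation", {
  spec <- synthetic_spec("FKRIVQRIKDFLRNLV", "I", n_frames = 1, seed = 9)
  fr <- traj_frames(generate_mode_trajectory(spec))[[1]]
  d0 <- as.numeric(peptide_surface_distance(fr))
  withr::with_seed(4, {
    for (i in 1:10) {
      sh <- fr
      dx <- runif(1, -5, 5); dy <- runif(1, -5, 5)
      sh$x <- sh$x + dx; sh$y <- sh$y + dy
      expect_equal(as.numeric(peptide_surface_distance(sh)), d0,
                   tolerance = 1e-9)
    }
  })
})

test_that("helix axis fitting and tilt behave on known geometries", {
  h <- build_ideal_helix("FKRIVQRIKDFLRNLV")
  axis <- fit_helix_axis(helimode:::.atom_xyz(h, "CA"))
  expect_gte(axis[3], 0.99) # built along +z, oriented N -> C
  # collinear points along x
  line <- cbind(seq(0, 4), 0, 0)
  expect_equal(fit_helix_axis(line), c(1, 0, 0), tolerance = 1e-9)
  expect_error(fit_helix_axis(line[1:4, ]), "at least 5")
  expect_equal(tilt_angle(c(0, 0, 1)), 0)
  expect_equal(tilt_angle(c(1, 0, 0)), 90)
  expect_equal(tilt_angle(c(1, 0, 1) / sqrt(2)), 45, tolerance = 1e-9)
  expect_error(tilt_angle(c(0, 0, 0)), "Zero")
})

test_that("tilt is symmetric under axis inversion", {
  withr::with_seed(12, {
    for (i in 1:25) {
      v <- rnorm(3)
      expect_equal(tilt_angle(v), tilt_angle(-v), tolerance = 1e-12)
    }
  })
})

test_that("insertion depths are signed against the nearer phosphate plane", {
  fr <- point_frame(pep_z = c(1.5, 2.5), p_upper_z = 2, p_lower_z = -2)
  d <- residue_insertion_depths(fr)
  expect_equal(d$depth, c(-0.5, 0.5))
  expect_equal(d$leaflet, c("upper", "upper"))
  # a peptide far above the membrane has all depths positive
  far <- point_frame(pep_z = c(5, 5.5, 6))
  expect_true(all(residue_insertion_depths(far)$depth > 0))
  # lower-leaflet insertion flips the sign convention
  low <- point_frame(pep_z = -1.6)
  expect_equal(residue_insertion_depths(low)$depth, -0.4)
})

test_that("exponential smoothing follows the recursion and stays bounded", {
  expect_equal(smooth_exponential(c(0, 1), 0.5), c(0, 0.5))
  x <- c(3, 7, 1, 9, 4)
  expect_equal(smooth_exponential(x, 1), x)
  expect_equal(smooth_exponential(rep(2, 10), 0.3), rep(2, 10))
  expect_error(smooth_exponential(x, 0), "alpha")
  expect_error(smooth_exponential(x, 1.5), "alpha")
  expect_error(smooth_exponential(numeric(0), 0.5), "Empty")
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- rnorm(50)
      a <- runif(1, 0.01, 1)
      y <- smooth_exponential(x, a)
      expect_gte(min(y), min(x) - 1e-12)
      expect_lte(max(y), max(x) + 1e-12)
    }
  })
})

test_that("generated trajectories recover generation parameters", {
  errs_tilt <- errs_dist <- errs_anchor <- c()
  for (s in 1:5) {
    spec <- example_mode_spec("I", seed = s, n_frames = 60)
    an <- pipeline_analyze(generate_mode_trajectory(spec), alpha = NULL)
    errs_tilt <- c(errs_tilt, abs(mean(an$traces$tilt$value) - spec$tilt_deg))
    errs_dist <- c(errs_dist,
                   abs(mean(an$traces$distance$value) - spec$com_height))
    spec3 <- example_mode_spec("III", seed = s, n_frames = 60)
    an3 <- pipeline_analyze(generate_mode_trajectory(spec3), alpha = NULL)
    errs_tilt <- c(errs_tilt, abs(mean(an3$traces$tilt$value) - spec3$tilt_deg))
    anchor <- an3$traces$depth[an3$traces$depth$residue %in%
                                 spec3$anchor_residues, ]
    md <- tapply(anchor$depth, anchor$residue, mean)
    errs_anchor <- c(errs_anchor, abs(md - (-spec3$anchor_depth)))
  }
  expect_lt(max(errs_tilt), 5)
  expect_lt(max(errs_dist), 0.1)
  expect_lt(max(errs_anchor), 0.1)
})
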