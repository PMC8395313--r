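test_that("ideal helix geometry matches canonical alpha-helix parameters", {
  h <- build_ideal_helix("FKRIVQRIKDFLRNLV")
  CA <- helimode:::.atom_xyz(h, "CA")
  expect_equal(nrow(CA), 16)
  d <- sqrt(rowSums(diff(CA)^2)) * 10
  expect_true(all(abs(d - 3.8) < 0.1)) # consecutive CA-CA distance
  # twist about the fitted axis ~ 100 degrees per residue (right-handed)
  az <- atan2(CA[, 2], CA[, 1]) * 180 / pi
  tw <- (diff(az)) %% 360
  expect_equal(mean(pmin(tw, 360 - tw)), 100, tolerance = 3)
  # rise per residue ~ 1.5 Angstrom along the axis
  expect_equal(mean(diff(CA[, 3])) * 10, 1.5, tolerance = 0.1)
  expect_error(build_ideal_helix("AKL"), "at least 4")
})

test_that("built helices are recognized by the structure assignment", {
  # the key generator <-> assignment integration: every panel sequence
  for (s in table1_peptides()$sequence) {
    expect_gte(helicity_fraction(assign_helix(build_ideal_helix(s))), 0.85)
  }
})

test_that("segment randomization is seeded, local, and identity on empty", {
  h <- build_ideal_helix("VNWKKILGKIIKVVK")
  expect_identical(randomize_segment(h, 5, 4, seed = 1), h) # empty interval
  r1 <- randomize_segment(h, 8, 15, seed = 42)
  r2 <- randomize_segment(h, 8, 15, seed = 42)
  expect_equal(r1, r2)
  r3 <- randomize_segment(h, 8, 15, seed = 43)
  expect_false(isTRUE(all.equal(r1$z, r3$z)))
  # untouched prefix is restored exactly
  pre <- function(fr) {
    as.matrix(fr[fr$residue <= 7 & fr$atom %in% c("N", "CA", "C"),
                 c("x", "y", "z")])
  }
  expect_equal(pre(r1), pre(h), tolerance = 1e-9)
  # full randomization destroys helicity
  full <- randomize_segment(h, 1, 15, seed = 7)
  expect_lt(helicity_fraction(assign_helix(full)), 0.2)
  expect_error(randomize_segment(h, 0, 5, seed = 1), "out of bounds")
})

test_that("bilayer generation round-trips through leaflet splitting", {
  b0 <- make_bilayer(n_p_per_leaflet = 16, jitter_sigma = 0, seed = 1)
  expect_equal(unique(abs(b0$z)), 2) # exact planes without jitter
  b <- make_bilayer(n_p_per_leaflet = 36, jitter_sigma = 0.1, seed = 2)
  re <- split_leaflets(as.matrix(b[, c("x", "y", "z")]))
  expect_equal(re$leaflet, b$leaflet)
  expect_error(make_bilayer(n_p_per_leaflet = 1), ">= 4")
})

test_that("spec validation catches inconsistent requests", {
  expect_error(synthetic_spec("AKLVAKLV", "IV"), "mode")
  expect_error(synthetic_spec("AKLVAKLV", "II"), "disorder_range")
  expect_error(synthetic_spec("AKLVAKLV", "II", disorder_range = c(1, 20)),
               "within")
  expect_error(synthetic_spec("AKLVAKLV", "I", n_frames = 0), "n_frames")
  spec <- synthetic_spec("AKLVAKLV", "II", disorder_range = c(1, 4))
  expect_equal(spec$anchor_residues, 3L) # Leu3: most hydrophobic in range
  expect_equal(spec$tilt_deg, 90)
})

test_that("mode-conditioned trajectories satisfy their construction", {
  # unbound stays far from the membrane by construction
  un <- generate_mode_trajectory(example_mode_spec("unbound", seed = 4,
                                                   n_frames = 30))
  dtr <- distance_trace(un)
  expect_gte(mean(dtr$value), 3)
  # mode III: tilt stays upright while the azimuth swings widely
  tr3 <- generate_mode_trajectory(example_mode_spec("III", seed = 4,
                                                    n_frames = 60))
  tt <- tilt_trace(tr3)
  expect_true(all(tt$value < 45))
  az_range <- diff(range(tt$azimuth))
  expect_gt(az_range, 90)
  # mode II helicity sits in the partially-helical band
  tr2 <- generate_mode_trajectory(example_mode_spec("II", seed = 4,
                                                    n_frames = 30))
  ht <- helicity_trace(tr2)
  expect_gte(mean(ht$value), 0.2)
  expect_lte(mean(ht$value), 0.6)
  # bound trajectories hug the surface
  tr1 <- generate_mode_trajectory(example_mode_spec("I", seed = 4,
                                                    n_frames = 30))
  expect_true(all(distance_trace(tr1)$value < 1))
})

test_that("identical specs generate byte-identical trajectory files", {
  spec <- example_mode_spec("II", seed = 19, n_frames = 8)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_structures(generate_mode_trajectory(spec), f1)
  write_structures(generate_mode_trajectory(spec), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("PDB round-trip preserves coordinates to 1e-3 Angstrom", {
  spec <- example_mode_spec("III", seed = 6, n_frames = 5)
  traj <- generate_mode_trajectory(spec)
  f <- tempfile(fileext = ".pdb")
  write_structures(traj, f)
  rt <- read_structures(f, timestep = spec$timestep)
  expect_equal(length(unique(rt$frame)), 5)
  orig <- as.matrix(traj[, c("x", "y", "z")])
  back <- as.matrix(rt[, c("x", "y", "z")])
  expect_equal(dim(orig), dim(back))
  expect_lt(max(abs(orig - back)) * 10, 1e-3)
  # leaflets are relabelled on read
  expect_equal(sort(unique(rt$leaflet[rt$part == "lipidP"])),
               c("lower", "upper"))
  unlink(f)
})

test_that("the written dialect agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  spec <- example_mode_spec("I", seed = 8, n_frames = 3)
  traj <- generate_mode_trajectory(spec)
  f <- tempfile(fileext = ".pdb")
  write_structures(traj, f)
  pdb <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(pdb$xyz), 3)
  fr1 <- read_structures(f)[read_structures(f)$frame == 1, ]
  ref <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_lt(max(abs(ref - as.matrix(fr1[, c("x", "y", "z")]) * 10)), 1e-6)
  unlink(f)
})

test_that("the PDB reader rejects malformed input with line numbers", {
  f <- tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_structures(f), "empty")
  writeLines(c("MODEL        1", "ENDMDL", "END"), f)
  expect_error(read_structures(f), "no ATOM")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000",
    "ENDMDL"
  ), f)
  expect_error(read_structures(f), "line 2")
  # single MODEL gives a one-frame trajectory
  spec <- synthetic_spec("AKLVAKLV", "I", n_frames = 1, seed = 1)
  write_structures(generate_mode_trajectory(spec), f)
  expect_equal(unique(read_structures(f)$frame), 1L)
  unlink(f)
})
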