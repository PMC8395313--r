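# Geometric trajectory metrics against a flat bilayer whose normal is the
# z axis: leaflet assignment, peptide-surface distance, helix tilt,
# per-residue insertion depth, exponential smoothing.

#' Assign phosphorus atoms to leaflets
#'
#' Partitions phosphorus coordinates into upper and lower leaflets by sign
#' relative to the median z of all P atoms (ties go to the lower leaflet).
#' Rejects one-sided input: if every P atom lies within 0.5 nm of the
#' median there is no bilayer to split.
#'
#' @param p_atoms A data frame with `x`, `y`, `z` columns (nm) or an n x 3
#'   matrix of P coordinates.
#' @param composition Optional composition label carried on the result.
#' @return A bilayer tibble (`part == "lipidP"`, `leaflet` in
#'   upper/lower) with `composition` and `normal` attributes.
#' @export
split_leaflets <- function(p_atoms, composition = NULL) {
  if (is.matrix(p_atoms)) {
    p_atoms <- tibble(x = p_atoms[, 1], y = p_atoms[, 2], z = p_atoms[, 3])
  }
  if (nrow(p_atoms) < 2) abort("Need at least 2 phosphorus atoms.")
  med <- stats::median(p_atoms$z)
  if (all(abs(p_atoms$z - med) < 0.5)) {
    abort("All phosphorus atoms lie within 0.5 nm of the median z: no bilayer.")
  }
  out <- tibble(
    residue = seq_len(nrow(p_atoms)),
    resname = "LIP", aa = NA_character_, atom = "P",
    x = p_atoms$x, y = p_atoms$y, z = p_atoms$z,
    part = "lipidP",
    leaflet = ifelse(p_atoms$z > med, "upper", "lower")
  )
  attr(out, "composition") <- composition %||% attr(p_atoms, "composition")
  attr(out, "normal") <- c(0, 0, 1)
  out
}

# z of the phosphorus centre of mass for one leaflet
.leaflet_z <- function(bilayer, which) {
  z <- bilayer$z[bilayer$leaflet == which]
  if (length(z) == 0) abort(sprintf("Leaflet '%s' is empty.", which))
  mean(z)
}

# bilayer rows from a frame, splitting leaflets if unlabelled
.frame_bilayer <- function(frame) {
  lip <- .lipid_part(frame)
  if (nrow(lip) == 0) abort("Frame has no phosphorus atoms: no bilayer.")
  if (any(is.na(lip$leaflet))) lip <- split_leaflets(lip)
  lip
}

# mass-weighted z centre of mass of the peptide part
.peptide_com_z <- function(frame, include_h = TRUE) {
  pep <- .peptide_part(frame)
  if (nrow(pep) == 0) abort("Frame has no peptide atoms.")
  if (!include_h) pep <- pep[pep$atom != "H", , drop = FALSE]
  m <- .atom_mass(pep$atom, pep$aa)
  sum(pep$z * m) / sum(m)
}

#' Peptide distance from the bilayer surface
#'
#' Absolute difference between the z coordinate of the peptide's
#' mass-weighted centre of mass and the z of the phosphorus centre of mass
#' of the nearer leaflet (nearer by this same absolute difference; ties go
#' to the upper leaflet).
#'
#' @param frame A frame tibble containing peptide atoms.
#' @param bilayer A bilayer tibble (defaults to the phosphorus atoms carried
#'   in `frame`).
#' @param include_h Include amide hydrogens (if present) in the centre of
#'   mass.
#' @return Distance in nm with attributes `leaflet` (which leaflet was
#'   nearer) and `signed` (positive above/outside the nearer plane).
#' @export
peptide_surface_distance <- function(frame, bilayer = NULL, include_h = TRUE) {
  bilayer <- bilayer %||% .frame_bilayer(frame)
  zc <- .peptide_com_z(frame, include_h = include_h)
  zu <- .leaflet_z(bilayer, "upper")
  zl <- .leaflet_z(bilayer, "lower")
  du <- abs(zc - zu); dl <- abs(zc - zl)
  if (du <= dl) {
    out <- du
    attr(out, "leaflet") <- "upper"
    attr(out, "signed") <- zc - zu
  } else {
    out <- dl
    attr(out, "leaflet") <- "lower"
    attr(out, "signed") <- zl - zc
  }
  out
}

#' Fit the helix axis of a CA segment
#'
#' Principal axis (largest-variance direction) of at least five ordered CA
#' positions, oriented from the N- to the C-terminal end, unit norm.
#'
#' @param ca_coords n x 3 matrix (or data frame with x/y/z) of ordered CA
#'   coordinates.
#' @return Unit 3-vector.
#' @export
fit_helix_axis <- function(ca_coords) {
  if (is.data.frame(ca_coords)) {
    ca_coords <- as.matrix(ca_coords[, c("x", "y", "z")])
  }
  if (nrow(ca_coords) < 5) abort("Need at least 5 CA positions.")
  axis <- .principal_axis(ca_coords)
  nc <- ca_coords[nrow(ca_coords), ] - ca_coords[1, ]
  if (sum(axis * nc) < 0) axis <- -axis
  .unit(axis)
}

#' Helix tilt relative to the membrane normal
#'
#' Angle between the helix axis and the z membrane normal, folded to
#' [0, 90] degrees: 0 deg is an upright helix perpendicular to the surface
#' (antenna-like), 90 deg lies parallel to the surface (carpet-like). The
#' fold makes the tilt invariant to the sign of the axis.
#'
#' @param axis Unit 3-vector.
#' @return Tilt in degrees.
#' @export
tilt_angle <- function(axis) {
  n <- .vnorm(axis)
  if (n < 1e-12) abort("Zero axis vector.")
  acos(min(abs(axis[3] / n), 1)) * 180 / pi
}

#' Per-residue insertion depth
#'
#' Signed z difference between each residue's side-chain centroid (the SC
#' pseudo-atom, or CA for glycine / when SC is absent) and the phosphorus
#' centre-of-mass plane of the nearer leaflet. Negative values lie below
#' the phosphate plane, i.e. inserted toward the membrane interior.
#'
#' @inheritParams peptide_surface_distance
#' @return Tibble with columns `residue`, `aa`, `depth` (nm), `leaflet`.
#' @export
residue_insertion_depths <- function(frame, bilayer = NULL) {
  bilayer <- bilayer %||% .frame_bilayer(frame)
  pep <- .peptide_part(frame)
  if (nrow(pep) == 0) abort("Frame has no peptide atoms.")
  zu <- .leaflet_z(bilayer, "upper")
  zl <- .leaflet_z(bilayer, "lower")
  res <- sort(unique(pep$residue))
  sc <- match(paste0(res, ".SC"), paste0(pep$residue, ".", pep$atom))
  ca <- match(paste0(res, ".CA"), paste0(pep$residue, ".", pep$atom))
  pick <- ifelse(is.na(sc), ca, sc)
  z <- pep$z[pick]
  upper <- abs(z - zu) <= abs(z - zl)
  tibble(
    residue = res,
    aa = pep$aa[pick],
    depth = ifelse(upper, z - zu, zl - z),
    leaflet = ifelse(upper, "upper", "lower")
  )
}

#' Exponential smoothing
#'
#' First-order exponential average: `y[1] = x[1]`,
#' `y[t] = alpha * x[t] + (1 - alpha) * y[t-1]`. `alpha = 1` is the
#' identity; smaller values smooth more. Output stays within
#' `[min(x), max(x)]`.
#'
#' @param x Numeric series.
#' @param alpha Weight in (0, 1].
#' @return Smoothed numeric series, same length.
#' @export
smooth_exponential <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    abort("`alpha` must be in (0, 1].")
  }
  if (length(x) == 0) abort("Empty series.")
  y <- numeric(length(x))
  y[1] <- x[1]
  if (length(x) > 1) {
    for (t in 2:length(x)) y[t] <- alpha * x[t] + (1 - alpha) * y[t - 1]
  }
  y
}

# per-frame helical CA matrix used for tilt: H-labelled residues (expanded
# by one residue on each side, since the assignment labels geometrically
# helical termini as coil) when at least 5, else all CAs
.tilt_of_frame <- function(frame, labels = NULL) {
  labels <- labels %||% assign_helix(frame)
  CA <- .atom_xyz(frame, "CA")
  hel <- which(labels == "H")
  if (length(hel) > 0) {
    hel <- sort(unique(pmin(pmax(c(hel - 1L, hel, hel + 1L), 1L),
                            length(labels))))
  }
  use <- if (length(hel) >= 5) CA[hel, , drop = FALSE] else CA
  axis <- fit_helix_axis(use)
  c(tilt = tilt_angle(axis),
    azimuth = (atan2(axis[2], axis[1]) * 180 / pi) %% 360)
}

#' Distance, tilt, and depth traces of a trajectory
#'
#' Per-frame trajectory metrics as tidy traces. `distance_trace()` follows
#' [peptide_surface_distance()]; `tilt_trace()` fits the helix axis on the
#' alpha-helical residues of each frame (all CAs when fewer than five are
#' helical) and reports tilt and in-plane azimuth; `depth_trace()` returns
#' the long per-residue [residue_insertion_depths()] table.
#'
#' @inheritParams helicity_trace
#' @param include_h Include hydrogens in the peptide centre of mass.
#' @return `distance_trace()` and `tilt_trace()` return `"pep_trace"`
#'   tibbles (`tilt_trace()` adds an `azimuth` column); `depth_trace()` a
#'   tibble with `frame`, `time`, `residue`, `aa`, `depth`, `leaflet`.
#' @export
distance_trace <- function(traj, alpha = NULL, include_h = TRUE) {
  frames <- traj_frames(traj)
  values <- vapply(frames, function(fr) {
    as.numeric(peptide_surface_distance(fr, include_h = include_h))
  }, numeric(1))
  .new_trace(frames, values, metric = "surface_distance", units = "nm",
             alpha = alpha)
}

#' @rdname distance_trace
#' @export
tilt_trace <- function(traj, alpha = NULL) {
  frames <- traj_frames(traj)
  ta <- t(vapply(frames, .tilt_of_frame, numeric(2)))
  .new_trace(frames, ta[, "tilt"], metric = "tilt", units = "degrees",
             alpha = alpha, extra = tibble(azimuth = ta[, "azimuth"]))
}

#' @rdname distance_trace
#' @export
depth_trace <- function(traj) {
  frames <- traj_frames(traj)
  purrr::imap_dfr(frames, function(fr, i) {
    d <- residue_insertion_depths(fr)
    dplyr::bind_cols(
      tibble(frame = i, time = attr(fr, "time") %||% NA_real_, .rows = nrow(d)),
      d
    )
  })
}

#' @rdname distance_trace
#' @export
com_height_trace <- function(traj, include_h = TRUE) {
  frames <- traj_frames(traj)
  values <- vapply(frames, function(fr) {
    attr(peptide_surface_distance(fr, include_h = include_h), "signed")
  }, numeric(1))
  .new_trace(frames, values, metric = "com_height", units = "nm")
}
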