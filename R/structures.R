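# Frame / trajectory representation
#
# A *frame* is a tibble of atoms at one time point with columns:
#   residue (int), resname (3-letter), aa (1-letter or NA), atom
#   (N/CA/C/O/H/SC/P), x, y, z (nm), part ("peptide" or "lipidP"),
#   leaflet ("upper"/"lower"/NA)
# and an attribute `time` (ps). A *trajectory* is the same shape with
# additional `frame` and `time` columns and attributes `timestep` (ps) and
# optionally `ground_truth` (the generating spec).

# average side-chain masses (residue mass minus the 56.04 backbone share)
.sc_mass <- c(
  A = 15.04, R = 100.15, N = 58.06, D = 59.05, C = 47.10,
  Q = 72.09, E = 73.08, G = 1.01, H = 81.10, I = 57.12,
  L = 57.12, K = 72.13, M = 75.15, F = 91.14, P = 41.08,
  S = 31.04, T = 45.06, W = 130.17, Y = 107.14, V = 43.09
)

# approximate CA -> side-chain-centroid distances (Angstrom)
.sc_radius <- c(
  A = 1.5, R = 4.1, N = 2.5, D = 2.5, C = 2.1,
  Q = 3.1, E = 3.1, G = 0.0, H = 3.1, I = 2.3,
  L = 2.6, K = 3.5, M = 2.9, F = 3.4, P = 1.9,
  S = 1.9, T = 1.9, W = 3.9, Y = 3.8, V = 2.0
)

.atom_masses <- c(N = 14.007, C = 12.011, O = 15.999, H = 1.008, P = 30.974)

# mass of one atom row; SC pseudo-atoms carry the whole side-chain mass
.atom_mass <- function(atom, aa) {
  ifelse(
    atom == "SC", unname(.sc_mass[aa]),
    ifelse(atom %in% c("CA", "C"), .atom_masses[["C"]],
           unname(.atom_masses[atom]))
  )
}

.peptide_part <- function(frame) frame[frame$part == "peptide", , drop = FALSE]

.lipid_part <- function(frame) frame[frame$part == "lipidP", , drop = FALSE]

# matrix of coordinates for one atom type over residues (ordered)
.atom_xyz <- function(frame, name) {
  rows <- frame[frame$part == "peptide" & frame$atom == name, , drop = FALSE]
  rows <- rows[order(rows$residue), , drop = FALSE]
  m <- as.matrix(rows[, c("x", "y", "z")])
  rownames(m) <- rows$residue
  m
}

.n_residues <- function(frame) {
  length(unique(frame$residue[frame$part == "peptide"]))
}

#' Split a trajectory into frames
#'
#' @param traj A trajectory tibble (from [generate_mode_trajectory()] or
#'   [read_structures()]).
#' @return A list of frame tibbles, each carrying a `time` attribute.
#' @export
traj_frames <- function(traj) {
  if (!is.data.frame(traj) || nrow(traj) == 0L) abort("Empty trajectory.")
  keep <- setdiff(names(traj), c("frame", "time"))
  idx <- unname(split(seq_len(nrow(traj)), traj$frame))
  lapply(idx, function(i) {
    out <- traj[i, keep, drop = FALSE]
    attr(out, "time") <- traj$time[i[1]]
    out
  })
}

# evaluate `code` under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ---- backbone construction from internal coordinates --------------------

# canonical backbone geometry (Angstrom / degrees)
.bb_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

# build N/CA/C/O arrays (L x 3, Angstrom) from phi/psi torsions (degrees);
# psi of the last residue only orients its carbonyl oxygen
.build_backbone <- function(phi, psi, omega = 180) {
  L <- length(phi)
  stopifnot(length(psi) == L, L >= 2)
  g <- .bb_geom
  N <- CA <- C <- O <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, psi[i])
    CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca, g$a_c_n_ca, omega)
    C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c, g$a_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(L)) {
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# extract phi/psi torsions (degrees) from a frame's backbone
.extract_torsions <- function(frame) {
  N <- .atom_xyz(frame, "N"); CA <- .atom_xyz(frame, "CA")
  C <- .atom_xyz(frame, "C"); O <- .atom_xyz(frame, "O")
  L <- nrow(N)
  phi <- psi <- numeric(L)
  phi[1] <- -57 # undefined for residue 1; value is inert (first placement)
  for (i in 2:L) phi[i] <- .dihedral(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
  for (i in seq_len(L - 1)) psi[i] <- .dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
  psiL <- .dihedral(N[L, ], CA[L, ], C[L, ], O[L, ]) - 180
  psi[L] <- ((psiL + 180) %% 360) - 180
  list(phi = phi, psi = psi)
}

# assemble a peptide frame tibble (nm) from backbone arrays (Angstrom)
.backbone_frame <- function(p, bb, time = 0) {
  L <- length(p$residues)
  aa <- p$residues
  # side-chain pseudo-atoms along the N->CA / C->CA bisector
  u <- (bb$CA - bb$N) + (bb$CA - bb$C)
  u <- u / sqrt(rowSums(u^2))
  SC <- bb$CA + u * .sc_radius[aa]
  has_sc <- aa != "G"
  per_res <- 4L + has_sc
  res_idx <- rep(seq_len(L), per_res)
  atom <- unlist(lapply(seq_len(L), function(i) {
    if (has_sc[i]) c("N", "CA", "C", "O", "SC") else c("N", "CA", "C", "O")
  }), use.names = FALSE)
  xyz <- matrix(NA_real_, length(res_idx), 3)
  for (nm in c("N", "CA", "C", "O")) {
    xyz[atom == nm, ] <- get(nm, list(N = bb$N, CA = bb$CA, C = bb$C, O = bb$O))
  }
  xyz[atom == "SC", ] <- SC[has_sc, , drop = FALSE]
  out <- tibble(
    residue = res_idx, resname = unname(.aa3[aa[res_idx]]), aa = aa[res_idx],
    atom = atom,
    x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10,
    part = "peptide", leaflet = NA_character_
  )
  attr(out, "time") <- time
  out
}

#' Build an ideal alpha-helix for a peptide
#'
#' Constructs a full backbone (N, CA, C, O) with canonical alpha-helical
#' torsions (phi = -57 deg, psi = -47 deg; about 1.5 Angstrom rise and 100
#' deg twist per residue) by forward kinematics from standard bond geometry,
#' adds one side-chain pseudo-atom per non-Gly residue at an approximate
#' centroid distance from CA, aligns the helix axis with +z (N-terminus at
#' the bottom), and centres the centre of mass at the origin.
#'
#' @inheritParams net_charge
#' @return A frame tibble (see package overview) in nm, `time` attribute 0.
#' @examples
#' helix <- build_ideal_helix("FKRIVQRIKDFLRNLV")
#' @export
build_ideal_helix <- function(p) {
  p <- .as_peptide(p)
  L <- length(p$residues)
  if (L < 4) abort("Need at least 4 residues to build a helix.")
  bb <- .build_backbone(rep(-57, L), rep(-47, L))
  frame <- .backbone_frame(p, bb)
  # align the CA principal axis with +z, oriented N -> C
  CA <- .atom_xyz(frame, "CA")
  axis <- .principal_axis(CA)
  if (sum(axis * (CA[L, ] - CA[1, ])) < 0) axis <- -axis
  R <- .rot_between(axis, c(0, 0, 1))
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(R)
  m <- .atom_mass(frame$atom, frame$aa)
  com <- colSums(xyz * m) / sum(m)
  xyz <- sweep(xyz, 2, com)
  frame$x <- xyz[, 1]; frame$y <- xyz[, 2]; frame$z <- xyz[, 3]
  frame
}

#' Randomize backbone torsions in a residue interval
#'
#' Resamples phi/psi of the given residues uniformly from extended
#' coil-region ranges (phi in [-160, -70], psi in [100, 180] degrees),
#' rebuilds the chain by forward kinematics with canonical bond geometry,
#' and rigidly superposes the untouched residues back onto their original
#' coordinates (exactly when at least two residues lie outside the
#' interval). Seeded and deterministic. Intended for frames built by this
#' package; a read-in frame with non-canonical bond geometry is regularized
#' to canonical geometry by the rebuild.
#'
#' @param frame A peptide frame tibble.
#' @param start,end 1-based inclusive residue interval. An empty interval
#'   (`start > end`) returns the frame unchanged.
#' @param seed Integer seed.
#' @return A frame tibble of the same shape.
#' @export
randomize_segment <- function(frame, start, end, seed = 1L) {
  pep <- .peptide_part(frame)
  L <- .n_residues(frame)
  if (start > end) return(frame)
  if (start < 1 || end > L) {
    abort(sprintf("Interval %d-%d is out of bounds (1-%d).", start, end, L))
  }
  tor <- .extract_torsions(frame)
  idx <- start:end
  .with_seed(seed, {
    tor$phi[idx] <- runif(length(idx), -160, -70)
    tor$psi[idx] <- runif(length(idx), 100, 180)
  })
  aa_by_res <- pep$aa[match(seq_len(L), pep$residue)]
  p <- parse_peptide(paste(aa_by_res, collapse = ""), id = "rebuilt")
  bb <- .build_backbone(tor$phi, tor$psi)
  new_frame <- .backbone_frame(p, bb, time = attr(frame, "time") %||% 0)
  keep <- setdiff(seq_len(L), idx)
  if (length(keep) >= 2) {
    sel <- function(fr) {
      rows <- fr[fr$part == "peptide" & fr$residue %in% keep &
                   fr$atom %in% c("N", "CA", "C"), , drop = FALSE]
      rows <- rows[order(rows$residue, match(rows$atom, c("N", "CA", "C"))), ]
      as.matrix(rows[, c("x", "y", "z")])
    }
    fit <- .kabsch(sel(new_frame), sel(frame))
    xyz <- .apply_rigid(as.matrix(new_frame[, c("x", "y", "z")]), fit$R, fit$t)
    new_frame$x <- xyz[, 1]; new_frame$y <- xyz[, 2]; new_frame$z <- xyz[, 3]
  }
  new_frame
}
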