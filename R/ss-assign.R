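# Alpha-helix assignment from coordinates via the Kabsch-Sander
# hydrogen-bond criterion, reduced to the {H, T, C} alphabet.

#' Reconstruct backbone amide hydrogens
#'
#' Places the amide H of each residue i >= 2 at 1.0 Angstrom from N along
#' the unit vector opposite the previous residue's C -> O direction (the
#' standard DSSP reconstruction). Residue 1 and prolines get no H. Existing
#' H rows are replaced by the reconstructed positions, which makes the
#' operation deterministic across input sources and idempotent on its own
#' output.
#'
#' @param frame A peptide frame tibble with complete N/CA/C/O backbone.
#' @return The frame with `H` atom rows for every eligible residue.
#' @export
reconstruct_amide_hydrogen <- function(frame) {
  pep <- .peptide_part(frame)
  L <- .n_residues(frame)
  if (L < 2) abort("Need at least 2 residues.")
  bb <- pep$atom %in% c("N", "CA", "C", "O")
  counts <- table(factor(pep$residue[bb], levels = seq_len(L)))
  if (any(counts < 4)) {
    i <- which(counts < 4)[1]
    have <- pep$atom[pep$residue == i]
    miss <- setdiff(c("N", "CA", "C", "O"), have)
    abort(sprintf("Residue %d is missing backbone atom(s): %s.",
                  i, paste(miss, collapse = ", ")))
  }
  N <- .atom_xyz(frame, "N")
  C <- .atom_xyz(frame, "C")
  O <- .atom_xyz(frame, "O")
  aa_by_res <- pep$aa[match(seq_len(L), pep$residue)]
  u <- C[-L, , drop = FALSE] - O[-L, , drop = FALSE]
  u <- u / sqrt(rowSums(u^2))
  H <- N[-1, , drop = FALSE] + 0.1 * u # 1.0 Angstrom in nm
  donors <- which(aa_by_res[-1] != "P") # row index into H; residue = +1
  out <- frame[!(frame$part == "peptide" & frame$atom == "H"), , drop = FALSE]
  hrows <- tibble(
    residue = donors + 1L,
    resname = unname(.aa3[aa_by_res[donors + 1L]]),
    aa = aa_by_res[donors + 1L],
    atom = "H",
    x = H[donors, 1], y = H[donors, 2], z = H[donors, 3],
    part = "peptide", leaflet = NA_character_
  )
  res <- dplyr::bind_rows(out, hrows)
  res <- res[order(res$part != "peptide", res$residue,
                   match(res$atom, c("N", "H", "CA", "C", "O", "SC", "P"))), ]
  attr(res, "time") <- attr(frame, "time")
  res
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of a candidate N-H...O=C hydrogen bond,
#' \deqn{E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' with distances in Angstrom and E in kcal/mol. Inputs are in nm (the
#' package-wide unit) and are converted at this boundary. A bond is called
#' when E < -0.5 kcal/mol. Distances below 0.5 Angstrom signal malformed
#' geometry and are rejected.
#'
#' @param c_pos,o_pos Carbonyl C and O coordinates (nm) of the acceptor.
#' @param n_pos,h_pos Amide N and H coordinates (nm) of the donor.
#' @return Energy in kcal/mol.
#' @examples
#' # ~ -4.24 kcal/mol for textbook helical geometry
#' @export
hbond_energy <- function(c_pos, o_pos, n_pos, h_pos) {
  pts <- rbind(c_pos, o_pos, n_pos, h_pos)
  if (!all(is.finite(pts))) abort("Coordinates must be finite.")
  r_on <- .vnorm(o_pos - n_pos) * 10
  r_ch <- .vnorm(c_pos - h_pos) * 10
  r_oh <- .vnorm(o_pos - h_pos) * 10
  r_cn <- .vnorm(c_pos - n_pos) * 10
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) {
    abort("Atoms closer than 0.5 Angstrom: malformed geometry.")
  }
  0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

.hbond_cutoff <- -0.5

#' Assign per-residue secondary structure
#'
#' Reduced Kabsch-Sander assignment: an i -> i+4 turn exists when the amide
#' H of residue i+4 is hydrogen-bonded (energy < -0.5 kcal/mol) to the
#' carbonyl of residue i; a residue is alpha-helical (`"H"`) when it lies in
#' two consecutive such turns, in a turn but not a helix it is `"T"`, and
#' otherwise coil `"C"`. Amide hydrogens are reconstructed from geometry
#' first. The first and last residues are always coil. 3_10/pi helices and
#' strands are not distinguished; only the alpha pattern is counted.
#'
#' @param frame A peptide frame tibble.
#' @return Character vector of per-residue labels in `{H, T, C}`.
#' @export
assign_helix <- function(frame) {
  L <- .n_residues(frame)
  if (L < 3) abort("Need at least 3 residues.")
  frame <- reconstruct_amide_hydrogen(frame)
  pep <- .peptide_part(frame)
  N <- .atom_xyz(frame, "N")
  C <- .atom_xyz(frame, "C")
  O <- .atom_xyz(frame, "O")
  Hrows <- pep[pep$atom == "H", , drop = FALSE]
  hmap <- setNames(seq_len(nrow(Hrows)), Hrows$residue)
  Hxyz <- as.matrix(Hrows[, c("x", "y", "z")])
  turn4 <- rep(FALSE, L)
  if (L >= 5) {
    acc <- seq_len(L - 4)
    don <- acc + 4L
    k <- hmap[as.character(don)]
    ok <- !is.na(k) # proline: no donor H
    if (any(ok)) {
      ai <- acc[ok]; di <- don[ok]; hi <- k[ok]
      dist <- function(A, B) sqrt(rowSums((A - B)^2)) * 10
      r_on <- dist(O[ai, , drop = FALSE], N[di, , drop = FALSE])
      r_ch <- dist(C[ai, , drop = FALSE], Hxyz[hi, , drop = FALSE])
      r_oh <- dist(O[ai, , drop = FALSE], Hxyz[hi, , drop = FALSE])
      r_cn <- dist(C[ai, , drop = FALSE], N[di, , drop = FALSE])
      if (min(r_on, r_ch, r_oh, r_cn) < 0.5) {
        abort("Atoms closer than 0.5 Angstrom: malformed geometry.")
      }
      e <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      turn4[ai] <- e < .hbond_cutoff
    }
  }
  labels <- rep("C", L)
  if (L >= 6) {
    for (i in 2:(L - 4)) {
      if (turn4[i - 1] && turn4[i]) labels[i:(i + 3)] <- "H"
    }
  }
  for (i in which(turn4)) {
    idx <- (i + 1):(i + 3)
    labels[idx][labels[idx] == "C"] <- "T"
  }
  labels[1] <- "C"; labels[L] <- "C"
  labels[labels == "H" & seq_len(L) %in% c(1L, L)] <- "C"
  labels
}

#' Helicity fraction of a label string
#'
#' Number of alpha-helical residues divided by the residue count minus the
#' two terminal residues (which the assignment inherently treats as coil),
#' clipped to [0, 1].
#'
#' @param labels Character vector of labels from [assign_helix()].
#' @return Helicity fraction in [0, 1].
#' @export
helicity_fraction <- function(labels) {
  L <- length(labels)
  if (L < 3) abort("Need at least 3 residues.")
  min(max(sum(labels == "H") / (L - 2), 0), 1)
}

#' Helicity over a trajectory
#'
#' Per-frame helicity fraction, optionally exponentially smoothed.
#'
#' @param traj Trajectory tibble.
#' @param alpha Optional smoothing weight in (0, 1] (see
#'   [smooth_exponential()]); `NULL` skips smoothing.
#' @return A trace tibble (class `"pep_trace"`) with columns `frame`,
#'   `time`, `value` and, when smoothed, `smoothed`.
#' @export
helicity_trace <- function(traj, alpha = NULL) {
  frames <- traj_frames(traj)
  values <- unname(purrr::imap_dbl(frames, function(fr, i) {
    tryCatch(
      helicity_fraction(assign_helix(fr)),
      error = function(e) abort(sprintf("Frame %d: %s", i, conditionMessage(e)))
    )
  }))
  .new_trace(frames, values, metric = "helicity", units = "fraction",
             alpha = alpha)
}

# shared trace assembly
.new_trace <- function(frames, values, metric, units, alpha = NULL,
                       extra = NULL) {
  out <- tibble(
    frame = seq_along(frames),
    time = vapply(frames, function(f) attr(f, "time") %||% NA_real_, numeric(1)),
    value = values
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  if (!is.null(alpha)) out$smoothed <- smooth_exponential(values, alpha)
  class(out) <- c("pep_trace", class(out))
  attr(out, "metric") <- metric
  attr(out, "units") <- units
  attr(out, "alpha") <- alpha
  out
}
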