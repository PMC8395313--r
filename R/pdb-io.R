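# Multi-model PDB input/output. One MODEL per frame, Angstrom on disk
# (converted to nm in memory), peptide as ATOM records on chain A, bilayer
# phosphorus as HETATM records named P on chain L. The writer emits the
# fixed-width PDB 3.3 column layout so identical trajectories produce
# byte-identical files.

.pdb_element <- c(N = "N", CA = "C", C = "C", O = "O", H = "H",
                  SC = "C", P = "P")

.pdb_atom_name <- function(atom) {
  # left-justified from column 14 for 1-3 character names
  vapply(atom, function(a) sprintf(" %-3s", a), character(1))
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj Trajectory tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structures <- function(traj, path) {
  frames <- traj_frames(traj)
  con <- file(path, open = "wb") # binary mode: fixed "\n", stable bytes
  on.exit(close(con))
  out <- character(0)
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    out <- c(out, sprintf("MODEL     %4d", fi))
    serial <- 0L
    pep <- .peptide_part(fr)
    pep <- pep[order(pep$residue,
                     match(pep$atom, c("N", "H", "CA", "C", "O", "SC"))), ]
    for (k in seq_len(nrow(pep))) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        "ATOM", serial, .pdb_atom_name(pep$atom[k]), " ",
        pep$resname[k], "A", pep$residue[k], " ",
        pep$x[k] * 10, pep$y[k] * 10, pep$z[k] * 10, 1, 0,
        .pdb_element[[pep$atom[k]]]
      ))
    }
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      %-3s %1s%4d",
                          serial, pep$resname[nrow(pep)], "A",
                          pep$residue[nrow(pep)]))
    lip <- .lipid_part(fr)
    for (k in seq_len(nrow(lip))) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        "HETATM", serial, " P  ", " ", "LIP", "L", lip$residue[k], " ",
        lip$x[k] * 10, lip$y[k] * 10, lip$z[k] * 10, 1, 0, " P"
      ))
    }
    out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Parses the dialect written by [write_structures()] (and plain
#' single-model PDB backbones): MODEL/ENDMDL per frame, ATOM records for
#' the peptide, HETATM records named `P` for bilayer phosphorus atoms.
#' Coordinates are converted from Angstrom to nm. Missing side-chain
#' pseudo-atoms are tolerated. Malformed ATOM/HETATM records are rejected
#' with their line number. Frame times are reconstructed as
#' `(frame - 1) * timestep`.
#'
#' @param path PDB file.
#' @param timestep Frame spacing in ps.
#' @return A trajectory tibble (class `"pep_trajectory"`).
#' @export
read_structures <- function(path, timestep = 1000) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(sprintf("%s: empty file.", path))
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_lines) == 0) abort(sprintf("%s: no ATOM/HETATM records.", path))
  model_starts <- which(rec == "MODEL ")
  frame_of_line <- if (length(model_starts) == 0) {
    rep(1L, length(lines))
  } else {
    findInterval(seq_along(lines), model_starts)
  }
  num <- function(s, ln, what) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) {
      abort(sprintf("%s: malformed %s in record at line %d.",
                    path, what, ln[which(is.na(v))[1]]))
    }
    v
  }
  al <- atom_lines
  txt <- lines[al]
  if (any(nchar(txt) < 54)) {
    abort(sprintf("%s: truncated record at line %d.",
                  path, al[which(nchar(txt) < 54)[1]]))
  }
  atom <- trimws(substr(txt, 13, 16))
  resname <- trimws(substr(txt, 18, 20))
  residue <- as.integer(num(substr(txt, 23, 26), al, "residue number"))
  x <- num(substr(txt, 31, 38), al, "x coordinate") / 10
  y <- num(substr(txt, 39, 46), al, "y coordinate") / 10
  z <- num(substr(txt, 47, 54), al, "z coordinate") / 10
  is_het <- rec[al] == "HETATM"
  part <- ifelse(is_het & atom == "P", "lipidP", "peptide")
  aa <- ifelse(part == "peptide", unname(.aa1[resname]), NA_character_)
  if (any(part == "peptide" & is.na(aa))) {
    bad <- which(part == "peptide" & is.na(aa))[1]
    abort(sprintf("%s: unknown residue name '%s' at line %d.",
                  path, resname[bad], al[bad]))
  }
  frame <- frame_of_line[al]
  if (length(unique(frame)) > 1) {
    counts <- table(frame)
    if (length(unique(counts)) != 1) {
      abort(sprintf("%s: frames have varying atom counts.", path))
    }
  }
  frame <- match(frame, sort(unique(frame)))
  out <- tibble(
    frame = frame,
    time = (frame - 1) * timestep,
    residue = residue, resname = resname, aa = aa, atom = atom,
    x = x, y = y, z = z,
    part = part, leaflet = NA_character_
  )
  # label leaflets once from the first frame's phosphorus set
  if (any(out$part == "lipidP")) {
    p1 <- out[out$part == "lipidP" & out$frame == 1L, , drop = FALSE]
    med <- stats::median(p1$z)
    out$leaflet[out$part == "lipidP"] <-
      ifelse(out$z[out$part == "lipidP"] > med, "upper", "lower")
  }
  class(out) <- c("pep_trajectory", class(tibble()))
  attr(out, "timestep") <- timestep
  out
}
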