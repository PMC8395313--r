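#' Net charge at neutral pH
#'
#' Integer charge-counting convention for short membrane-active peptides:
#' Lys/Arg +1, Asp/Glu -1, His 0, +1 for a free (protonated) N-terminal
#' amine, -1 for a free-acid C-terminus and 0 when the C-terminus is
#' amidated. No pKa model is applied.
#'
#' @param p A peptide (from [parse_peptide()]), a plain sequence string, or a
#'   one-row peptide table.
#' @inheritParams parse_peptide
#' @return Integer net charge.
#' @examples
#' net_charge("VNWKKILGKIIKVVK", amidated = TRUE) # +6
#' @export
net_charge <- function(p, amidated = TRUE, n_terminal_free = TRUE) {
  p <- .as_peptide(p, amidated = amidated, n_terminal_free = n_terminal_free)
  side <- sum(p$residues %in% c("K", "R")) - sum(p$residues %in% c("D", "E"))
  nterm <- if (p$n_terminal_free) 1L else 0L
  cterm <- if (p$c_terminal_amidated) 0L else -1L
  as.integer(side + nterm + cterm)
}

# window starts for a sequence of length L: all contiguous windows, or the
# whole sequence as a single window when it is shorter than the window
.window_starts <- function(len, window) {
  if (len < window) return(list(starts = 1L, width = len))
  list(starts = seq_len(len - window + 1L), width = window)
}

#' Windowed amphipathicity metrics
#'
#' Per-window mean hydrophobicity and Eisenberg hydrophobic moment of a
#' peptide, assuming an ideal alpha-helix (`delta` degrees of azimuthal twist
#' per residue). For a window of residues with hydrophobicities \eqn{H_k}
#' (k = 0..w-1 within the window) the moment is the per-residue-normalized
#' vector sum
#' \deqn{\mu_H = \frac{1}{w}\sqrt{\left(\sum_k H_k \sin(k\delta)\right)^2 +
#'   \left(\sum_k H_k \cos(k\delta)\right)^2}.}
#' Sequences shorter than the window are scored as one whole-sequence
#' window. The whole-sequence summaries `mean_H` and `mean_muH` are
#' arithmetic means of the per-window values; with the default 11-residue
#' window and the Fauchere-Pliska scale this is the HELIQUEST-style
#' "average values" convention.
#'
#' @inheritParams net_charge
#' @param scale Hydrophobicity scale name or named 20-vector (see
#'   [hydro_scale()]).
#' @param window Window width in residues.
#' @param delta Helical twist per residue, degrees.
#' @return A tibble with one row per window: `start`, `end` (1-based
#'   inclusive), `H`, `muH`, plus attributes `mean_H`, `mean_muH`, `window`,
#'   `delta`, `scale`.
#' @examples
#' pep_windows("VNWKKILGKIIKVVK")
#' @export
pep_windows <- function(p, scale = "fauchere_pliska", window = 11L,
                        delta = 100) {
  p <- .as_peptide(p)
  if (!is.numeric(window) || length(window) != 1L || window < 1) {
    abort("`window` must be a single count >= 1.")
  }
  window <- as.integer(window)
  values <- .resolve_scale(scale)
  h <- unname(values[p$residues])
  w <- .window_starts(length(h), window)
  rad <- delta * pi / 180
  rows <- purrr::map(w$starts, function(s) {
    hh <- h[s:(s + w$width - 1L)]
    k <- seq_along(hh) - 1
    sx <- sum(hh * sin(k * rad))
    cx <- sum(hh * cos(k * rad))
    tibble(
      start = s, end = s + w$width - 1L,
      H = mean(hh),
      muH = sqrt(sx^2 + cx^2) / length(hh)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_H") <- mean(out$H)
  attr(out, "mean_muH") <- mean(out$muH)
  attr(out, "window") <- window
  attr(out, "delta") <- delta
  attr(out, "scale") <- .scale_label(scale)
  out
}

#' Amphipathicity profile of a peptide table
#'
#' Maps [pep_windows()] and [net_charge()] over a tidy peptide table (columns
#' `id`, `sequence`, and optionally `amidated`, `n_terminal_free`), returning
#' one row per peptide with the window-averaged metrics. This reproduces the
#' standard sequence-property table for a peptide panel.
#'
#' @param peptides Data frame with at least `id` and `sequence` columns.
#' @inheritParams pep_windows
#' @return A tibble with columns `id`, `length`, `net_charge`, `mean_H`,
#'   `mean_muH`, `window`, `scale`.
#' @examples
#' acp_peptides() |> pep_profile()
#' @export
pep_profile <- function(peptides, scale = "fauchere_pliska", window = 11L,
                        delta = 100) {
  if (!is.data.frame(peptides) || nrow(peptides) == 0L) {
    abort("`peptides` must be a data frame with at least one row.")
  }
  if (!all(c("id", "sequence") %in% names(peptides))) {
    abort("`peptides` needs `id` and `sequence` columns.")
  }
  purrr::map_dfr(seq_len(nrow(peptides)), function(i) {
    p <- .as_peptide(peptides[i, , drop = FALSE])
    wins <- pep_windows(p, scale = scale, window = window, delta = delta)
    tibble(
      id = p$id,
      length = length(p$residues),
      net_charge = net_charge(p),
      mean_H = attr(wins, "mean_H"),
      mean_muH = attr(wins, "mean_muH"),
      window = attr(wins, "window"),
      scale = attr(wins, "scale")
    )
  })
}

#' Amphipathicity of sub-sequences
#'
#' Applies the windowed metrics independently to 1-based inclusive residue
#' intervals of one peptide (e.g. the N-terminal 1-11 segment of a long
#' sequence). An interval shorter than the window is scored as a single
#' window.
#'
#' @inheritParams pep_windows
#' @param ranges Data frame (or list coercible to one) with columns `start`
#'   and `end`, 1-based inclusive.
#' @return A tibble with one row per interval: `start`, `end`, `length`,
#'   `mean_H`, `mean_muH`, `n_windows`.
#' @examples
#' pep_segments(acp_peptides()[5, ], data.frame(start = 1, end = 11))
#' @export
pep_segments <- function(p, ranges, scale = "fauchere_pliska", window = 11L,
                         delta = 100) {
  p <- .as_peptide(p)
  ranges <- as.data.frame(ranges)
  if (!all(c("start", "end") %in% names(ranges))) {
    abort("`ranges` needs `start` and `end` columns.")
  }
  L <- length(p$residues)
  purrr::map_dfr(seq_len(nrow(ranges)), function(i) {
    s <- ranges$start[i]; e <- ranges$end[i]
    if (s < 1 || e > L || s > e) {
      abort(sprintf("Interval %d-%d is out of bounds for a %d-residue peptide.", s, e, L))
    }
    sub <- parse_peptide(
      paste(p$residues[s:e], collapse = ""),
      id = sprintf("%s_%d-%d", p$id, s, e),
      amidated = p$c_terminal_amidated
    )
    wins <- pep_windows(sub, scale = scale, window = window, delta = delta)
    tibble(
      start = as.integer(s), end = as.integer(e), length = e - s + 1L,
      mean_H = attr(wins, "mean_H"),
      mean_muH = attr(wins, "mean_muH"),
      n_windows = nrow(wins)
    )
  })
}

#' Helical wheel projection
#'
#' Projects residues onto the helical wheel (residue k, 0-based, at azimuth
#' `k * delta` mod 360) and locates the hydrophobic face as the direction of
#' the per-residue-normalized hydrophobic-moment vector
#' \eqn{\frac{1}{L}\sum_k H_k e^{i k \delta}}. When the face magnitude is
#' numerically zero (below 1e-9, e.g. poly-Gly) the face direction is
#' undefined and reported as `NA`.
#'
#' @inheritParams pep_windows
#' @return A tibble of class `"pep_wheel"` with one row per residue:
#'   `residue`, `aa`, `azimuth` (degrees in [0, 360)), `H`; attributes
#'   `face_azimuth` (degrees or `NA`), `face_magnitude`, `delta`, `id`.
#' @examples
#' pep_wheel("FKRIVQRIKDFLRNLV")
#' @export
pep_wheel <- function(p, scale = "fauchere_pliska", delta = 100) {
  p <- .as_peptide(p)
  values <- .resolve_scale(scale)
  h <- unname(values[p$residues])
  k <- seq_along(h) - 1
  azimuth <- (k * delta) %% 360
  rad <- azimuth * pi / 180
  fx <- sum(h * cos(rad)) / length(h)
  fy <- sum(h * sin(rad)) / length(h)
  mag <- sqrt(fx^2 + fy^2)
  face <- if (mag < 1e-9) NA_real_ else (atan2(fy, fx) * 180 / pi) %% 360
  out <- tibble(
    residue = seq_along(h),
    aa = p$residues,
    azimuth = azimuth,
    H = h
  )
  class(out) <- c("pep_wheel", class(out))
  attr(out, "face_azimuth") <- face
  attr(out, "face_magnitude") <- mag
  attr(out, "delta") <- delta
  attr(out, "id") <- p$id
  out
}

#' Write a profile table as TSV
#'
#' @param profile Output of [pep_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Half-up rounding
#'
#' Rounding convention used when comparing computed metrics against
#' 2-decimal published property tables (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
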