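# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use explicit loops and no package
# internals.

fp_scale_ref <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22
)

# brute-force window-averaged mean hydrophobicity
oracle_mean_h <- function(sequence, window = 11) {
  h <- unname(fp_scale_ref[strsplit(sequence, "")[[1]]])
  L <- length(h)
  if (L < window) return(mean(h))
  means <- numeric(0)
  for (j in 1:(L - window + 1)) {
    acc <- 0
    for (k in 0:(window - 1)) acc <- acc + h[j + k]
    means <- c(means, acc / window)
  }
  mean(means)
}

# brute-force window-averaged Eisenberg hydrophobic moment
oracle_mean_muh <- function(sequence, window = 11, delta = 100) {
  h <- unname(fp_scale_ref[strsplit(sequence, "")[[1]]])
  L <- length(h)
  one <- function(hh) {
    sx <- 0; cx <- 0
    for (k in seq_along(hh)) {
      ang <- (k - 1) * delta * pi / 180
      sx <- sx + hh[k] * sin(ang)
      cx <- cx + hh[k] * cos(ang)
    }
    sqrt(sx^2 + cx^2) / length(hh)
  }
  if (L < window) return(one(h))
  vals <- numeric(0)
  for (j in 1:(L - window + 1)) vals <- c(vals, one(h[j:(j + window - 1)]))
  mean(vals)
}

random_sequence <- function(len) {
  paste(sample(names(fp_scale_ref), len, replace = TRUE), collapse = "")
}

# minimal hand-built frame: a fake peptide of point "atoms" plus a bilayer,
# for arithmetic checks of the membrane metrics
point_frame <- function(pep_z, p_upper_z = 2, p_lower_z = -2, n_p = 8,
                        pep_atom = "CA", aa = "A") {
  pep <- tibble::tibble(
    residue = seq_along(pep_z), resname = "ALA", aa = aa,
    atom = pep_atom, x = 0, y = 0, z = pep_z,
    part = "peptide", leaflet = NA_character_
  )
  lip <- tibble::tibble(
    residue = seq_len(2 * n_p), resname = "LIP", aa = NA_character_,
    atom = "P",
    x = rep(seq_len(n_p), 2), y = 0,
    z = rep(c(p_upper_z, p_lower_z), each = n_p),
    part = "lipidP", leaflet = rep(c("upper", "lower"), each = n_p)
  )
  out <- dplyr::bind_rows(pep, lip)
  attr(out, "time") <- 0
  out
}

table1_peptides <- function() acp_peptides()
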