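#' Amino-acid hydrophobicity scales
#'
#' Registry of per-residue hydrophobicity scales keyed by name. The default
#' `"fauchere_pliska"` scale holds the octanol/water side-chain partition
#' values of Fauchere & Pliska as published to two decimals (Gly = 0.00),
#' the scale used by HELIQUEST-style amphipathicity calculations.
#'
#' @param name Scale name. See `hydro_scale_names()` for what is registered.
#' @return `hydro_scale()` returns a named numeric vector of length 20
#'   (one value per canonical one-letter amino-acid code).
#' @examples
#' hydro_scale()[c("G", "W", "K")]
#' @export
hydro_scale <- function(name = "fauchere_pliska") {
  if (!is.character(name) || length(name) != 1L) {
    abort("`name` must be a single string.")
  }
  reg <- .hydro_registry()
  if (!name %in% names(reg)) {
    abort(sprintf(
      "Unknown hydrophobicity scale '%s'. Registered: %s.",
      name, paste(names(reg), collapse = ", ")
    ))
  }
  reg[[name]]
}

#' @rdname hydro_scale
#' @export
hydro_scale_names <- function() names(.hydro_registry())

#' Register a hydrophobicity scale
#'
#' Adds (or replaces) a named scale in the session registry. All 20 canonical
#' residue codes must be present.
#'
#' @param name Scale name.
#' @param values Named numeric vector over the 20 canonical one-letter codes.
#' @return The values, invisibly.
#' @export
register_hydro_scale <- function(name, values) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  values <- unlist(values)
  missing <- setdiff(.aa_codes, names(values))
  if (length(missing) > 0L) {
    abort(sprintf(
      "Scale '%s' is missing residues: %s.", name,
      paste(missing, collapse = ", ")
    ))
  }
  if (!is.numeric(values) || any(!is.finite(values[.aa_codes]))) {
    abort("Scale values must be finite numbers.")
  }
  .hydro_env$registry[[name]] <- values[.aa_codes]
  invisible(values[.aa_codes])
}

# canonical 20 one-letter codes, fixed order
.aa_codes <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Fauchere-Pliska octanol/water partition scale, published 2-decimal values
.fp_values <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22
)

.hydro_env <- new.env(parent = emptyenv())

.hydro_registry <- function() {
  if (is.null(.hydro_env$registry)) {
    .hydro_env$registry <- list(fauchere_pliska = .fp_values[.aa_codes])
  }
  .hydro_env$registry
}

# resolve a scale argument that may be a name or a full named vector
.resolve_scale <- function(scale) {
  if (is.character(scale) && length(scale) == 1L) return(hydro_scale(scale))
  values <- unlist(scale)
  missing <- setdiff(.aa_codes, names(values))
  if (length(missing) > 0L) {
    abort(sprintf("Scale is missing residues: %s.", paste(missing, collapse = ", ")))
  }
  values[.aa_codes]
}

.scale_label <- function(scale) {
  if (is.character(scale) && length(scale) == 1L) scale else "custom"
}
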