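#' Parse and validate a peptide sequence
#'
#' Builds a validated peptide record from one-letter sequence text. Parsing is
#' case-insensitive and strips whitespace; any character outside the 20
#' canonical codes is rejected with its position. Terminal chemistry is
#' explicit: many natural membrane-active peptides are C-terminally amidated,
#' which removes the terminal negative charge, so the flag is never inferred
#' from the sequence.
#'
#' @param sequence One-letter amino-acid string.
#' @param id Short label for the peptide.
#' @param amidated Is the C-terminus amidated (carboxamide)?
#' @param n_terminal_free Is the N-terminus a free (protonatable) amine?
#' @return An object of class `"peptide"`: a list with `id`, `residues`
#'   (character vector of one-letter codes), `c_terminal_amidated`,
#'   `n_terminal_free`.
#' @examples
#' parse_peptide("VNWKKILGKIIKVVK", id = "lasio_iii", amidated = TRUE)
#' @export
parse_peptide <- function(sequence, id = "peptide", amidated = TRUE,
                          n_terminal_free = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort("`sequence` must be a single string.")
  }
  txt <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(txt)) abort("Empty peptide sequence.")
  residues <- strsplit(txt, "", fixed = TRUE)[[1]]
  bad <- which(!residues %in% .aa_codes)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Non-canonical residue code '%s' at position %d.",
      residues[bad[1]], bad[1]
    ))
  }
  structure(
    list(
      id = as.character(id),
      residues = residues,
      c_terminal_amidated = isTRUE(amidated),
      n_terminal_free = isTRUE(n_terminal_free)
    ),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf(
    "<peptide> %s (%d aa)%s%s\n  %s\n",
    x$id, length(x$residues),
    if (x$c_terminal_amidated) ", C-amidated" else ", free acid C-terminus",
    if (x$n_terminal_free) "" else ", blocked N-terminus",
    paste(x$residues, collapse = "")
  ))
  invisible(x)
}

#' @export
length.peptide <- function(x) length(x$residues)

# accept a peptide, a string, or a one-row slice of a peptide table
.as_peptide <- function(p, id = "peptide", amidated = TRUE,
                        n_terminal_free = TRUE) {
  if (inherits(p, "peptide")) return(p)
  if (is.character(p) && length(p) == 1L) {
    return(parse_peptide(p, id = id, amidated = amidated,
                         n_terminal_free = n_terminal_free))
  }
  if (is.data.frame(p) && nrow(p) == 1L && "sequence" %in% names(p)) {
    return(parse_peptide(
      p$sequence,
      id = if ("id" %in% names(p)) p$id else id,
      amidated = if ("amidated" %in% names(p)) p$amidated else amidated,
      n_terminal_free = if ("n_terminal_free" %in% names(p)) p$n_terminal_free else n_terminal_free
    ))
  }
  abort("Cannot interpret `p` as a peptide (need a peptide, a string, or a one-row data frame with a `sequence` column).")
}

#' Read peptides from FASTA into a tidy table
#'
#' Reads single- or multi-record FASTA. A record whose description contains
#' the token `amidated` (case-insensitive) is flagged as C-terminally
#' amidated; `free_acid` forces the opposite; otherwise `default_amidated`
#' applies.
#'
#' @param path FASTA file.
#' @param default_amidated Amidation flag when the description says nothing.
#' @return A tibble with columns `id`, `sequence`, `length`, `amidated`,
#'   `n_terminal_free` -- the table shape consumed by [pep_profile()].
#' @export
read_peptides <- function(path, default_amidated = TRUE) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    if (length(set) == 0L) abort(sprintf("No FASTA records in %s", path))
    headers <- names(set)
    seqs <- as.character(set)
  } else {
    lines <- readLines(path)
    idx <- grep("^>", lines)
    if (length(idx) == 0L) abort(sprintf("No FASTA records in %s", path))
    headers <- sub("^>", "", lines[idx])
    ends <- c(idx[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(idx), function(i) {
      paste(lines[seq(idx[i] + 1L, ends[i])], collapse = "")
    }, character(1))
  }
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[[`, character(1), 1L)
  desc <- tolower(headers)
  amidated <- ifelse(
    grepl("free_acid", desc), FALSE,
    ifelse(grepl("amidated", desc), TRUE, default_amidated)
  )
  peps <- purrr::map2(seqs, seq_along(seqs), function(s, i) {
    parse_peptide(s, id = ids[i], amidated = amidated[i])
  })
  tibble(
    id = unname(ids),
    sequence = unname(vapply(peps, function(p) paste(p$residues, collapse = ""), character(1))),
    length = unname(vapply(peps, function(p) length(p$residues), integer(1))),
    amidated = amidated,
    n_terminal_free = TRUE
  )
}

#' Bundled anticancer peptide set
#'
#' Returns the five natural anticancer peptides shipped with the package
#' (Lasioglossin LL-III, Macropin 1, Temporin-La, FK-16, LL-37), all
#' C-terminally amidated, as a tidy peptide table.
#'
#' @return A tibble as from [read_peptides()].
#' @examples
#' acp_peptides()
#' @export
acp_peptides <- function() {
  read_peptides(system.file("extdata", "acp_peptides.fasta",
                            package = "helimode", mustWork = TRUE))
}

# one-letter -> three-letter residue codes (PDB resName) and back
.aa3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)
.aa1 <- setNames(names(.aa3), unname(.aa3))
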