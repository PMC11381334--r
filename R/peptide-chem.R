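#' Monoisotopic mass of a peptide
#'
#' Sum of the residue masses plus one water (the N- and C-terminal H and OH).
#' Permutation-invariant in the residues; the empty peptide is one water.
#'
#' @param peptide Character vector of peptide sequences (uppercase one-letter
#'   codes, N-to-C). Vectorized.
#' @param mass_table A table from [residue_mass_table()]; defaults to the
#'   unmodified standard table.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("YLLEAK")
#' monoisotopic_mass(c("ILAGS", "LIAGS")) # isobaric: I/L share a mass
#' @export
monoisotopic_mass <- function(peptide, mass_table = default_mass_table()) {
  vapply(peptide, function(p) {
    validate_peptide(p)
    if (nchar(p) == 0L) {
      return(mass_table$water)
    }
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    sum(mass_table$residues[chars]) + mass_table$water
  }, numeric(1), USE.NAMES = FALSE)
}

# Vectorized residue-count mass for equal-length sequences. Computing the mass
# as counts %*% masses makes permutations of one composition bit-identical,
# which exact-mass grouping in the design module relies on.
composition_mass <- function(sequences, mass_table = default_mass_table()) {
  if (length(sequences) == 0L) {
    return(numeric(0))
  }
  k <- unique(nchar(sequences))
  stopifnot(length(k) == 1L)
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
    ncol = k, byrow = TRUE
  )
  letters_used <- sort(unique(as.vector(mat)))
  counts <- vapply(letters_used, function(a) rowSums(mat == a),
    numeric(nrow(mat))
  )
  if (nrow(mat) == 1L) counts <- matrix(counts, nrow = 1L)
  drop(counts %*% mass_table$residues[letters_used]) + mass_table$water
}

#' Precursor m/z of a peptide at a given charge
#'
#' @inheritParams monoisotopic_mass
#' @param charge Positive integer charge state (vectorized over peptides,
#'   scalar charge).
#' @return Numeric vector of m/z values: `(M + z * proton) / z`.
#' @examples
#' precursor_mz("G", 1)
#' @export
precursor_mz <- function(peptide, charge, mass_table = default_mass_table()) {
  if (!is.numeric(charge) || length(charge) != 1L || is.na(charge) ||
    charge < 1 || charge != as.integer(charge)) {
    stop("`charge` must be a positive integer (>= 1).", call. = FALSE)
  }
  (monoisotopic_mass(peptide, mass_table) + charge * mass_table$proton) / charge
}

#' Singly-protonated b/y fragment-ion series
#'
#' Computes the standard collision-induced dissociation fragment series at
#' charge 1: `b_i` is the sum of the first `i` residues plus a proton, `y_j`
#' the sum of the last `j` residues plus water plus a proton. The two series
#' obey the complementarity identity
#' `b_i + y_(n-i) == monoisotopic_mass + 2 * proton` at every index. Fragments
#' whose N-terminal residue is proline are collected as diagnostic y ions:
#' proline's cyclic side chain promotes strong y-series cleavage N-terminal to
#' it, so a proline placed in every barcode guarantees a predictable,
#' intense reporter fragment at MS2.
#'
#' @param peptide A single peptide sequence of length >= 2.
#' @inheritParams monoisotopic_mass
#' @return An object of class `fragment_spectrum`: a list with `peptide`,
#'   `b_ions` and `y_ions` (data frames with columns `index`, `mz`), and
#'   `diagnostic_y` (the subset of `y_ions` starting at a proline).
#' @examples
#' fragment_ions("GGPAK")
#' @export
fragment_ions <- function(peptide, mass_table = default_mass_table()) {
  validate_peptide(peptide)
  n <- nchar(peptide)
  if (n < 2L) {
    stop("`peptide` must have at least 2 residues to fragment.", call. = FALSE)
  }
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  res <- mass_table$residues[chars]
  idx <- seq_len(n - 1L)
  b <- cumsum(res)[idx] + mass_table$proton
  y <- cumsum(rev(res))[idx] + mass_table$water + mass_table$proton
  b_ions <- data.frame(index = idx, mz = unname(b))
  y_ions <- data.frame(index = idx, mz = unname(y))
  # y_j covers residues (n - j + 1) .. n; its N-terminal residue is chars[n - j + 1]
  diag_sel <- chars[n - y_ions$index + 1L] == "P"
  structure(
    list(
      peptide = peptide,
      b_ions = b_ions,
      y_ions = y_ions,
      diagnostic_y = y_ions[diag_sel, , drop = FALSE]
    ),
    class = "fragment_spectrum"
  )
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat("Fragment spectrum (singly protonated b/y) for", x$peptide, "\n")
  cat(sprintf(
    "  %d b ions, %d y ions, %d diagnostic proline y ion(s)\n",
    nrow(x$b_ions), nrow(x$y_ions), nrow(x$diagnostic_y)
  ))
  invisible(x)
}

# Position-wise b-ion matrix for equal-length sequences (one row per peptide);
# used by the MS2 distinguishability screen, where pairwise comparison over
# thousands of isobaric permutations must be vectorized.
b_ion_matrix <- function(sequences, mass_table = default_mass_table()) {
  k <- unique(nchar(sequences))
  stopifnot(length(k) == 1L, k >= 2L)
  mat <- matrix(
    mass_table$residues[
      unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE)
    ],
    ncol = k, byrow = TRUE
  )
  out <- mat
  for (j in 2:k) out[, j] <- out[, j - 1L] + mat[, j]
  out[, -k, drop = FALSE] + mass_table$proton
}
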