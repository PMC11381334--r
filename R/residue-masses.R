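#' Monoisotopic residue-mass table
#'
#' The chemistry ground truth used by every mass computation in the package:
#' monoisotopic residue (amino-acid minus water) masses for the 20 standard
#' amino acids, together with the monoisotopic mass of water and the proton.
#' Isoleucine and leucine share one mass value exactly, which is why they are
#' indistinguishable at MS1 and within any single fragment.
#'
#' @param fixed_mods Optional named numeric vector of fixed modifications to
#'   add to specific residues, e.g. `c(C = 57.021464)` for carbamidomethyl
#'   cysteine. Barcode peptides exclude cysteine by design, so the default
#'   (no modification) never affects them.
#'
#' @return A list with components `residues` (named numeric vector of length
#'   20, one-letter codes), `water` and `proton` (Da).
#' @examples
#' tab <- residue_mass_table()
#' tab$residues[["G"]]
#' @export
residue_mass_table <- function(fixed_mods = NULL) {
  residues <- c(
    G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
    V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
  )
  if (!is.null(fixed_mods)) {
    if (is.null(names(fixed_mods)) || !all(names(fixed_mods) %in% names(residues))) {
      stop("`fixed_mods` must be named by standard one-letter residue codes.",
        call. = FALSE
      )
    }
    residues[names(fixed_mods)] <- residues[names(fixed_mods)] + fixed_mods
  }
  list(residues = residues, water = 18.010565, proton = 1.007276)
}

#' @keywords internal
#' @noRd
default_mass_table <- function() {
  if (is.null(.pals_env$mass_table)) .pals_env$mass_table <- residue_mass_table()
  .pals_env$mass_table
}

.pals_env <- new.env(parent = emptyenv())

#' Validate a peptide sequence
#'
#' Checks that a sequence is a non-NA character scalar containing only the
#' 20 standard uppercase one-letter residue codes. An empty string is allowed
#' (the empty peptide is one water molecule); the caller decides whether that
#' makes sense for the operation at hand.
#'
#' @param sequence Character scalar, N-to-C orientation.
#' @return The validated sequence, invisibly.
#' @export
validate_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("`sequence` must be a single non-NA character string.", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(residue_mass_table()$residues))
  if (length(bad) > 0) {
    stop(
      "Unknown residue character(s) in peptide: ",
      paste0("'", bad, "'", collapse = ", "),
      call. = FALSE
    )
  }
  invisible(sequence)
}
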