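#' Read protein or peptide sequences from FASTA
#'
#' @param path Path to a FASTA file (single or multi-record).
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- names(seqs)
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a targeted-MS inclusion list for a set of peptides
#'
#' Exports one row per peptide with its monoisotopic mass and precursor m/z
#' at charges 1-3, the input a vendor-agnostic targeted acquisition (or XIC
#' extraction) list. All charge states are exported because the charge used
#' for extraction is an acquisition-time decision; the quantitation module is
#' charge-agnostic.
#'
#' @param ids Character vector of identifiers (e.g. barcode ids).
#' @param sequences Character vector of peptide sequences, same length.
#' @param path Output CSV path.
#' @inheritParams monoisotopic_mass
#' @return The tibble written, invisibly.
#' @export
write_inclusion_list <- function(ids, sequences, path,
                                 mass_table = default_mass_table()) {
  stopifnot(length(ids) == length(sequences))
  mass <- monoisotopic_mass(sequences, mass_table)
  tab <- tibble::tibble(
    barcode_id = as.character(ids),
    sequence = sequences,
    monoisotopic_mass = mass,
    mz_z1 = (mass + 1 * mass_table$proton) / 1,
    mz_z2 = (mass + 2 * mass_table$proton) / 2,
    mz_z3 = (mass + 3 * mass_table$proton) / 3
  )
  readr::write_csv(tab, path)
  invisible(tab)
}
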