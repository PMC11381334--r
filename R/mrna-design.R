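#' Standard codon table keyed by residue
#'
#' Built from the standard genetic code: each of the 20 residues maps to its
#' synonymous sense codons (61 in total), lexicographically sorted. The GC
#' count of each codon is precomputed for the reverse-translation optimizer.
#'
#' @return An object of class `codon_table`: list with `codons` (residue ->
#'   character vector) and `gc` (residue -> integer GC counts, parallel).
#' @export
codon_table <- function() {
  gc_code <- Biostrings::GENETIC_CODE
  sense <- gc_code[gc_code != "*"]
  by_res <- split(names(sense), sense)
  by_res <- lapply(by_res, sort)
  gc <- lapply(by_res, function(cs) {
    vapply(cs, function(cd) {
      sum(strsplit(cd, "", fixed = TRUE)[[1]] %in% c("G", "C"))
    }, integer(1))
  })
  structure(list(codons = by_res, gc = gc), class = "codon_table")
}

#' GC fraction of a nucleotide sequence
#'
#' @param nt Character vector of nucleotide sequences.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_content <- function(nt) {
  vapply(nt, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    if (length(chars) == 0) {
      return(NaN)
    }
    mean(chars %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Feasible GC envelope of a protein's coding sequence
#'
#' Minimum and maximum GC fraction achievable by synonymous codon choice.
#'
#' @param protein Protein sequence.
#' @param table A [codon_table()].
#' @return Numeric length-2 `c(min, max)`.
#' @export
gc_envelope <- function(protein, table = codon_table()) {
  validate_peptide(protein)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  lo <- sum(vapply(chars, function(a) min(table$gc[[a]]), numeric(1)))
  hi <- sum(vapply(chars, function(a) max(table$gc[[a]]), numeric(1)))
  c(lo, hi) / (3 * length(chars))
}

#' Reverse-translate a protein to a GC-targeted ORF
#'
#' Chooses one synonymous codon per residue, greedily with running-deficit
#' correction: at each position the codon minimizing the absolute deviation
#' of the projected GC count from the target trajectory is picked, ties
#' broken by lexicographically smallest codon. Because every residue's
#' synonymous GC counts form a contiguous integer range, the running
#' correction keeps the achieved GC within one codon's worth of the target
#' (when the target is inside the feasible envelope) and makes the achieved
#' GC monotone in the target. The result is deterministic.
#'
#' @param protein Protein sequence.
#' @param table A [codon_table()].
#' @param gc_target Desired GC fraction in `[0, 1]`. A target outside the
#'   protein's feasible envelope is clamped to the nearest feasible value
#'   with a warning.
#' @return The ORF nucleotide string; its translation equals `protein`.
#' @examples
#' orf <- reverse_translate("GGGG", gc_target = 1)
#' gc_content(orf)
#' @export
reverse_translate <- function(protein, table = codon_table(), gc_target = 0.62) {
  validate_peptide(protein)
  stopifnot(gc_target >= 0, gc_target <= 1)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) {
    return("")
  }
  env <- gc_envelope(protein, table)
  if (gc_target < env[1] || gc_target > env[2]) {
    clamped <- min(max(gc_target, env[1]), env[2])
    warning(
      sprintf(
        "gc_target %.3f outside the feasible envelope [%.3f, %.3f]; using %.3f.",
        gc_target, env[1], env[2], clamped
      ),
      call. = FALSE
    )
    gc_target <- clamped
  }
  n <- length(chars)
  gc_min <- vapply(chars, function(a) min(table$gc[[a]]), numeric(1))
  gc_max <- vapply(chars, function(a) max(table$gc[[a]]), numeric(1))
  # GC still obtainable from positions after i (suffix envelope); the running
  # deficit is clamped into it so a GC-poor tail is anticipated, not discovered
  suffix_min <- rev(cumsum(rev(gc_min))) - gc_min
  suffix_max <- rev(cumsum(rev(gc_max))) - gc_max
  total_target <- gc_target * 3 * n
  g <- 0 # accumulated GC count
  picks <- character(n)
  for (i in seq_len(n)) {
    opts <- table$codons[[chars[i]]]
    gcs <- table$gc[[chars[i]]]
    desired <- gc_target * 3 * i - g # running-deficit trajectory
    feas_lo <- (total_target - g) - suffix_max[i]
    feas_hi <- (total_target - g) - suffix_min[i]
    desired <- min(max(desired, feas_lo), feas_hi)
    dev <- abs(gcs - desired)
    # ties: round the GC deficit down consistently (keeps achieved GC monotone
    # in the target), then lexicographically smallest codon (opts are sorted)
    pick <- order(dev, gcs, opts)[1]
    picks[i] <- opts[pick]
    g <- g + gcs[pick]
  }
  paste0(picks, collapse = "")
}

#' Translate an ORF back to protein
#'
#' @param orf Nucleotide string, length divisible by 3, sense codons only.
#' @return The protein sequence.
#' @export
translate_orf <- function(orf) {
  orf <- toupper(orf)
  n <- nchar(orf)
  if (n %% 3 != 0) stop("ORF length must be divisible by 3.", call. = FALSE)
  if (n == 0) {
    return("")
  }
  codons <- substring(orf, seq(1, n, 3), seq(3, n, 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa) || any(aa == "*")) {
    stop("ORF contains a stop or unrecognized codon.", call. = FALSE)
  }
  paste0(aa, collapse = "")
}

#' mRNA layout: UTRs and poly(A) tail
#'
#' The default tail length of 120 adenosines mirrors the optimized construct
#' layout (synthetic 5' UTR, beta-haemoglobin-derived 3' UTR, 120-A tail);
#' the UTR sequences themselves are user-supplied.
#'
#' @param utr5,utr3 Untranslated region nucleotide strings (may be empty).
#' @param polya_length Number of adenosines appended (default 120).
#' @return An object of class `mrna_layout`.
#' @export
mrna_layout <- function(utr5 = "", utr3 = "", polya_length = 120L) {
  stopifnot(polya_length >= 0)
  ok_nt <- function(s) grepl("^[ACGTUacgtu]*$", s)
  if (!ok_nt(utr5) || !ok_nt(utr3)) {
    stop("UTRs must contain only A/C/G/T/U.", call. = FALSE)
  }
  structure(
    list(
      utr5 = toupper(utr5), utr3 = toupper(utr3),
      polya_length = as.integer(polya_length)
    ),
    class = "mrna_layout"
  )
}

#' Assemble the full mRNA sequence
#'
#' `utr5 + orf + utr3 + poly(A)`.
#'
#' @param orf ORF nucleotide string (length divisible by 3).
#' @param layout An [mrna_layout()].
#' @return The full mRNA nucleotide string.
#' @export
assemble_mrna <- function(orf, layout = mrna_layout()) {
  stopifnot(inherits(layout, "mrna_layout"))
  if (nchar(orf) %% 3 != 0) stop("ORF length must be divisible by 3.", call. = FALSE)
  paste0(
    layout$utr5, toupper(orf), layout$utr3,
    strrep("A", layout$polya_length)
  )
}

#' T7 promoter core sequence
#'
#' The minimal T7 RNA polymerase promoter that an in-vitro-transcription
#' forward template primer must contain.
#' @export
T7_PROMOTER_CORE <- "TAATACGACTCACTATA"

#' Check an IVT forward primer for the T7 promoter core
#'
#' @param primer Nucleotide string.
#' @return Logical: does the primer contain [T7_PROMOTER_CORE]?
#' @export
has_t7_promoter <- function(primer) {
  grepl(T7_PROMOTER_CORE, toupper(gsub("\\s", "", primer)), fixed = TRUE)
}
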