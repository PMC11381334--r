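#' In-silico trypsin digestion
#'
#' Cleaves C-terminal to lysine or arginine except when the following residue
#' is proline (the classic trypsin rule; no further exceptions are modelled,
#' which is sufficient for verifying barcode release). With
#' `max_missed > 0`, peptides spanning up to that many skipped cleavage sites
#' are additionally emitted.
#'
#' @param sequence Protein sequence (uppercase one-letter codes).
#' @param max_missed Maximum number of missed cleavages (default 0, the
#'   design-verification setting; 2 is typical for carrier-peptide
#'   prediction).
#' @return A tibble with columns `peptide`, `start`, `end` (0-based,
#'   half-open) and `missed_cleavages`, ordered by start position then missed
#'   cleavages. The fully cleaved peptides (missed_cleavages == 0), taken in
#'   order, concatenate back to the input sequence exactly.
#' @examples
#' trypsin_digest("AAAKGGGR")
#' trypsin_digest("AAKPGG") # no cleavage before proline
#' @export
trypsin_digest <- function(sequence, max_missed = 0L) {
  validate_peptide(sequence)
  if (nchar(sequence) == 0L) stop("`sequence` must be non-empty.", call. = FALSE)
  stopifnot(max_missed >= 0L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n) # 0-based half-open segment boundaries
  n_seg <- length(bounds) - 1L
  out <- list()
  for (m in 0:min(max_missed, n_seg - 1L)) {
    i <- seq_len(n_seg - m)
    start <- bounds[i]
    end <- bounds[i + m + 1L]
    out[[m + 1L]] <- tibble::tibble(
      peptide = substring(sequence, start + 1L, end),
      start = start, end = end, missed_cleavages = m
    )
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$start, .data$missed_cleavages)
}

#' Verify tryptic release of panel barcodes from a protein construct
#'
#' Digests a barcoded construct and checks that each annotated barcode is
#' released as exactly one intact tryptic peptide matching its panel
#' `full_peptide`. Carrier-derived peptides whose mass falls within
#' `ms1_min_separation` of any panel barcode mass are flagged as potential
#' interferences.
#'
#' @param construct A list with `sequence` (the full protein) and
#'   `annotations`: a data frame with columns `label`, `start`, `end`
#'   (0-based half-open) and `type` (`"barcode"` rows are checked; the
#'   `label` must match a panel `barcode_id`).
#' @param panel A [select_panel()] result (or a tibble with `barcode_id` and
#'   `full_peptide` columns).
#' @inheritParams enumerate_cores
#' @return A list with `barcodes` (tibble: `barcode_id`, `released`,
#'   `n_matches`, `message`), `interferences` (tibble of carrier peptides
#'   isobaric with a barcode), `all_released` (logical).
#' @export
verify_barcode_release <- function(construct, panel,
                                   constraints = design_constraints()) {
  members <- if (inherits(panel, "barcode_panel")) panel$members else panel
  ann <- construct$annotations
  stopifnot(
    is.character(construct$sequence),
    all(c("label", "start", "end", "type") %in% names(ann))
  )
  if (any(ann$start < 0 | ann$end > nchar(construct$sequence) | ann$start >= ann$end)) {
    stop("Annotations must be in-bounds, 0-based half-open spans.", call. = FALSE)
  }
  ov <- ann[order(ann$start), ]
  if (nrow(ov) > 1 && any(ov$start[-1] < ov$end[-nrow(ov)])) {
    stop("Annotations must be non-overlapping.", call. = FALSE)
  }

  digest <- trypsin_digest(construct$sequence, max_missed = 0L)
  bc_ann <- ann[ann$type == "barcode", , drop = FALSE]
  rows <- lapply(seq_len(nrow(bc_ann)), function(i) {
    label <- bc_ann$label[i]
    exp_pep <- members$full_peptide[match(label, members$barcode_id)]
    if (is.na(exp_pep)) {
      return(tibble::tibble(
        barcode_id = label, released = FALSE, n_matches = 0L,
        message = "barcode label not found in panel"
      ))
    }
    hit <- digest$peptide == exp_pep
    n_hit <- sum(hit)
    if (n_hit == 1L) {
      tibble::tibble(
        barcode_id = label, released = TRUE, n_matches = 1L, message = ""
      )
    } else if (n_hit == 0L) {
      # name the digest peptides overlapping the annotated span
      span_hits <- digest$peptide[digest$end > bc_ann$start[i] &
        digest$start < bc_ann$end[i]]
      tibble::tibble(
        barcode_id = label, released = FALSE, n_matches = 0L,
        message = paste0(
          "not released intact; span digested into: ",
          paste(span_hits, collapse = " | ")
        )
      )
    } else {
      tibble::tibble(
        barcode_id = label, released = FALSE, n_matches = n_hit,
        message = "released more than once (ambiguous quantitation)"
      )
    }
  })
  barcodes <- dplyr::bind_rows(rows)

  carrier <- digest[!(digest$peptide %in% members$full_peptide), , drop = FALSE]
  if (nrow(carrier) > 0) {
    cm <- monoisotopic_mass(carrier$peptide)
    near <- vapply(cm, function(m) {
      d <- abs(members$mass - m)
      if (any(d < constraints$ms1_min_separation)) {
        members$barcode_id[which.min(d)]
      } else {
        NA_character_
      }
    }, character(1))
    interferences <- tibble::tibble(
      peptide = carrier$peptide, mass = cm, isobaric_with = near
    )
    interferences <- interferences[!is.na(interferences$isobaric_with), , drop = FALSE]
  } else {
    interferences <- tibble::tibble(
      peptide = character(), mass = numeric(), isobaric_with = character()
    )
  }

  list(
    barcodes = barcodes,
    interferences = interferences,
    all_released = all(barcodes$released)
  )
}

#' Build a barcoded construct from a carrier protein and a panel member
#'
#' Convenience constructor: appends `K` (a tryptic release site) followed by
#' the barcode full peptide to the carrier's C-terminus, and annotates the
#' spans. The barcode sits at the protein C-terminus, so no trailing cleavage
#' site is required for its release.
#'
#' @param carrier Carrier protein sequence.
#' @param panel A `barcode_panel` (or members tibble).
#' @param barcode_id Which panel member to encode.
#' @return A construct list accepted by [verify_barcode_release()].
#' @export
barcoded_construct <- function(carrier, panel, barcode_id) {
  members <- if (inherits(panel, "barcode_panel")) panel$members else panel
  validate_peptide(carrier)
  i <- match(barcode_id, members$barcode_id)
  if (is.na(i)) stop("`barcode_id` not found in panel.", call. = FALSE)
  bc <- members$full_peptide[i]
  seqn <- paste0(carrier, "K", bc)
  nc <- nchar(carrier)
  list(
    sequence = seqn,
    annotations = tibble::tibble(
      label = c("carrier", barcode_id),
      start = c(0L, nc + 1L),
      end = c(nc, nc + 1L + nchar(bc)),
      type = c("carrier", "barcode")
    )
  )
}
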