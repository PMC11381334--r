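#' Construct or validate a peak-area table
#'
#' The quantitation input: one row per animal per barcode with the integrated
#' XIC peak area (arbitrary units), emulating the output of manual peak
#' integration. `(animal_id, barcode_id)` pairs must be unique and areas
#' non-negative.
#'
#' @param x A data frame with columns `animal_id`, `group_id`, `barcode_id`,
#'   `peak_area` and optionally `below_loq` (logical, default `FALSE`).
#' @return A validated tibble (class `peak_table` prepended).
#' @export
peak_table <- function(x) {
  need <- c("animal_id", "group_id", "barcode_id", "peak_area")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("Peak table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x <- tibble::as_tibble(x)
  if (!("below_loq" %in% names(x))) x$below_loq <- FALSE
  if (any(is.na(x$peak_area)) || any(x$peak_area < 0)) {
    stop("`peak_area` must be non-negative and non-missing.", call. = FALSE)
  }
  if (anyDuplicated(x[, c("animal_id", "barcode_id")])) {
    stop("(animal_id, barcode_id) pairs must be unique.", call. = FALSE)
  }
  class(x) <- c("peak_table", class(x))
  x
}

#' Read a peak-area CSV
#'
#' @param path CSV with columns `animal_id`, `group_id`, `barcode_id`,
#'   `peak_area` (and optionally `below_loq`).
#' @return A validated `peak_table` tibble.
#' @export
read_peak_table <- function(path) {
  peak_table(readr::read_csv(path, show_col_types = FALSE))
}

#' Censor peak areas at a lower limit of quantitation
#'
#' Rows with `peak_area < loq_value` are flagged `below_loq` and set to the
#' censoring value (conservative substitution at the LOQ; substitution is the
#' default rather than exclusion so that censored barcodes still appear in
#' rankings, as "at most this much"). The original area is preserved in
#' `peak_area_raw` for audit.
#'
#' @param table A `peak_table`.
#' @param loq_value Positive censoring threshold, in the table's area units.
#' @param method `"substitute"` (default: set to `loq_value`), `"halve"`
#'   (set to `loq_value / 2`) or `"exclude"` (drop censored rows).
#' @return The censored `peak_table` with a `peak_area_raw` audit column.
#' @export
loq_censor <- function(table, loq_value, method = c("substitute", "halve", "exclude")) {
  method <- match.arg(method)
  stopifnot(loq_value > 0)
  table <- peak_table(table)
  table$peak_area_raw <- table$peak_area
  low <- table$peak_area < loq_value
  table$below_loq <- low
  if (method == "exclude") {
    return(table[!low, , drop = FALSE])
  }
  table$peak_area[low] <- if (method == "substitute") loq_value else loq_value / 2
  table
}

#' Minimum detectable total protein for a pooled screen
#'
#' With a per-barcode protein-equivalent LOQ, a pool of `pool_size` equally
#' expressed barcoded proteins must in total reach `pool_size` times that
#' LOQ before every member is quantifiable (assuming 100% recovery).
#'
#' @param per_barcode_loq Per-barcode protein-equivalent LOQ (e.g. ng/mL).
#' @param pool_size Number of barcoded LNPs in the pool.
#' @return Minimum detectable total, same units as `per_barcode_loq`.
#' @examples
#' pool_loq_total(0.6, 10) # 6 ng/mL for a 10-LNP pool
#' @export
pool_loq_total <- function(per_barcode_loq, pool_size) {
  stopifnot(per_barcode_loq > 0, pool_size >= 1)
  per_barcode_loq * pool_size
}

#' Platform LOQ reference values
#'
#' Two independently stated sensitivity constants for the platform, kept as
#' separate entries because they are not unit-interconvertible without
#' knowing the full sample-processing dilution: the per-barcode peptide LOQ
#' (~2 fmol/uL at the instrument) and the per-barcode protein-equivalent LOQ
#' in serum (~0.6 ng/mL for a ~30 kDa carrier).
#' @export
loq_reference <- list(
  peptide_fmol_per_ul = 2,
  protein_ng_per_ml = 0.6,
  carrier_kda = 30
)

#' Normalize peak areas to a reference barcode, per animal
#'
#' Divides every area by the same animal's reference-barcode area, producing
#' per-animal fold changes in which any animal-level multiplicative factor
#' (dose delivered, overall expression, recovery) cancels. The reference
#' maps to exactly 1 in every animal. Animals in which the reference is
#' absent or below the LOQ are excluded with a warning naming them.
#'
#' @param table A `peak_table` (optionally LOQ-censored).
#' @param reference_barcode The `barcode_id` used as denominator.
#' @return A tibble with columns `animal_id`, `group_id`, `barcode_id`,
#'   `fold_change`.
#' @export
normalize_to_reference <- function(table, reference_barcode) {
  table <- peak_table(table)
  ref <- table[table$barcode_id == reference_barcode, , drop = FALSE]
  usable <- ref$animal_id[!ref$below_loq & ref$peak_area > 0]
  all_animals <- unique(table$animal_id)
  dropped <- setdiff(all_animals, usable)
  if (length(dropped) > 0) {
    warning(
      "Reference barcode '", reference_barcode,
      "' absent or below LOQ in animal(s): ",
      paste(dropped, collapse = ", "), "; excluded from normalization.",
      call. = FALSE
    )
  }
  out <- table[table$animal_id %in% usable, , drop = FALSE]
  ref_area <- stats::setNames(ref$peak_area, ref$animal_id)
  out$fold_change <- out$peak_area / unname(ref_area[out$animal_id])
  tibble::as_tibble(out[, c("animal_id", "group_id", "barcode_id", "fold_change")])
}

#' Rank LNPs by group mean fold change
#'
#' Maps barcodes to LNP labels, averages fold changes per LNP (mean and SD
#' over all animal-level observations) and ranks in descending order of the
#' mean. Exact ties receive average ranks. Ordering is deterministic (mean
#' descending, then label).
#'
#' @param normalized Output of [normalize_to_reference()] (or any data frame
#'   with `barcode_id` and `fold_change`).
#' @param assignment Named character vector or two-column data frame mapping
#'   `barcode_id` to LNP label.
#' @return A tibble `lnp`, `mean_fold_change`, `sd_fold_change`, `n`, `rank`,
#'   ordered by rank. Class `lnp_ranking` prepended.
#' @export
rank_lnps <- function(normalized, assignment) {
  if (is.data.frame(assignment)) {
    assignment <- stats::setNames(
      as.character(assignment[[2]]),
      as.character(assignment[[1]])
    )
  }
  x <- normalized
  x$lnp <- unname(assignment[as.character(x$barcode_id)])
  if (anyNA(x$lnp)) {
    stop("Some barcode_ids have no LNP assignment: ",
      paste(unique(x$barcode_id[is.na(x$lnp)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(unique(x$lnp)) < 2) {
    stop("Ranking requires at least 2 LNPs.", call. = FALSE)
  }
  res <- dplyr::summarise(
    dplyr::group_by(x, .data$lnp),
    mean_fold_change = mean(.data$fold_change),
    sd_fold_change = stats::sd(.data$fold_change),
    n = dplyr::n(),
    .groups = "drop"
  )
  res$rank <- rank(-res$mean_fold_change, ties.method = "average")
  res <- res[order(res$rank, res$lnp), , drop = FALSE]
  class(res) <- c("lnp_ranking", class(res))
  res
}

#' @export
print.lnp_ranking <- function(x, ...) {
  cat(
    "LNP ranking:",
    paste(x$lnp[order(x$rank)], collapse = " > "), "\n"
  )
  NextMethod()
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided exact p-value computed by full enumeration of the signed-rank
#' null: every one of the 2^n assignments of signs to the ranked absolute
#' paired differences is equally likely under the null of symmetry, and the
#' p-value is twice the smaller tail probability of the observed
#' positive-rank sum (capped at 1). No normal approximation and no
#' continuity correction are used, so the minimal attainable two-sided p at
#' n pairs is 2/2^n (0.0625 at n = 5). Zero differences are dropped before
#' ranking (the standard convention); ties among absolute differences
#' receive average ranks and the enumeration remains exact conditional on
#' the observed rank pattern.
#'
#' @param x,y Paired numeric vectors (equal length, 1-20 informative pairs).
#' @return An object of class `htest` with `statistic` (V, the positive-rank
#'   sum), `p.value`, and `parameter` (n after dropping zeros). If all
#'   differences are zero, `p.value` is 1 and the result carries a
#'   `degenerate = TRUE` attribute.
#' @examples
#' wilcoxon_signed_rank_exact(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
#' @export
wilcoxon_signed_rank_exact <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  if (anyNA(d)) stop("Paired differences contain NA.", call. = FALSE)
  d <- d[d != 0]
  method <- "Exact Wilcoxon matched-pairs signed-rank test (full enumeration)"
  if (length(d) == 0) {
    out <- structure(
      list(
        statistic = c(V = 0), p.value = 1, parameter = c(n = 0),
        method = method, alternative = "two.sided",
        data.name = "paired differences (all zero)"
      ),
      class = "htest", degenerate = TRUE
    )
    return(out)
  }
  n <- length(d)
  if (n > 20) {
    stop("Exact enumeration supports at most 20 informative pairs.", call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  # Enumerate the null distribution of V over all 2^n sign assignments.
  # Doubled ranks are integers even with average-rank ties, so the count of
  # assignments reaching each value of 2V is accumulated exactly.
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- rep(0, total + 1) # counts[k + 1] = #assignments with 2V == k
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  v2 <- as.integer(round(2 * v))
  p_le <- sum(counts[seq_len(v2 + 1)]) / 2^n
  p_ge <- sum(counts[seq.int(v2 + 1, total + 1)]) / 2^n
  p <- min(1, 2 * min(p_le, p_ge))
  structure(
    list(
      statistic = c(V = v), p.value = p, parameter = c(n = n),
      method = method, alternative = "two.sided",
      data.name = paste(deparse(substitute(x)), "vs", deparse(substitute(y)))
    ),
    class = "htest"
  )
}

#' Squared Pearson correlation between two quantitation methods
#'
#' @param x,y Numeric vectors of paired measurements (n >= 3, finite).
#' @return r^2 in `[0, 1]`; invariant to affine rescaling of either axis.
#' @export
method_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    stop("Need at least 3 finite pairs for a correlation.", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Correlation undefined: one of the vectors has zero variance.",
      call. = FALSE
    )
  }
  stats::cor(x, y)^2
}

#' Write a ranking report
#'
#' TSV of the ranking plus a JSON summary (per-LNP mean, SD, rank, n).
#'
#' @param ranking An `lnp_ranking`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `ranking`, invisibly.
#' @export
write_ranking <- function(ranking, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(ranking, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(ranking, json_path, dataframe = "rows", digits = NA)
  }
  invisible(ranking)
}
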