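#' Design constraints for peptide barcode candidates
#'
#' Bundles every tunable rule of the barcode design cascade. The defaults
#' encode the screening platform's published design: a 5-residue randomized
#' core; residues M, W, N, Q, C, R, K, D and E excluded from the core
#' (oxidation/deamidation-prone residues, plus K/R which would create internal
#' tryptic sites); exactly one proline in the core as an MS2 diagnostic
#' fragment anchor; constant 6-residue flanks on each side of the core to
#' stabilize trypsin digestion efficiency; and MS resolvability parameters
#' matching a typical high-resolution acquisition (350-2000 m/z full-scan
#' window, 1.2 m/z quadrupole isolation width).
#'
#' The default flank sequences are documented placeholders chosen from the
#' allowed alphabet (K/R-free so the barcode is released as one tryptic
#' peptide); every cascade count is flank-independent because the flanks add
#' a constant mass offset to all candidates.
#'
#' @param excluded_residues Character vector of one-letter codes banned from
#'   the variable core.
#' @param core_length Length of the randomized core (residues).
#' @param proline_rule `"exactly_one"` (default) or `"at_least_one"` proline
#'   in the core.
#' @param n_term_flank,c_term_flank Constant 6-residue flanks. Must be free
#'   of excluded residues; the C-terminal flank may end in K/R (a tryptic
#'   site terminating the barcode peptide) but neither flank may contain an
#'   internal K/R, which would split the barcode on digestion.
#' @param ms1_min_separation Minimum precursor mass separation (Da) for two
#'   barcodes to count as MS1-resolvable.
#' @param ms2_min_separation Minimum fragment m/z separation (Da) for two
#'   isobaric barcodes to count as MS2-distinguishable.
#' @param mz_window Numeric length-2: the instrument full-scan m/z range; a
#'   panel member must have at least one considered charge state inside it.
#' @param isolation_window Quadrupole isolation width (m/z) used to report
#'   potential co-selection of near-isobaric precursors.
#' @param charges_considered Integer vector of precursor charge states.
#' @return An object of class `design_constraints` (a validated list).
#' @examples
#' cons <- design_constraints()
#' length(cons$alphabet) # 11 residues remain available for the core
#' @export
design_constraints <- function(excluded_residues = c("M", "W", "N", "Q", "C", "R", "K", "D", "E"),
                               core_length = 5L,
                               proline_rule = c("exactly_one", "at_least_one"),
                               n_term_flank = "GSGSGA",
                               c_term_flank = "AGSGSG",
                               ms1_min_separation = 0.01,
                               ms2_min_separation = 0.01,
                               mz_window = c(350, 2000),
                               isolation_window = 1.2,
                               charges_considered = 1:3) {
  proline_rule <- match.arg(proline_rule)
  all20 <- names(residue_mass_table()$residues)
  stopifnot(all(excluded_residues %in% all20))
  alphabet <- sort(setdiff(all20, excluded_residues))
  if (length(alphabet) == 0L) {
    stop("All residues are excluded: the core alphabet is empty.", call. = FALSE)
  }
  if (!is.numeric(core_length) || core_length < 1L) {
    stop("`core_length` must be >= 1.", call. = FALSE)
  }
  if (!is.numeric(ms1_min_separation) || ms1_min_separation <= 0) {
    stop("`ms1_min_separation` must be > 0.", call. = FALSE)
  }
  validate_peptide(n_term_flank)
  validate_peptide(c_term_flank)
  check_flank(n_term_flank, excluded_residues, allow_terminal_kr = FALSE, "n_term_flank")
  check_flank(c_term_flank, excluded_residues, allow_terminal_kr = TRUE, "c_term_flank")
  stopifnot(length(mz_window) == 2L, mz_window[1] < mz_window[2])
  structure(
    list(
      excluded_residues = sort(excluded_residues),
      alphabet = alphabet,
      core_length = as.integer(core_length),
      proline_rule = proline_rule,
      n_term_flank = n_term_flank,
      c_term_flank = c_term_flank,
      ms1_min_separation = ms1_min_separation,
      ms2_min_separation = ms2_min_separation,
      mz_window = as.numeric(mz_window),
      isolation_window = isolation_window,
      charges_considered = sort(as.integer(charges_considered))
    ),
    class = "design_constraints"
  )
}

check_flank <- function(flank, excluded, allow_terminal_kr, what) {
  chars <- strsplit(flank, "", fixed = TRUE)[[1]]
  internal <- if (allow_terminal_kr) chars[-length(chars)] else chars
  if (any(internal %in% c("K", "R"))) {
    stop("`", what, "` contains an internal K/R, which would split the barcode ",
      "peptide on tryptic digestion.",
      call. = FALSE
    )
  }
  bad <- intersect(internal, excluded)
  if (length(bad) > 0) {
    stop("`", what, "` contains excluded residue(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(flank)
}

#' @export
print.design_constraints <- function(x, ...) {
  cat("Barcode design constraints\n")
  cat("  core:", x$core_length, "residues over {",
    paste(x$alphabet, collapse = ""), "}, proline rule:", x$proline_rule, "\n"
  )
  cat("  flanks:", x$n_term_flank, "/", x$c_term_flank, "\n")
  cat(
    "  MS1 separation:", x$ms1_min_separation, "Da; MS2 separation:",
    x$ms2_min_separation, "Da\n"
  )
  cat(
    "  scan window:", x$mz_window[1], "-", x$mz_window[2], "m/z; charges",
    paste(x$charges_considered, collapse = ","), "\n"
  )
  invisible(x)
}

#' Enumerate all candidate barcode cores
#'
#' Generates every `core_length`-mer over the allowed alphabet in ascending
#' lexicographic order. Under the default constraints (11 allowed residues,
#' length 5) this is the initial candidate database of 11^5 = 161,051 cores.
#'
#' @param constraints A [design_constraints()] object.
#' @return Character vector of cores, lexicographically ordered.
#' @export
enumerate_cores <- function(constraints = design_constraints()) {
  stopifnot(inherits(constraints, "design_constraints"))
  k <- constraints$core_length
  alpha <- constraints$alphabet
  # expand.grid varies its first factor fastest; feed positions in reverse so
  # that the first core position is the most significant lexicographically.
  grid <- expand.grid(rep(list(alpha), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

#' Filter cores by the proline rule
#'
#' Retains cores with exactly one (default) or at least one proline in the
#' variable region, preserving order. Under the default cascade the
#' exactly-one rule keeps 5 * 10^4 = 50,000 of the 161,051 enumerated cores.
#'
#' @param cores Character vector from [enumerate_cores()].
#' @inheritParams enumerate_cores
#' @return The retained cores, in input order.
#' @export
filter_proline <- function(cores, constraints = design_constraints()) {
  n_pro <- nchar(cores) - nchar(gsub("P", "", cores, fixed = TRUE))
  keep <- switch(constraints$proline_rule,
    exactly_one = n_pro == 1L,
    at_least_one = n_pro >= 1L
  )
  cores[keep]
}

#' Assemble full barcode candidates from filtered cores
#'
#' Prepends and appends the constant flanks, computes the monoisotopic mass
#' and the precursor m/z at each considered charge. Masses are computed from
#' residue counts so that permutations of one composition have bit-identical
#' masses, which exact-mass grouping downstream relies on.
#'
#' @param cores Character vector of cores (typically from [filter_proline()]).
#' @inheritParams enumerate_cores
#' @return A tibble with columns `barcode_id`, `core`, `full_peptide`,
#'   `mass`, and `mz_z<charge>` for each considered charge.
#' @export
assemble_barcodes <- function(cores, constraints = design_constraints()) {
  stopifnot(inherits(constraints, "design_constraints"), length(cores) > 0)
  tab <- default_mass_table()
  flank_mass <- monoisotopic_mass(constraints$n_term_flank, tab) +
    monoisotopic_mass(constraints$c_term_flank, tab) - 2 * tab$water
  mass <- composition_mass(cores, tab) + flank_mass
  out <- tibble::tibble(
    barcode_id = sprintf("BC%06d", seq_along(cores)),
    core = cores,
    full_peptide = paste0(constraints$n_term_flank, cores, constraints$c_term_flank),
    mass = mass
  )
  for (z in constraints$charges_considered) {
    out[[paste0("mz_z", z)]] <- (mass + z * tab$proton) / z
  }
  out
}

mz_in_window <- function(candidates, constraints) {
  ok <- rep(FALSE, nrow(candidates))
  for (z in constraints$charges_considered) {
    mz <- candidates[[paste0("mz_z", z)]]
    ok <- ok | (mz >= constraints$mz_window[1] & mz <= constraints$mz_window[2])
  }
  ok
}

#' Select an MS1-resolvable barcode panel
#'
#' Applies the final resolvability filter to assembled candidates. Two modes:
#'
#' * `strict_unique`: collapses candidates sharing an identical monoisotopic
#'   mass (permutations of one residue composition, and I/L swaps, are
#'   exactly isobaric) to one representative — the lexicographically smallest
#'   core — then retains representatives whose mass is at least
#'   `ms1_min_separation` away from every other representative's mass.
#' * `max_separated`: returns a maximum-cardinality subset with all pairwise
#'   mass separations at least `ms1_min_separation`, found by a sort-by-mass
#'   greedy sweep (optimal for points on a line).
#'
#' Candidates without any considered charge state inside the scan `mz_window`
#' are dropped first. Pairs of selected precursors falling within one
#' quadrupole `isolation_window` at a shared charge are counted and reported
#' (possible MS2 co-selection), but not filtered out.
#'
#' @param candidates Tibble from [assemble_barcodes()].
#' @inheritParams enumerate_cores
#' @param mode `"strict_unique"` or `"max_separated"`.
#' @param target_size Optional desired panel size. If fewer members are
#'   achievable a warning flag is set; if more are achievable the panel is
#'   thinned to `target_size` members by an even stride over the mass-sorted
#'   selection (keeps the mass spread).
#' @param lnp_labels Optional character vector of LNP labels to assign to the
#'   panel members in order; defaults to `LNP01`, `LNP02`, ...
#' @return An object of class `barcode_panel`: list with `members` (tibble
#'   with `nearest_neighbor_distance_Da` and `lnp_label` columns), `mode`,
#'   `tolerance_used`, `target_met`, and `coisolation_pairs`.
#' @export
select_panel <- function(candidates, constraints = design_constraints(),
                         mode = c("strict_unique", "max_separated"),
                         target_size = NULL, lnp_labels = NULL) {
  mode <- match.arg(mode)
  tol <- constraints$ms1_min_separation
  cand <- candidates[mz_in_window(candidates, constraints), , drop = FALSE]
  cand <- cand[order(cand$mass, cand$core), , drop = FALSE]

  if (mode == "strict_unique") {
    # one representative (lex-smallest core) per exact-mass class
    first_of_class <- !duplicated(cand$mass)
    reps <- cand[first_of_class, , drop = FALSE]
    m <- reps$mass
    gap_prev <- c(Inf, diff(m))
    gap_next <- c(diff(m), Inf)
    keep <- gap_prev >= tol & gap_next >= tol
    sel <- reps[keep, , drop = FALSE]
  } else {
    keep <- logical(nrow(cand))
    last <- -Inf
    for (i in seq_len(nrow(cand))) {
      if (cand$mass[i] - last >= tol) {
        keep[i] <- TRUE
        last <- cand$mass[i]
      }
    }
    sel <- cand[keep, , drop = FALSE]
  }

  target_met <- TRUE
  if (!is.null(target_size)) {
    if (nrow(sel) < target_size) {
      target_met <- FALSE
      warning(
        "Requested panel size ", target_size, " not achievable at separation ",
        tol, " Da; returning best achievable (", nrow(sel), ").",
        call. = FALSE
      )
    } else if (nrow(sel) > target_size) {
      idx <- unique(round(seq(1, nrow(sel), length.out = target_size)))
      sel <- sel[idx, , drop = FALSE]
    }
  }

  m <- sel$mass
  nn <- if (length(m) > 1) {
    pmin(c(Inf, diff(m)), c(diff(m), Inf))
  } else {
    rep(Inf, length(m))
  }
  sel$nearest_neighbor_distance_Da <- nn
  if (is.null(lnp_labels)) lnp_labels <- sprintf("LNP%02d", seq_len(nrow(sel)))
  if (length(lnp_labels) < nrow(sel)) {
    stop("Fewer `lnp_labels` than panel members.", call. = FALSE)
  }
  sel$lnp_label <- lnp_labels[seq_len(nrow(sel))]

  co <- 0L
  for (z in constraints$charges_considered) {
    mz <- sort(sel[[paste0("mz_z", z)]])
    in_win <- mz >= constraints$mz_window[1] & mz <= constraints$mz_window[2]
    mz <- mz[in_win]
    if (length(mz) > 1) co <- co + sum(diff(mz) < constraints$isolation_window)
  }

  structure(
    list(
      members = tibble::as_tibble(sel),
      mode = mode,
      tolerance_used = tol,
      target_met = target_met,
      coisolation_pairs = co
    ),
    class = "barcode_panel"
  )
}

#' @export
print.barcode_panel <- function(x, ...) {
  cat(
    "Barcode panel:", nrow(x$members), "members (mode", x$mode,
    ", MS1 separation", x$tolerance_used, "Da)\n"
  )
  if (x$coisolation_pairs > 0) {
    cat(
      "  note:", x$coisolation_pairs,
      "adjacent precursor pair(s) fall within one isolation window",
      "and may co-fragment at MS2\n"
    )
  }
  if (!x$target_met) cat("  warning: requested target size was not achievable\n")
  print(utils::head(x$members, 10))
  invisible(x)
}

#' Calibrate the MS1 separation tolerance for a desired panel size
#'
#' Panel size is non-increasing in the separation tolerance, so a bisection
#' over the tolerance finds the largest tolerance whose panel still has at
#' least `desired_panel_size` members. Because the tolerance behind any
#' particular published panel size is rarely stated, this is reported as a
#' calibration — the tolerance band over which the achievable panel brackets
#' the desired size — rather than asserted as a single value.
#'
#' @inheritParams select_panel
#' @param desired_panel_size Integer >= 1.
#' @param tol_range Numeric length-2 search interval (Da).
#' @param grid_points Number of log-spaced tolerances profiled.
#' @return A list with `tolerance` (largest achieving >= desired size),
#'   `achieved` (panel size there), `panel`, `band` (tolerances bracketing
#'   the drop below the desired size), `profile` (tibble of tolerance vs
#'   panel size), and `reachable`.
#' @export
calibrate_separation <- function(candidates, desired_panel_size,
                                 constraints = design_constraints(),
                                 mode = c("strict_unique", "max_separated"),
                                 tol_range = c(1e-5, 10), grid_points = 25) {
  mode <- match.arg(mode)
  stopifnot(desired_panel_size >= 1)
  size_at <- function(tol) {
    cons <- constraints
    cons$ms1_min_separation <- tol
    nrow(select_panel(candidates, cons, mode = mode)$members)
  }
  grid <- exp(seq(log(tol_range[1]), log(tol_range[2]), length.out = grid_points))
  sizes <- vapply(grid, size_at, integer(1))
  profile <- tibble::tibble(tolerance = grid, panel_size = sizes)
  if (sizes[1] < desired_panel_size) {
    return(list(
      tolerance = NA_real_, achieved = sizes[1], panel = NULL,
      band = c(NA_real_, NA_real_), profile = profile, reachable = FALSE
    ))
  }
  lo <- max(grid[sizes >= desired_panel_size])
  hi_cands <- grid[sizes < desired_panel_size]
  hi <- if (length(hi_cands) > 0) min(hi_cands) else tol_range[2]
  if (length(hi_cands) > 0) {
    for (i in 1:30) {
      mid <- sqrt(lo * hi)
      if (size_at(mid) >= desired_panel_size) lo <- mid else hi <- mid
    }
  }
  cons <- constraints
  cons$ms1_min_separation <- lo
  panel <- select_panel(candidates, cons, mode = mode)
  list(
    tolerance = lo, achieved = nrow(panel$members), panel = panel,
    band = c(lo, hi), profile = profile, reachable = TRUE
  )
}

#' Build the isobaric barcode library
#'
#' Barcodes sharing a precursor mass cannot be told apart at MS1 but may
#' still be usable together if their fragment-ion series differ at MS2.
#' Candidates are grouped by precursor mass (single linkage along the sorted
#' mass line: adjacent masses closer than `ms1_min_separation` join a group);
#' within each group a maximal subset is retained greedily (lexicographic
#' core order) such that every retained pair differs in at least one b or y
#' ion by `ms2_min_separation` or more. Note that two cores differing only by
#' I/L at the same positions have identical fragment series and can never be
#' distinguished.
#'
#' @inheritParams select_panel
#' @return An object of class `isobaric_library`: list with `groups` (tibble
#'   of retained members with `group_id`), `members_total` (retained members
#'   across groups of size >= 2), `n_groups` (groups of size >= 2).
#' @export
build_isobaric_library <- function(candidates, constraints = design_constraints()) {
  tab <- default_mass_table()
  tol <- constraints$ms1_min_separation
  ms2 <- constraints$ms2_min_separation
  cand <- candidates[order(candidates$mass, candidates$core), , drop = FALSE]
  grp <- cumsum(c(1, diff(cand$mass) >= tol))
  cand$group_id <- grp

  keep_all <- logical(nrow(cand))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) == 1L) {
      keep_all[idx] <- TRUE
      next
    }
    seqs <- cand$full_peptide[idx]
    b <- b_ion_matrix(seqs, tab)
    n <- nchar(seqs[1])
    y <- (cand$mass[idx] + 2 * tab$proton) - b[, rev(seq_len(n - 1L)), drop = FALSE]
    kept <- 1L
    for (j in 2:length(idx)) {
      db <- abs(b[kept, , drop = FALSE] -
        matrix(b[j, ], nrow = length(kept), ncol = n - 1L, byrow = TRUE))
      dy <- abs(y[kept, , drop = FALSE] -
        matrix(y[j, ], nrow = length(kept), ncol = n - 1L, byrow = TRUE))
      dmax <- do.call(pmax, c(
        as.data.frame(db, optional = TRUE),
        as.data.frame(dy, optional = TRUE)
      ))
      if (all(dmax >= ms2)) kept <- c(kept, j)
    }
    keep_all[idx[kept]] <- TRUE
  }

  retained <- cand[keep_all, , drop = FALSE]
  sizes <- table(retained$group_id)
  multi <- names(sizes)[sizes >= 2]
  structure(
    list(
      groups = tibble::as_tibble(retained[retained$group_id %in% multi, , drop = FALSE]),
      members_total = sum(sizes[sizes >= 2]),
      n_groups = length(multi),
      ms1_min_separation = tol,
      ms2_min_separation = ms2
    ),
    class = "isobaric_library"
  )
}

#' @export
print.isobaric_library <- function(x, ...) {
  cat(
    "Isobaric barcode library:", x$members_total,
    "MS2-distinguishable members in", x$n_groups, "isobaric group(s)\n"
  )
  cat(
    "  (MS1 grouping within", x$ms1_min_separation,
    "Da; MS2 distinction at >=", x$ms2_min_separation, "Da)\n"
  )
  invisible(x)
}

#' Write a panel report TSV
#'
#' @param panel A `barcode_panel`.
#' @param path Output TSV path.
#' @return The members tibble, invisibly.
#' @export
write_panel_report <- function(panel, path) {
  stopifnot(inherits(panel, "barcode_panel"))
  readr::write_tsv(panel$members, path)
  invisible(panel$members)
}

#' Export panel peptides as FASTA
#'
#' @inheritParams write_panel_report
#' @return `path`, invisibly.
#' @export
panel_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "barcode_panel"))
  seqs <- panel$members$full_peptide
  names(seqs) <- panel$members$barcode_id
  write_fasta(seqs, path)
}
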