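toy_constraints <- function(alphabet_keep, core_length = 2L, ...) {
  all20 <- names(residue_mass_table()$residues)
  flank <- strrep(alphabet_keep[1], 6)
  design_constraints(
    excluded_residues = setdiff(all20, alphabet_keep),
    core_length = core_length,
    n_term_flank = flank, c_term_flank = flank, ...
  )
}

# minimal assembled-candidate tibble for panel-selection tests
fake_candidates <- function(masses, cores = NULL) {
  n <- length(masses)
  if (is.null(cores)) cores <- sprintf("C%04d", seq_len(n))
  tibble::tibble(
    barcode_id = sprintf("BC%06d", seq_len(n)),
    core = cores,
    full_peptide = cores,
    mass = masses,
    mz_z1 = masses + 1.007276,
    mz_z2 = (masses + 2 * 1.007276) / 2,
    mz_z3 = (masses + 3 * 1.007276) / 3
  )
}

test_that("constraint validation enforces alphabet and flank rules", {
  cons <- design_constraints()
  expect_length(cons$alphabet, 11L)
  expect_false(any(c("M", "W", "N", "Q", "C", "R", "K", "D", "E") %in% cons$alphabet))
  all20 <- names(residue_mass_table()$residues)
  expect_error(design_constraints(excluded_residues = all20), "empty")
  expect_error(design_constraints(n_term_flank = "GSKSGA"), "internal K/R")
  expect_error(design_constraints(c_term_flank = "GSRSGA"), "internal K/R")
  # a trailing tryptic site on the C-terminal flank is legitimate
  expect_s3_class(
    design_constraints(
      c_term_flank = "AGSGSK",
      excluded_residues = c("M", "W", "N", "Q", "C", "R", "D", "E")
    ),
    "design_constraints"
  )
  expect_error(design_constraints(n_term_flank = "GSMSGA"), "excluded")
})

test_that("core enumeration is complete, lexicographic and sized |alphabet|^k", {
  expect_identical(enumerate_cores(toy_constraints("A", 5L)), "AAAAA")
  cons <- toy_constraints(c("A", "P"), 2L)
  cores <- enumerate_cores(cons)
  expect_identical(cores, c("AA", "AP", "PA", "PP"))
  cons3 <- toy_constraints(c("G", "A", "P"), 3L)
  cores3 <- enumerate_cores(cons3)
  expect_length(cores3, 27L)
  expect_identical(cores3, sort(cores3))
  expect_false(anyDuplicated(cores3) > 0)
})

test_that("proline filter implements both rules and preserves order", {
  cons <- toy_constraints(c("A", "P"), 2L)
  expect_identical(filter_proline(enumerate_cores(cons), cons), c("AP", "PA"))
  cons_al <- toy_constraints(c("A", "P"), 2L, proline_rule = "at_least_one")
  expect_identical(filter_proline(enumerate_cores(cons_al), cons_al), c("AP", "PA", "PP"))
})

test_that("assembled barcodes have correct structure, mass additivity, isobarism", {
  cons <- design_constraints()
  cand <- assemble_barcodes(c("APGLS", "APGIS"), cons)
  expect_equal(nchar(cand$full_peptide), c(17L, 17L))
  expect_identical(
    cand$full_peptide[1],
    paste0(cons$n_term_flank, "APGLS", cons$c_term_flank)
  )
  water <- residue_mass_table()$water
  flanks_only <- monoisotopic_mass(paste0(cons$n_term_flank, cons$c_term_flank))
  expect_equal(
    cand$mass[1],
    flanks_only + monoisotopic_mass("APGLS") - water,
    tolerance = 1e-9
  )
  # I <-> L in the core: identical mass, different sequence
  expect_identical(cand$mass[1], cand$mass[2])
  expect_false(cand$full_peptide[1] == cand$full_peptide[2])
  expect_equal(cand$mz_z2, precursor_mz(cand$full_peptide, 2), tolerance = 1e-9)
})

test_that("strict_unique panel selection drops colliding masses and dedups permutations", {
  cons <- design_constraints()
  cand <- fake_candidates(c(900.0, 900.0005, 1100.0))
  panel <- select_panel(cand, cons, mode = "strict_unique")
  expect_equal(nrow(panel$members), 1L)
  expect_equal(panel$members$mass, 1100.0)

  # all-distinct, widely spaced: everything retained
  cand2 <- fake_candidates(seq(900, 1000, by = 10))
  expect_equal(nrow(select_panel(cand2, cons, "strict_unique")$members), 11L)
  expect_equal(nrow(select_panel(cand2, cons, "max_separated")$members), 11L)

  # exact-mass class (permutations) collapses to lexicographically smallest core
  cand3 <- fake_candidates(c(900, 900, 1000), cores = c("PB", "BP", "AA"))
  panel3 <- select_panel(cand3, cons, "strict_unique")
  expect_setequal(panel3$members$core, c("BP", "AA"))
})

test_that("panel invariants hold: separation, m/z window, determinism", {
  cons <- design_constraints()
  set.seed(21)
  cores <- sample(filter_proline(enumerate_cores(cons), cons), 500)
  cand <- assemble_barcodes(cores, cons)
  for (mode in c("strict_unique", "max_separated")) {
    panel <- select_panel(cand, cons, mode = mode)
    m <- sort(panel$members$mass)
    expect_true(all(diff(m) >= panel$tolerance_used))
    in_win <- rep(FALSE, nrow(panel$members))
    for (z in cons$charges_considered) {
      mz <- panel$members[[paste0("mz_z", z)]]
      in_win <- in_win | (mz >= cons$mz_window[1] & mz <= cons$mz_window[2])
    }
    expect_true(all(in_win))
    # byte-identical reruns
    panel2 <- select_panel(cand, cons, mode = mode)
    expect_identical(panel$members, panel2$members)
  }
})

test_that("candidates outside the scan window at every charge are excluded", {
  cons <- design_constraints(charges_considered = 1L)
  cand <- fake_candidates(c(100, 900)) # mz_z1 101 is below the 350-2000 window
  panel <- select_panel(cand, cons, "max_separated")
  expect_equal(panel$members$mass, 900)
})

test_that("greedy max_separated equals the exhaustive maximum-subset oracle", {
  cons <- design_constraints()
  set.seed(22)
  for (i in 1:12) {
    n <- sample(5:14, 1)
    tol <- runif(1, 0.05, 2)
    masses <- 900 + cumsum(runif(n, 0, 2 * tol))
    masses <- sample(masses)
    cons$ms1_min_separation <- tol
    got <- nrow(select_panel(fake_candidates(masses), cons, "max_separated")$members)
    expect_equal(got, oracle_max_separated_size(masses, tol))
  }
})

test_that("unreachable target size is reported, achievable one thinned deterministically", {
  cons <- design_constraints()
  cand <- fake_candidates(seq(900, 990, by = 10))
  expect_warning(
    panel <- select_panel(cand, cons, "max_separated", target_size = 50),
    "not achievable"
  )
  expect_false(panel$target_met)
  panel2 <- select_panel(cand, cons, "max_separated", target_size = 4)
  expect_equal(nrow(panel2$members), 4L)
  expect_true(panel2$target_met)
})

test_that("separation calibration is monotone and brackets the requested size", {
  cons <- design_constraints()
  set.seed(23)
  masses <- 900 + cumsum(runif(60, 0.001, 0.6))
  cand <- fake_candidates(sample(masses))
  cal <- calibrate_separation(cand, 20, cons, mode = "max_separated")
  expect_true(cal$reachable)
  expect_true(all(diff(cal$profile$panel_size) <= 0))
  expect_gte(cal$achieved, 20)
  # just past the band's upper edge the panel falls below the desired size
  cons_hi <- cons
  cons_hi$ms1_min_separation <- cal$band[2] * 1.001
  expect_lt(nrow(select_panel(cand, cons_hi, "max_separated")$members), 20)
  # desired size 1 is reachable at any tolerance
  cal1 <- calibrate_separation(fake_candidates(900), 1, cons)
  expect_true(cal1$reachable)
  expect_equal(cal1$achieved, 1L)
})

test_that("isobaric grouping keeps only MS2-distinguishable members", {
  cons <- design_constraints()
  # same-position I/L swaps are invisible in every fragment: only one survives
  cand <- assemble_barcodes(c("APGIS", "APGLS"), cons)
  lib <- build_isobaric_library(cand, cons)
  expect_equal(lib$members_total, 0L) # the surviving group has one member
  expect_equal(lib$n_groups, 0L)

  # reordering residues changes the fragment series: both permutations survive
  cand2 <- assemble_barcodes(c("APGIS", "IPGAS"), cons)
  lib2 <- build_isobaric_library(cand2, cons)
  expect_equal(lib2$members_total, 2L)
  expect_equal(lib2$n_groups, 1L)

  # singleton mass groups never count toward members_total
  cand3 <- assemble_barcodes(c("APGGS", "FPYYH"), cons)
  lib3 <- build_isobaric_library(cand3, cons)
  expect_equal(lib3$members_total, 0L)
})

test_that("panel report and FASTA exports round-trip", {
  cons <- design_constraints()
  cand <- assemble_barcodes(c("APGLS", "GPAST", "HPFYV"), cons)
  panel <- select_panel(cand, cons, "max_separated")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_panel_report(panel, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$full_peptide, panel$members$full_peptide)
  expect_true(all(c("nearest_neighbor_distance_Da", "lnp_label") %in% names(back)))
  fa <- withr::local_tempfile(fileext = ".fasta")
  panel_fasta(panel, fa)
  expect_equal(unname(read_fasta(fa)), panel$members$full_peptide)
})
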