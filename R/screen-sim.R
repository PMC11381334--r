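#' Hill/Emax model for one LNP
#'
#' Each LNP's in-vivo protein output as a function of administered mRNA dose
#' is modelled with a saturating Hill curve: expression is far from linear in
#' dose and the curve shape is characteristic of the ionizable lipid.
#'
#' @param label LNP label.
#' @param emax Maximal protein signal (arbitrary units, > 0).
#' @param ed50 Dose at half-maximal signal (mg/kg, > 0).
#' @param hill Hill slope (>= 0, default 1).
#' @return A one-row tibble (class `lnp_model` prepended).
#' @export
lnp_model <- function(label, emax, ed50, hill = 1) {
  stopifnot(emax > 0, ed50 > 0, hill >= 0)
  out <- tibble::tibble(
    label = as.character(label),
    emax = emax, ed50 = ed50, hill = hill
  )
  class(out) <- c("lnp_model", class(out))
  out
}

#' Illustrative built-in LNP models
#'
#' Five ionizable-lipid LNPs in the potency order commonly reported for
#' hepatic mRNA delivery (MC3 > KC2 > C12-200 > DLin-DMA > DOTAP). The
#' numeric parameters are illustrative defaults for simulation studies, not
#' fitted values: adjacent potencies are separated about two-fold at a
#' 0.1 mg/kg screening dose, a spacing at which a 5-animal group resolves
#' the order comfortably.
#'
#' @return A tibble of five LNP models.
#' @export
default_lnp_models <- function() {
  dplyr::bind_rows(
    lnp_model("MC3", emax = 100, ed50 = 0.15, hill = 1.5),
    lnp_model("KC2", emax = 60, ed50 = 0.20, hill = 1.3),
    lnp_model("C12-200", emax = 35, ed50 = 0.25, hill = 1.2),
    lnp_model("DLin-DMA", emax = 20, ed50 = 0.30, hill = 1.1),
    lnp_model("DOTAP", emax = 10, ed50 = 0.35, hill = 1.0)
  )
}

#' Expected signal of an LNP at a dose (Hill/Emax)
#'
#' `emax * dose^hill / (ed50^hill + dose^hill)`; exactly 0 at dose 0 and
#' monotone non-decreasing in dose.
#'
#' @param model A one-row `lnp_model` (or tibble with `emax`, `ed50`, `hill`).
#' @param dose Dose in mg/kg (vectorized, >= 0).
#' @return Expected signal(s).
#' @export
dose_response <- function(model, dose) {
  if (any(dose < 0)) stop("`dose` must be >= 0.", call. = FALSE)
  stopifnot(nrow(model) == 1)
  out <- numeric(length(dose))
  pos <- dose > 0
  dh <- dose[pos]^model$hill
  out[pos] <- model$emax * dh / (model$ed50^model$hill + dh)
  out
}

#' Pooled-screen design
#'
#' Describes a simulated in-vivo screen: the pools (which LNPs at which
#' doses, with which barcode each is tracked), the group size, and the noise
#' and censoring model. Defaults mirror a typical screening study: groups of
#' 5 mice, a total mRNA dose cap of 0.5 mg/kg per pool (so a 5-LNP pool runs
#' at 0.1 mg/kg/LNP and a 10-LNP pool at 0.05 mg/kg/LNP), lognormal
#' inter-animal variability, and lognormal per-measurement MS noise.
#'
#' @param pools A data frame with columns `pool_id`, `label` (LNP label,
#'   matching a row of `models`), `barcode_id`, `dose` (mg/kg).
#' @param models A tibble of LNP models (e.g. [default_lnp_models()]).
#' @param n_animals Animals per pool group (default 5).
#' @param animal_cv Coefficient of variation of the animal-level lognormal
#'   factor shared by all barcodes within one animal (default 0.3).
#' @param ms_cv Coefficient of variation of the per-measurement lognormal
#'   MS noise (default 0.2).
#' @param loq Censoring threshold in signal units (default 0, no censoring).
#' @param total_dose_cap Maximum total dose per pool (default 0.5 mg/kg).
#' @param seed Integer seed; every random draw in the simulation derives
#'   from it.
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(pools, models = default_lnp_models(),
                          n_animals = 5L, animal_cv = 0.3, ms_cv = 0.2,
                          loq = 0, total_dose_cap = 0.5, seed = 1L) {
  need <- c("pool_id", "label", "barcode_id", "dose")
  stopifnot(all(need %in% names(pools)), n_animals >= 1, animal_cv >= 0, ms_cv >= 0)
  pools <- tibble::as_tibble(pools)
  if (!all(pools$label %in% models$label)) {
    stop("Every pool `label` must match a model label.", call. = FALSE)
  }
  totals <- tapply(pools$dose, pools$pool_id, sum)
  if (any(totals > total_dose_cap + 1e-12)) {
    stop(
      "Pool(s) exceed the total dose cap of ", total_dose_cap, " mg/kg: ",
      paste(names(totals)[totals > total_dose_cap], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      pools = pools, models = tibble::as_tibble(models),
      n_animals = as.integer(n_animals), animal_cv = animal_cv,
      ms_cv = ms_cv, loq = loq, total_dose_cap = total_dose_cap,
      seed = as.integer(seed)
    ),
    class = "screen_design"
  )
}

# lognormal with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# run `code` under a temporary RNG state seeded with `seed`
with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Simulate a pooled LNP screen
#'
#' For each animal of each pool group, the measured peak area of each
#' barcode is `dose_response(model, dose) * animal_factor * ms_factor`,
#' where the animal factor (lognormal, CV `animal_cv`) is shared by all
#' barcodes within the animal — so normalizing to a reference barcode
#' cancels it exactly — and the MS factor (lognormal, CV `ms_cv`) is drawn
#' per measurement. Areas below `loq` are censored at the LOQ and flagged.
#' The same seed always reproduces the same table.
#'
#' @param design A [screen_design()].
#' @param seed Optional integer overriding `design$seed`.
#' @return A list with `peaks` (a `peak_table`) and `truth` (tibble with the
#'   noise-free expected signal and the true within-pool potency rank of
#'   each barcode).
#' @export
simulate_screen <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "screen_design"))
  pools <- design$pools
  models <- design$models
  expected <- vapply(seq_len(nrow(pools)), function(i) {
    dose_response(models[models$label == pools$label[i], ], pools$dose[i])
  }, numeric(1))
  truth <- pools
  truth$expected_signal <- expected
  truth <- dplyr::mutate(
    dplyr::group_by(truth, .data$pool_id),
    true_rank = rank(-.data$expected_signal, ties.method = "average")
  )
  truth <- dplyr::ungroup(truth)

  peaks <- with_sim_seed(seed, {
    rows <- lapply(unique(pools$pool_id), function(pid) {
      sub <- pools[pools$pool_id == pid, , drop = FALSE]
      exp_sub <- truth$expected_signal[truth$pool_id == pid]
      lapply(seq_len(design$n_animals), function(a) {
        af <- rlnorm_cv(1, design$animal_cv)
        mf <- rlnorm_cv(nrow(sub), design$ms_cv)
        tibble::tibble(
          animal_id = paste0(pid, "_a", a),
          group_id = as.character(pid),
          barcode_id = sub$barcode_id,
          peak_area = exp_sub * af * mf
        )
      })
    })
    dplyr::bind_rows(unlist(rows, recursive = FALSE))
  })
  peaks$below_loq <- FALSE
  if (design$loq > 0) {
    low <- peaks$peak_area < design$loq
    peaks$below_loq <- low
    peaks$peak_area[low] <- design$loq
  }
  list(peaks = peak_table(peaks), truth = truth)
}

#' Monte-Carlo probability of recovering the true LNP ranking
#'
#' Repeatedly simulates the screen, ranks LNPs from the normalized fold
#' changes, and estimates the probability that the full true potency order
#' is recovered exactly, together with a per-pair recovery matrix (how often
#' each truly-better LNP ranks above each truly-worse one).
#'
#' @param design A [screen_design()] with a single pool.
#' @param n_replicates Number of Monte-Carlo replicates (>= 1).
#' @param reference_barcode Barcode used for normalization (default: the
#'   pool's truly most potent barcode).
#' @return A list with `p_exact`, `se` (binomial standard error),
#'   `pair_recovery` (matrix of pairwise recovery frequencies, rows = truly
#'   better LNP), and `n_replicates`.
#' @export
ranking_recovery <- function(design, n_replicates, reference_barcode = NULL) {
  stopifnot(inherits(design, "screen_design"), n_replicates >= 1)
  pid <- unique(design$pools$pool_id)
  if (length(pid) != 1) {
    stop("`ranking_recovery` expects a single-pool design.", call. = FALSE)
  }
  base <- simulate_screen(design)
  truth <- base$truth[order(base$truth$true_rank), ]
  true_order <- truth$label
  if (is.null(reference_barcode)) reference_barcode <- truth$barcode_id[1]
  assignment <- stats::setNames(design$pools$label, design$pools$barcode_id)

  labels <- true_order
  k <- length(labels)
  pair_hits <- matrix(0, k, k, dimnames = list(labels, labels))
  exact <- 0L
  for (r in seq_len(n_replicates)) {
    sim <- simulate_screen(design, seed = design$seed + r)
    norm <- normalize_to_reference(sim$peaks, reference_barcode)
    rk <- rank_lnps(norm, assignment)
    obs <- stats::setNames(rk$rank, rk$lnp)
    if (identical(unname(obs[labels]), as.numeric(seq_len(k)))) {
      exact <- exact + 1L
    }
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        if (obs[labels[i]] < obs[labels[j]]) {
          pair_hits[i, j] <- pair_hits[i, j] + 1
        }
      }
    }
  }
  p <- exact / n_replicates
  list(
    p_exact = p,
    se = sqrt(p * (1 - p) / n_replicates),
    pair_recovery = pair_hits / n_replicates,
    n_replicates = n_replicates
  )
}

#' Group size for a standardized effect (two-sample normal approximation)
#'
#' The per-group sample size needed to detect a difference of
#' `effect_sd_units` standard deviations between two group means:
#' `ceiling(2 * (z_{1-alpha/2} + z_{power})^2 / d^2)`. This is the standard
#' approximation behind choosing 5 animals per group to resolve a 2-SD
#' difference.
#'
#' @param effect_sd_units Effect size d in SD units (> 0).
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @param power Desired power (default 0.8).
#' @return Integer group size.
#' @examples
#' group_size_for_effect(2) # 4 by the unadjusted normal approximation
#' @export
group_size_for_effect <- function(effect_sd_units, alpha = 0.05, power = 0.8) {
  stopifnot(effect_sd_units > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(2 * z^2 / effect_sd_units^2))
}

#' Build a single-pool design over a set of LNP models
#'
#' Convenience wrapper: one pool containing every model at a common
#' per-LNP dose, each tracked by one barcode (`BC01`, `BC02`, ...).
#'
#' @param models LNP models tibble.
#' @param dose_per_lnp Dose per LNP (mg/kg).
#' @param pool_id Pool identifier.
#' @param ... Passed to [screen_design()].
#' @return A `screen_design`.
#' @export
pooled_design <- function(models = default_lnp_models(), dose_per_lnp = 0.1,
                          pool_id = "pool1", ...) {
  pools <- tibble::tibble(
    pool_id = pool_id,
    label = models$label,
    barcode_id = sprintf("BC%02d", seq_len(nrow(models))),
    dose = dose_per_lnp
  )
  screen_design(pools, models = models, ...)
}

#' Build an individual-administration design over a set of LNP models
#'
#' One singleton "pool" per LNP (its own animal group), as in a classical
#' one-LNP-per-group study arm.
#'
#' @inheritParams pooled_design
#' @return A `screen_design`.
#' @export
individual_design <- function(models = default_lnp_models(), dose_per_lnp = 0.1,
                              ...) {
  pools <- tibble::tibble(
    pool_id = paste0("grp_", models$label),
    label = models$label,
    barcode_id = sprintf("BC%02d", seq_len(nrow(models))),
    dose = dose_per_lnp
  )
  screen_design(pools, models = models, ...)
}
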