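# Independent oracles used across the suite. Each one derives its answer by a
# different route than the implementation it checks.

# Residue monoisotopic masses recomputed from elemental composition and atomic
# monoisotopic masses (CODATA/AME values), independently of the package's
# residue table.
oracle_residue_masses <- function() {
  atom <- c(
    H = 1.00782503207, C = 12, N = 14.0030740048,
    O = 15.9949146196, S = 31.97207100
  )
  # residue (amino acid minus water) elemental compositions, C/H/N/O/S
  comp <- list(
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0)
  )
  vapply(comp, function(x) {
    sum(x * atom[c("C", "H", "N", "O", "S")])
  }, numeric(1))
}

oracle_peptide_mass <- function(sequence) {
  res <- oracle_residue_masses()
  water <- 2 * 1.00782503207 + 15.9949146196
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(res[chars]) + water
}

# Exhaustive maximum-cardinality subset of masses with all pairwise gaps >= tol
oracle_max_separated_size <- function(masses, tol) {
  n <- length(masses)
  best <- 0L
  for (code in 0:(2^n - 1)) {
    sel <- masses[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
    if (length(sel) <= best) next
    if (length(sel) < 2 || min(diff(sort(sel))) >= tol) best <- length(sel)
  }
  best
}

# Exact two-sided signed-rank p by literal enumeration of sign vectors
oracle_wilcoxon_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  center_le <- mean(v_all <= v_obs)
  center_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(center_le, center_ge))
}

random_peptide <- function(n, alphabet = names(pals::residue_mass_table()$residues)) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# rank LNPs of an individually-administered arm by group mean raw peak area
# (no in-animal reference exists when each animal received a single LNP)
rank_individual_arm <- function(peaks, assignment) {
  peaks$lnp <- assignment[as.character(peaks$barcode_id)]
  means <- tapply(peaks$peak_area, peaks$lnp, mean)
  names(sort(means, decreasing = TRUE))
}
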