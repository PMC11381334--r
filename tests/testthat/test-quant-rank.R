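toy_peaks <- function() {
  peak_table(tibble::tibble(
    animal_id = rep(c("a1", "a2", "a3"), each = 3),
    group_id = "pool1",
    barcode_id = rep(c("B1", "B2", "B3"), 3),
    peak_area = c(200, 100, 50, 400, 220, 90, 100, 48, 26)
  ))
}

test_that("peak table validation catches malformed input", {
  expect_error(peak_table(data.frame(animal_id = 1)), "missing column")
  bad <- data.frame(
    animal_id = c("a", "a"), group_id = "g", barcode_id = c("b", "b"),
    peak_area = c(1, 2)
  )
  expect_error(peak_table(bad), "unique")
  neg <- data.frame(
    animal_id = "a", group_id = "g", barcode_id = "b", peak_area = -1
  )
  expect_error(peak_table(neg), "non-negative")
})

test_that("normalization divides per animal and maps the reference to 1", {
  single <- peak_table(tibble::tibble(
    animal_id = "a1", group_id = "g", barcode_id = c("B1", "B2"),
    peak_area = c(200, 100)
  ))
  norm <- normalize_to_reference(single, "B1")
  expect_equal(norm$fold_change[norm$barcode_id == "B1"], 1.0)
  expect_equal(norm$fold_change[norm$barcode_id == "B2"], 0.5)

  norm_all <- normalize_to_reference(toy_peaks(), "B1")
  expect_true(all(norm_all$fold_change[norm_all$barcode_id == "B1"] == 1.0))
})

test_that("normalization is invariant to per-animal scaling", {
  peaks <- toy_peaks()
  scaled <- peaks
  fac <- c(a1 = 3.7, a2 = 0.2, a3 = 11)
  scaled$peak_area <- scaled$peak_area * unname(fac[scaled$animal_id])
  expect_equal(
    normalize_to_reference(peak_table(scaled), "B1")$fold_change,
    normalize_to_reference(peaks, "B1")$fold_change
  )
})

test_that("animals lacking a usable reference are excluded by name", {
  peaks <- toy_peaks()
  peaks$below_loq[peaks$animal_id == "a2" & peaks$barcode_id == "B1"] <- TRUE
  expect_warning(norm <- normalize_to_reference(peaks, "B1"), "a2")
  expect_false("a2" %in% norm$animal_id)
  expect_setequal(unique(norm$animal_id), c("a1", "a3"))
})

test_that("LNP ranking orders by mean fold change with average-rank ties", {
  norm <- tibble::tibble(
    animal_id = "a", group_id = "g",
    barcode_id = c("B1", "B2", "B3"),
    fold_change = c(3, 2, 1)
  )
  assign <- c(B1 = "A", B2 = "B", B3 = "C")
  rk <- rank_lnps(norm, assign)
  expect_identical(rk$lnp, c("A", "B", "C"))
  expect_equal(rk$rank, c(1, 2, 3))

  tied <- tibble::tibble(
    animal_id = "a", group_id = "g",
    barcode_id = c("B1", "B2", "B3"), fold_change = c(3, 2, 2)
  )
  rk2 <- rank_lnps(tied, assign)
  expect_equal(sort(rk2$rank), c(1, 2.5, 2.5))
  # ranks are always a permutation (with tied averages) of 1..n
  expect_equal(sum(rk2$rank), sum(seq_len(3)))
})

test_that("ranking is invariant under strictly monotone transforms", {
  set.seed(51)
  norm <- tibble::tibble(
    animal_id = rep(paste0("a", 1:4), each = 5),
    group_id = "g",
    barcode_id = rep(paste0("B", 1:5), 4),
    fold_change = runif(20, 0.1, 5)
  )
  assign <- stats::setNames(paste0("L", 1:5), paste0("B", 1:5))
  base_order <- rank_lnps(norm, assign)$lnp
  for (f in list(function(x) 2 * x + 0, function(x) x^3, function(x) exp(x))) {
    tr <- norm
    tr$fold_change <- f(tr$fold_change)
    expect_identical(rank_lnps(tr, assign)$lnp, base_order)
  }
})

test_that("exact signed-rank test reproduces the one-sided-differences worked case", {
  res <- wilcoxon_signed_rank_exact(c(1.2, 2.1, 3.3, 4.0, 5.9), c(1, 2, 3, 3.5, 5))
  expect_equal(res$p.value, 0.0625)
  expect_equal(unname(res$parameter), 5)
  # 2/2^5 is the minimal attainable two-sided p at n = 5
  expect_equal(res$p.value, 2 / 2^5)
})

test_that("exact signed-rank test: symmetric data, zeros, degenerate input", {
  # signs perfectly balanced around the null statistic
  res <- wilcoxon_signed_rank_exact(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(res$p.value, 1.0)
  # zero differences are dropped before ranking
  res2 <- wilcoxon_signed_rank_exact(c(5, 1, 2, 3, 4, 6), c(5, 0, 1, 2, 3, 5))
  expect_equal(unname(res2$parameter), 5)
  expect_equal(res2$p.value, 0.0625)
  # all-zero differences: degenerate, p = 1
  res3 <- wilcoxon_signed_rank_exact(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res3$p.value, 1)
  expect_true(attr(res3, "degenerate"))
})

test_that("exact signed-rank test matches enumeration oracle and base R", {
  set.seed(52)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    x <- round(stats::rnorm(n), 2)
    y <- round(stats::rnorm(n), 2)
    x <- x + (x == y) * 0.01
    expect_equal(
      wilcoxon_signed_rank_exact(x, y)$p.value,
      oracle_wilcoxon_p(x, y)
    )
  }
  # untied continuous data: base R's exact test is an independent check
  for (i in 1:5) {
    n <- sample(5:10, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    expect_equal(
      wilcoxon_signed_rank_exact(x, y)$p.value,
      stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    )
  }
})

test_that("method correlation: exact cases, affine invariance, oracle, errors", {
  x <- c(0, 1, 2, 3)
  expect_equal(method_correlation(x, 2 * x + 1), 1.0)
  expect_equal(method_correlation(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0.0)
  set.seed(53)
  a <- stats::rnorm(20)
  b <- 0.3 * a + stats::rnorm(20)
  r2_oracle <- (sum((a - mean(a)) * (b - mean(b)))^2) /
    (sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(method_correlation(a, b), r2_oracle)
  expect_equal(method_correlation(a, b), method_correlation(5 * a - 2, -0.1 * b + 7))
  expect_error(method_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(method_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("LOQ censoring substitutes at the threshold and keeps an audit trail", {
  peaks <- peak_table(tibble::tibble(
    animal_id = c("a", "a"), group_id = "g",
    barcode_id = c("B1", "B2"), peak_area = c(1, 3)
  ))
  cens <- loq_censor(peaks, 2)
  expect_equal(cens$peak_area, c(2, 3))
  expect_equal(cens$below_loq, c(TRUE, FALSE))
  expect_equal(cens$peak_area_raw, c(1, 3))
  # loq approaching zero flags nothing
  none <- loq_censor(peaks, 1e-12)
  expect_false(any(none$below_loq))
  halved <- loq_censor(peaks, 2, method = "halve")
  expect_equal(halved$peak_area, c(1, 3))
  excl <- loq_censor(peaks, 2, method = "exclude")
  expect_equal(nrow(excl), 1L)
})

test_that("pool-size LOQ arithmetic scales linearly", {
  expect_equal(pool_loq_total(0.6, 10), 6)
  expect_equal(pool_loq_total(loq_reference$protein_ng_per_ml, 5), 3)
})
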